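#' Full descriptive profile of an annotated mitogenome
#'
#' One call recomputes, from the input annotation (and sequence when
#' available), the standard characterization tables: a genome summary (gene
#' counts by type and strand), the region composition/skew table, the codon
#' usage table of the protein-coding genes, the boundary overlap/spacer
#' summary, and a per-gene table with recomputed sizes, amino-acid counts
#' and upstream-attributed intergenic offsets. Nothing is passed through
#' from the input unverified: sizes come from the coordinates, amino-acid
#' counts from the stop model, offsets from the coordinate arithmetic.
#'
#' @param input a [MitoGenome-class], or a path to a GenBank flat file
#'   (`.gb`/`.gbk`/`.genbank`) or a feature-table TSV.
#' @param sequence optional genome FASTA path or sequence string, used when
#'   `input` is a feature table.
#' @param out_dir if non-NULL, the four report TSVs (`gene_table.tsv`,
#'   `composition.tsv`, `codon_usage.tsv`, `boundaries.tsv`) are written
#'   there with a provenance header; re-running on identical input is
#'   byte-identical.
#' @param code a [geneticCode()] object.
#' @return (invisibly when writing) a list of class `ProfileReport`:
#'   `summary`, `gene_table`, `composition`, `codon_usage`, `boundaries`.
#' @export
runProfile <- function(input, sequence = NULL, out_dir = NULL,
                       code = geneticCode(2L)) {
  genome <- if (is(input, "MitoGenome")) input
  else if (grepl("\\.(gb|gbk|genbank)$", input, ignore.case = TRUE))
    readGenBank(input)
  else readFeatureTable(input, sequence = sequence)

  f <- features(genome)
  has_seq <- !is.null(genomeSequence(genome))

  summary <- list(
    genome_length = genomeLength(genome),
    circular = isCircular(genome),
    n_by_type = table(factor(f$type, levels = .FEATURE_TYPES)),
    n_by_type_strand = table(factor(f$type, levels = .FEATURE_TYPES),
                             factor(f$strand, levels = c("H", "L"))))

  # per-gene table; init/term re-inferred from sequence when present
  gene_table <- f
  if (has_seq) {
    for (i in which(f$type == "PCG")) {
      info <- inferInitTerm(featureSequence(genome, i), code)
      gene_table$init_codon[i] <- info$initiation
      gene_table$term_codon[i] <- info$termination
    }
  }
  stop_len <- ifelse(is.na(gene_table$term_codon), NA_integer_,
                     ifelse(gene_table$term_codon %in% code$stops, 3L,
                            nchar(gene_table$term_codon)))
  gene_table$n_aa <- ifelse(gene_table$type == "PCG",
                            (gene_table$size - stop_len) %/% 3L, NA_integer_)
  off <- boundaryOffsets(genome)
  gene_table$intergenic <- off$offset[match(gene_table$name, off$upstream)]

  composition <- if (has_seq) {
    comp <- regionComposition(genome)
    pc <- c("pct_A", "pct_T", "pct_C", "pct_G", "at_content")
    comp[pc] <- lapply(comp[pc], round, 2L)
    comp[c("at_skew", "gc_skew")] <-
      lapply(comp[c("at_skew", "gc_skew")], round, 4L)
    comp
  } else NULL

  codon_usage <- if (has_seq && any(f$type == "PCG"))
    usageTable(countCodons(featureSequences(genome, "PCG"), code)) else NULL

  bounds <- summarizeBoundaries(genome)
  boundary_table <- off
  boundary_table$kind <- ifelse(off$offset < 0L, "overlap",
                                ifelse(off$offset > 0L, "spacer", "abutting"))

  report <- list(summary = summary, gene_table = gene_table,
                 composition = composition, codon_usage = codon_usage,
                 boundaries = bounds, boundary_table = boundary_table)
  class(report) <- "ProfileReport"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    src <- if (is.character(input)) basename(input) else "in-memory MitoGenome"
    .writeReport(gene_table, file.path(out_dir, "gene_table.tsv"), src)
    if (!is.null(composition))
      .writeReport(composition, file.path(out_dir, "composition.tsv"), src)
    if (!is.null(codon_usage))
      .writeReport(codon_usage, file.path(out_dir, "codon_usage.tsv"), src)
    .writeReport(boundary_table, file.path(out_dir, "boundaries.tsv"), src)
    return(invisible(report))
  }
  report
}

# plain TSV with a small comment header; deliberately no timestamps so that
# re-runs on identical input are byte-identical
.writeReport <- function(df, path, src) {
  header <- c(sprintf("# mitoprofile %s", packageVersion("mitoprofile")),
              sprintf("# input: %s", src))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

#' @export
print.ProfileReport <- function(x, ...) {
  cat(sprintf("Mitogenome profile: %d bp, %d features\n",
              x$summary$genome_length, nrow(x$gene_table)))
  print(x$summary$n_by_type_strand)
  print(x$boundaries)
  invisible(x)
}

#' Ka/Ks grid from per-gene alignment files
#'
#' Reads one FASTA per gene (each holding the codon-aligned CDS of every
#' species, named by species), runs [kaksMatrix()], and optionally writes
#' the long-format grid TSV.
#'
#' @param input directory of per-gene FASTA files (`<gene>.fa[sta]`), or a
#'   ready `cds_sets` list as for [kaksMatrix()].
#' @param out optional output TSV path.
#' @param code a [geneticCode()] object.
#' @param exclude_stops passed to [kaksMatrix()].
#' @return the [kaksMatrix()] result list.
#' @export
runKaks <- function(input, out = NULL, code = geneticCode(2L),
                    exclude_stops = TRUE) {
  if (is.character(input)) {
    files <- list.files(input, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", input)
    cds_sets <- list()
    for (fp in files) {
      gene <- sub("\\.(fa|fasta)$", "", basename(fp))
      seqs <- Biostrings::readDNAStringSet(fp)
      for (sp in names(seqs))
        cds_sets[[sp]][[gene]] <- as.character(seqs[[sp]])
    }
  } else cds_sets <- input
  res <- kaksMatrix(cds_sets, code, exclude_stops)
  if (!is.null(out)) {
    .writeReport(res$results, out,
                 sprintf("kaks (stop exclusion %s)",
                         if (exclude_stops) "on" else "off"))
  }
  res
}

.CANONICAL_PCGS <- c("ND1", "ND2", "COXI", "COXII", "ATP8", "ATP6", "COXIII",
                     "ND3", "ND4L", "ND4", "ND5", "ND6", "Cytb")

#' Export a concatenated 13-gene supermatrix
#'
#' Concatenates the 13 canonical protein-coding genes of each genome in
#' canonical order, coding orientation, terminal stop signals trimmed, and
#' writes a FASTA plus a `gene = start-end` partition file for downstream
#' alignment/tree software. Genomes missing any of the 13 genes are skipped
#' with a warning. Per-gene lengths must agree across the retained genomes
#' (align per gene first if they do not).
#'
#' @param genomes list of [MitoGenome-class] objects with sequences, named
#'   by taxon.
#' @param file FASTA output path.
#' @param partition_file optional partition file path.
#' @param code a [geneticCode()] object.
#' @return invisibly, a list with `matrix` (named character) and
#'   `partitions` (data.frame `gene`, `start`, `end`).
#' @export
exportSupermatrix <- function(genomes, file, partition_file = NULL,
                              code = geneticCode(2L)) {
  if (is.null(names(genomes)))
    names(genomes) <- paste0("taxon", seq_along(genomes))
  per_tax <- list()
  for (tx in names(genomes)) {
    g <- genomes[[tx]]
    have <- features(g)$name
    missing <- setdiff(.CANONICAL_PCGS, have)
    if (length(missing)) {
      warning("genome ", tx, " missing ", paste(missing, collapse = ", "),
              "; skipped")
      next
    }
    per_tax[[tx]] <- vapply(.CANONICAL_PCGS, function(gene)
      trimTerminalStop(featureSequence(g, gene), code), "")
  }
  if (!length(per_tax)) stop("no genome carries all 13 protein-coding genes")
  lens <- vapply(per_tax, nchar, integer(length(.CANONICAL_PCGS)))
  lens <- matrix(lens, nrow = length(.CANONICAL_PCGS))
  if (any(apply(lens, 1L, function(x) length(unique(x)) > 1L)))
    stop("per-gene lengths differ across genomes; align each gene first")
  gene_len <- lens[, 1L]
  ends <- cumsum(gene_len)
  partitions <- data.frame(gene = .CANONICAL_PCGS,
                           start = c(1L, head(ends, -1L) + 1L), end = ends,
                           stringsAsFactors = FALSE)
  mat <- vapply(per_tax, paste, "", collapse = "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mat), file)
  if (!is.null(partition_file))
    writeLines(sprintf("%s = %d-%d", partitions$gene, partitions$start,
                       partitions$end), partition_file)
  invisible(list(matrix = mat, partitions = partitions))
}
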