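#' MitoGenome: an annotated (usually circular) mitochondrial genome
#'
#' Container for a mitogenome annotation: an optional nucleotide sequence
#' (the published heavy-strand reference), a circularity flag, a genome
#' length, and an ordered feature table. Feature coordinates are 1-based
#' inclusive throughout, matching GenBank convention. A feature whose `end`
#' is smaller than its `start` wraps across the origin of a circular genome;
#' its size is `genome_length - start + 1 + end`.
#'
#' The feature table has one row per locus with columns `name`, `type`
#' (one of `PCG`, `tRNA`, `rRNA`, `control_region`), `start`, `end`, `size`,
#' `strand` (`H` or `L`), `anticodon` (tRNAs), `init_codon` and `term_codon`
#' (protein-coding genes; `term_codon` may be an incomplete `TA` or `T`
#' completed by polyadenylation in vivo). Duplicate tRNA names (the two Ser
#' and two Leu genes of vertebrate mitogenomes) are disambiguated by
#' appending the anticodon, e.g. `tRNA-Ser(TGA)`.
#'
#' @slot sequence character; length-0 when no sequence is attached,
#'   otherwise a single A/C/G/T/N string.
#' @slot circular logical flag.
#' @slot length integer genome length in bp.
#' @slot features data.frame as described above, sorted by `start`.
#'
#' @aliases MitoGenome
#' @exportClass MitoGenome
setClass("MitoGenome",
  slots = c(sequence = "character", circular = "logical",
            length = "integer", features = "data.frame"))

.FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "control_region")

.featureSize <- function(start, end, genome_length) {
  ifelse(end >= start, end - start + 1L, genome_length - start + 1L + end)
}

setValidity("MitoGenome", function(object) {
  f <- object@features
  msgs <- character(0)
  need <- c("name", "type", "start", "end", "size", "strand",
            "anticodon", "init_codon", "term_codon")
  if (!all(need %in% names(f)))
    return(paste("features lacks columns:",
                 paste(setdiff(need, names(f)), collapse = ", ")))
  if (nrow(f)) {
    if (any(f$start < 1L) || any(f$end < 1L))
      msgs <- c(msgs, "coordinates must be >= 1")
    if (!all(f$type %in% .FEATURE_TYPES))
      msgs <- c(msgs, paste("unknown feature type:",
                            paste(unique(setdiff(f$type, .FEATURE_TYPES)), collapse = ", ")))
    if (!all(f$strand %in% c("H", "L")))
      msgs <- c(msgs, "strand must be 'H' or 'L'")
    expect <- .featureSize(f$start, f$end, object@length)
    if (any(f$size != expect))
      msgs <- c(msgs, paste("size disagrees with coordinates for:",
                            paste(f$name[f$size != expect], collapse = ", ")))
    if (anyDuplicated(f$name))
      msgs <- c(msgs, paste("duplicate feature names after disambiguation:",
                            paste(unique(f$name[duplicated(f$name)]), collapse = ", ")))
    if (any(f$end > object@length & f$end >= f$start))
      msgs <- c(msgs, "feature end beyond genome length")
    if (!object@circular && any(f$end < f$start))
      msgs <- c(msgs, "wrapping feature on a linear genome")
  }
  if (length(object@sequence) == 1L && nchar(object@sequence) != object@length)
    msgs <- c(msgs, "genome length disagrees with sequence length")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MitoGenome
#'
#' @param features data.frame with at least `name`, `type`, `start`, `end`,
#'   `strand`; optional `anticodon`, `init_codon`, `term_codon` and `size`
#'   (checked against the coordinates when present).
#' @param sequence optional nucleotide string (or `Biostrings::DNAString`)
#'   for the heavy-strand reference.
#' @param circular logical, default `TRUE`.
#' @param genome_length required when no sequence is given and features wrap;
#'   otherwise inferred from the sequence or from `max(end)`.
#' @return a validated [MitoGenome-class] object with features sorted by
#'   start and duplicate tRNA names disambiguated by anticodon.
#' @examples
#' g <- MitoGenome(data.frame(name = "geneX", type = "PCG", start = 1,
#'                            end = 300, strand = "H"))
#' genomeLength(g)
#' @export
MitoGenome <- function(features, sequence = NULL, circular = TRUE,
                       genome_length = NULL) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("no features")
  need <- c("name", "type", "start", "end", "strand")
  if (!all(need %in% names(features)))
    stop("features lacks required columns: ",
         paste(setdiff(need, names(features)), collapse = ", "))
  f <- features
  f$type[f$type %in% c("D-loop", "CR", "d-loop")] <- "control_region"
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  if (anyNA(f$start) || anyNA(f$end)) stop("non-numeric coordinate")
  for (col in c("anticodon", "init_codon", "term_codon"))
    if (is.null(f[[col]])) f[[col]] <- NA_character_
  if (!is.null(sequence)) {
    sequence <- .normSeq(as.character(sequence), what = "genome sequence")
    genome_length <- nchar(sequence)
  } else if (is.null(genome_length)) {
    if (any(f$end < f$start))
      stop("genome_length required when features wrap and no sequence is given")
    genome_length <- max(f$end)
  }
  genome_length <- as.integer(genome_length)
  size <- .featureSize(f$start, f$end, genome_length)
  if (!is.null(f$size)) {
    given <- suppressWarnings(as.integer(f$size))
    bad <- which(!is.na(given) & given != size)
    if (length(bad))
      stop("size column disagrees with coordinates for row(s): ",
           paste(f$name[bad], collapse = ", "))
  }
  f$size <- size
  # disambiguate the duplicated tRNA-Ser / tRNA-Leu style names by anticodon
  dup <- f$name %in% f$name[duplicated(f$name)]
  fix <- dup & !is.na(f$anticodon)
  f$name[fix] <- paste0(f$name[fix], "(", f$anticodon[fix], ")")
  if (is.unsorted(f$start)) f <- f[order(f$start), , drop = FALSE]
  keep <- c("name", "type", "start", "end", "size", "strand",
            "anticodon", "init_codon", "term_codon")
  f <- f[, keep]
  rownames(f) <- NULL
  if (!is.null(sequence) && grepl("N", sequence, fixed = TRUE))
    message("genome sequence contains N bases; they are excluded from ",
            "composition percentages")
  new("MitoGenome",
      sequence = if (is.null(sequence)) character(0) else sequence,
      circular = isTRUE(circular), length = genome_length, features = f)
}

#' @describeIn MitoGenome feature table accessor.
#' @param x a `MitoGenome`.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @export
setMethod("features", "MitoGenome", function(x) x@features)

#' @describeIn MitoGenome genome length (bp) accessor.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @export
setMethod("genomeLength", "MitoGenome", function(x) x@length)

#' @describeIn MitoGenome heavy-strand sequence accessor (`NULL` if absent).
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @export
setMethod("genomeSequence", "MitoGenome", function(x)
  if (length(x@sequence)) x@sequence else NULL)

#' @describeIn MitoGenome circularity flag accessor.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @export
setMethod("isCircular", "MitoGenome", function(x) x@circular)

setMethod("show", "MitoGenome", function(object) {
  f <- object@features
  cat(sprintf("MitoGenome: %s genome, %d bp, %d features%s\n",
              if (object@circular) "circular" else "linear",
              object@length, nrow(f),
              if (length(object@sequence)) " (sequence attached)" else ""))
  tab <- table(factor(f$type, levels = .FEATURE_TYPES))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  byStrand <- table(factor(f$strand, levels = c("H", "L")))
  cat(sprintf("  strand H: %d, strand L: %d\n", byStrand["H"], byStrand["L"]))
  invisible(NULL)
})
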