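#' Read an annotation feature table
#'
#' Parses the simple tab-separated annotation dialect used throughout the
#' package: required columns `name`, `type`, `from`, `to`, `strand`, optional
#' `anticodon`, `init_codon`, `term_codon` and `size` (the latter is checked
#' against `to - from + 1`, wrap-aware). Any additional columns are ignored.
#' Coordinates are 1-based inclusive; `to < from` denotes a feature wrapping
#' the origin of a circular genome.
#'
#' @param file path to a TSV file, or a character vector of TSV text lines.
#' @param sequence optional genome sequence (string, `DNAString`, or path to
#'   a FASTA file); when given, the genome length comes from it.
#' @param circular logical, default `TRUE`.
#' @param genome_length optional explicit length (otherwise `max(to)` when no
#'   sequence is supplied).
#' @return a [MitoGenome-class].
#' @seealso [writeFeatureTable()], [readGenBank()]
#' @export
readFeatureTable <- function(file, sequence = NULL, circular = TRUE,
                             genome_length = NULL) {
  if (length(file) > 1L || grepl("\t|\n", file[1L])) {
    tab <- read.delim(text = paste(file, collapse = "\n"),
                      stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else {
    tab <- read.delim(file, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  if (nrow(tab) == 0L) stop("no features")
  need <- c("name", "type", "from", "to", "strand")
  if (!all(need %in% names(tab)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  coord <- suppressWarnings(cbind(as.integer(tab$from), as.integer(tab$to)))
  if (anyNA(coord))
    stop("non-numeric coordinate in row(s): ",
         paste(tab$name[apply(is.na(coord), 1L, any)], collapse = ", "))
  f <- data.frame(name = tab$name, type = tab$type,
                  start = coord[, 1L], end = coord[, 2L],
                  strand = tab$strand, stringsAsFactors = FALSE)
  for (col in c("anticodon", "init_codon", "term_codon", "size"))
    if (!is.null(tab[[col]])) f[[col]] <- tab[[col]]
  if (is.character(sequence) && length(sequence) == 1L &&
      file.exists(sequence) && !grepl("^[ACGTUacgtun]+$", sequence)) {
    sequence <- as.character(Biostrings::readDNAStringSet(sequence)[[1L]])
  }
  MitoGenome(f, sequence = sequence, circular = circular,
             genome_length = genome_length)
}

#' Write the annotation feature table
#'
#' Emits the TSV dialect read by [readFeatureTable()] plus a derived
#' `intergenic` column: the offset to the next feature attributed to the
#' upstream row (negative = overlap, positive = spacer), as computed by
#' [boundaryOffsets()].
#'
#' @param genome a [MitoGenome-class].
#' @param file output path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of TSV lines.
#' @export
writeFeatureTable <- function(genome, file = NULL) {
  f <- features(genome)
  out <- data.frame(name = f$name, type = f$type, from = f$start, to = f$end,
                    size = f$size, strand = f$strand, anticodon = f$anticodon,
                    init_codon = f$init_codon, term_codon = f$term_codon,
                    stringsAsFactors = FALSE)
  out$intergenic <- NA_integer_
  if (nrow(f) >= 2L) {
    off <- boundaryOffsets(genome)
    out$intergenic[match(off$upstream, out$name)] <- off$offset
  }
  lines <- c(paste(names(out), collapse = "\t"),
             apply(out, 1L, function(r) paste(ifelse(is.na(r), "NA", trimws(r)),
                                              collapse = "\t")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
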