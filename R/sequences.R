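#' Extract a feature's sequence in coding orientation
#'
#' Heavy-strand features return the genome slice as-is; light-strand features
#' return its reverse complement; wrapping features (`end < start` on a
#' circular genome) concatenate the tail and head slices before orientation.
#' The returned string always has length equal to the feature size.
#'
#' @param genome a [MitoGenome-class] with a sequence attached.
#' @param feature a feature name, or a row index into `features(genome)`.
#' @return a character string (coding orientation).
#' @examples
#' g <- MitoGenome(data.frame(name = "x", type = "PCG", start = 4, end = 6,
#'                            strand = "L"), sequence = "AAACCC")
#' featureSequence(g, "x")  # "GGG"
#' @export
featureSequence <- function(genome, feature) {
  seq <- genomeSequence(genome)
  if (is.null(seq)) stop("genome has no sequence attached")
  f <- features(genome)
  i <- if (is.character(feature)) match(feature, f$name) else as.integer(feature)
  if (is.na(i) || i < 1L || i > nrow(f)) stop("no such feature: ", feature)
  s <- .spanSequence(seq, f$start[i], f$end[i], genomeLength(genome),
                     isCircular(genome))
  if (f$strand[i] == "L") s <- revComp(s)
  s
}

# raw H-strand slice for a (possibly wrapping) span
.spanSequence <- function(seq, start, end, L, circular) {
  if (end >= start) {
    if (end > nchar(seq)) stop("coordinates beyond genome length")
    return(substring(seq, start, end))
  }
  if (!circular) stop("wrapping span on a linear genome")
  paste0(substring(seq, start, L), substring(seq, 1L, end))
}

#' Extract all feature sequences
#'
#' @param genome a [MitoGenome-class] with sequence.
#' @param type optional filter (e.g. `"PCG"`).
#' @return a named character vector of coding-orientation sequences, in
#'   genome order.
#' @export
featureSequences <- function(genome, type = NULL) {
  f <- features(genome)
  idx <- if (is.null(type)) seq_len(nrow(f)) else which(f$type %in% type)
  setNames(vapply(idx, function(i) featureSequence(genome, i), ""),
           f$name[idx])
}

#' Offsets between consecutive gene boundaries
#'
#' For consecutive features (sorted by start) the offset is
#' `next_start - current_end - 1`: negative values are overlaps, positive
#' values intergenic spacers, zero means the genes abut. On a circular genome
#' the closing pair wraps: `first_start + genome_length - last_end - 1`.
#' Each offset is attributed to the upstream feature's row.
#'
#' @param genome a [MitoGenome-class] with at least two features.
#' @return data.frame with columns `upstream`, `downstream`, `offset` (one
#'   row per feature on circular genomes, `n - 1` rows on linear ones).
#' @seealso [summarizeBoundaries()]
#' @export
boundaryOffsets <- function(genome) {
  f <- features(genome)
  if (nrow(f) < 2L) stop("need at least two features")
  n <- nrow(f)
  off <- f$start[-1L] - f$end[-n] - 1L
  out <- data.frame(upstream = f$name[-n], downstream = f$name[-1L],
                    offset = off, stringsAsFactors = FALSE)
  if (isCircular(genome)) {
    closing <- f$start[1L] + genomeLength(genome) - f$end[n] - 1L
    out <- rbind(out, data.frame(upstream = f$name[n], downstream = f$name[1L],
                                 offset = closing))
  }
  rownames(out) <- NULL
  out
}
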