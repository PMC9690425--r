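#' Summarize gene-boundary overlaps and intergenic spacers
#'
#' Builds on [boundaryOffsets()]: negative offsets are overlaps, positive
#' offsets spacers; zero offsets (abutting genes) count as neither. On
#' circular genomes the closing boundary (last feature back to the first) is
#' included.
#'
#' @param genome a [MitoGenome-class] with at least two features.
#' @return list of class `BoundarySummary` with elements `overlaps` and
#'   `spacers` (data.frames `upstream`, `downstream`, `bp`), `n_overlaps`,
#'   `n_spacers`, `max_overlap`, `max_spacer`, `total_overlap_bp`,
#'   `total_spacer_bp` (magnitudes, in bp).
#' @examples
#' f <- data.frame(name = c("a", "b"), type = "PCG",
#'                 start = c(1, 91), end = c(100, 200), strand = "H")
#' summarizeBoundaries(MitoGenome(f, circular = FALSE))$max_overlap  # 10
#' @export
summarizeBoundaries <- function(genome) {
  off <- boundaryOffsets(genome)
  ov <- off[off$offset < 0L, , drop = FALSE]
  sp <- off[off$offset > 0L, , drop = FALSE]
  out <- list(
    overlaps = data.frame(upstream = ov$upstream, downstream = ov$downstream,
                          bp = -ov$offset, stringsAsFactors = FALSE),
    spacers = data.frame(upstream = sp$upstream, downstream = sp$downstream,
                         bp = sp$offset, stringsAsFactors = FALSE),
    n_overlaps = nrow(ov), n_spacers = nrow(sp),
    max_overlap = if (nrow(ov)) max(-ov$offset) else 0L,
    max_spacer = if (nrow(sp)) max(sp$offset) else 0L,
    total_overlap_bp = sum(-ov$offset), total_spacer_bp = sum(sp$offset))
  class(out) <- "BoundarySummary"
  out
}

#' @export
print.BoundarySummary <- function(x, ...) {
  cat(sprintf("%d overlaps (max %d bp, total %d bp); %d spacers (max %d bp, total %d bp)\n",
              x$n_overlaps, x$max_overlap, x$total_overlap_bp,
              x$n_spacers, x$max_spacer, x$total_spacer_bp))
  invisible(x)
}

#' Signed gene-order string
#'
#' Gene names in start-coordinate order, prefixed with `-` for light-strand
#' features.
#'
#' @param genome a [MitoGenome-class].
#' @return character vector of signed names.
#' @export
geneOrderString <- function(genome) {
  f <- features(genome)
  if (any(is.na(f$name)) || any(!nzchar(f$name))) stop("unnamed features")
  paste0(ifelse(f$strand == "L", "-", ""), f$name)
}

#' Compare two gene orders
#'
#' Signed gene-order vectors (see [geneOrderString()]) are compared
#' rotation-invariantly when `circular = TRUE`, as appropriate for circular
#' genomes: two orders differing only by the choice of origin are identical.
#'
#' @param a,b [MitoGenome-class] objects or signed gene-order character
#'   vectors.
#' @param circular whether rotations count as identical (default `TRUE`).
#' @return list with `identical` (logical) and `first_divergence` (the
#'   unsigned name at the first differing position, `NA` when identical).
#' @export
compareGeneOrder <- function(a, b, circular = TRUE) {
  if (is(a, "MitoGenome")) a <- geneOrderString(a)
  if (is(b, "MitoGenome")) b <- geneOrderString(b)
  strip <- function(x) sub("^-", "", x)
  if (length(a) == length(b)) {
    rots <- if (circular) seq_along(b) - 1L else 0L
    for (r in rots) {
      rb <- if (r == 0L) b else c(b[-seq_len(r)], b[seq_len(r)])
      if (identical(a, rb))
        return(list(identical = TRUE, first_divergence = NA_character_))
    }
  }
  # align on the unsigned name of a's first gene where possible
  pos <- match(strip(a[1L]), strip(b))
  rb <- if (!is.na(pos) && circular && pos > 1L)
    c(b[pos:length(b)], b[seq_len(pos - 1L)]) else b
  n <- min(length(a), length(rb))
  mism <- which(a[seq_len(n)] != rb[seq_len(n)])
  first <- if (length(mism)) strip(a[mism[1L]]) else
    strip(a[min(n + 1L, length(a))])
  list(identical = FALSE, first_divergence = first)
}

#' Canonical vertebrate mitochondrial gene order
#'
#' The signed 38-element gene order (37 genes plus control region) shared by
#' most vertebrates, with ND6 and eight tRNAs on the light strand; duplicate
#' Ser/Leu tRNAs carry their anticodon.
#'
#' @return signed gene-name character vector.
#' @export
canonicalVertebrateOrder <- function() {
  geneOrderString(ariusMaculatusAnnotation())
}
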