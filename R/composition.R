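#' Base counts of a nucleotide sequence
#'
#' Case-insensitive; U is treated as T; N is counted separately and excluded
#' from downstream percentages. Characters outside A/C/G/T/U/N raise an
#' error.
#'
#' @param seq nucleotide string.
#' @return named integer vector with elements `A`, `C`, `G`, `T`, `N`.
#' @examples
#' baseCounts("AACGT")
#' @export
baseCounts <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty string")
  seq <- .normSeq(seq, what = "seq")
  fr <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  out <- fr[c("A", "C", "G", "T", "N")]
  storage.mode(out) <- "integer"
  out
}

#' Strand skew statistic
#'
#' `skew(x, y) = (x - y) / (x + y)`, the classic AT / GC strand-asymmetry
#' measure: `skew(A, T)` gives the AT skew, `skew(G, C)` the GC skew. Always
#' in `[-1, 1]`; antisymmetric in its arguments. A zero denominator yields
#' `NaN` with a warning.
#'
#' @param x,y non-negative counts (or percentages; the statistic is scale
#'   invariant).
#' @return dimensionless numeric.
#' @examples
#' skew(50, 50)        # 0
#' skew(29.46, 33.09)  # AT skew of an A+T-rich control region
#' @export
skew <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- x + y
  if (any(tot == 0)) warning("skew undefined when both counts are zero")
  (x - y) / tot
}

.compositionRow <- function(region, counts, size) {
  acgt <- sum(counts[c("A", "C", "G", "T")])
  data.frame(
    region = region, size = size,
    pct_A = 100 * counts[["A"]] / acgt, pct_T = 100 * counts[["T"]] / acgt,
    pct_C = 100 * counts[["C"]] / acgt, pct_G = 100 * counts[["G"]] / acgt,
    at_content = 100 * (counts[["A"]] + counts[["T"]]) / acgt,
    at_skew = skew(counts[["A"]], counts[["T"]]),
    gc_skew = skew(counts[["G"]], counts[["C"]]),
    stringsAsFactors = FALSE)
}

#' Region-wise composition and skew table
#'
#' One row for the whole genome plus one per feature class (protein-coding
#' genes, tRNA, rRNA, control region). A class row is built from the
#' concatenation of its features' spans; by default the spans are taken on
#' the published heavy-strand reference in genome order, *without*
#' reverse-complementing light-strand features, which is the convention under
#' which whole-genome C content exceeds G content in fish mitogenomes.
#' Bases shared by overlapping features are counted once per feature, so a
#' class size is the plain sum of its feature sizes. N bases are excluded
#' from numerator and denominator of all percentages and skews.
#'
#' @param genome a [MitoGenome-class] with sequence.
#' @param coding_strand if `TRUE`, light-strand features are
#'   reverse-complemented before tallying (sensitivity analysis).
#' @return data.frame with columns `region`, `size`, `pct_A`, `pct_T`,
#'   `pct_C`, `pct_G`, `at_content`, `at_skew`, `gc_skew`. Values are
#'   unrounded; [runProfile()] rounds for reports (percentages 2 dp,
#'   skews 4 dp).
#' @export
regionComposition <- function(genome, coding_strand = FALSE) {
  seq <- genomeSequence(genome)
  if (is.null(seq)) stop("genome has no sequence attached")
  f <- features(genome)
  rows <- list(.compositionRow("whole", baseCounts(seq), genomeLength(genome)))
  for (cls in .FEATURE_TYPES) {
    idx <- which(f$type == cls)
    if (!length(idx)) {
      message("no features of class ", cls, "; row omitted")
      next
    }
    pieces <- vapply(idx, function(i) {
      s <- .spanSequence(seq, f$start[i], f$end[i], genomeLength(genome),
                         isCircular(genome))
      if (coding_strand && f$strand[i] == "L") s <- revComp(s) else s
    }, "")
    rows[[length(rows) + 1L]] <- .compositionRow(
      cls, baseCounts(paste(pieces, collapse = "")), sum(f$size[idx]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
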