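#' @importFrom methods new validObject is setValidity show
#' @importFrom stats runif rpois setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

# complement lookup shared by several modules; N maps to N
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x single nucleotide string over A, C, G, T, N.
#' @return the reverse complement as a character string.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so generators never leak global state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.splitCodons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# normalize a nucleotide string: upper case, U -> T; error on anything
# outside A/C/G/T/N unless `allow` extends the alphabet (e.g. "-")
.normSeq <- function(x, allow = character(0), what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(.splitChars(x)), c("A", "C", "G", "T", "N", allow))
  if (length(bad))
    stop(what, " contains characters outside the IUPAC set handled here: ",
         paste(bad, collapse = ", "))
  x
}
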