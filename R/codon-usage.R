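#' Infer initiation and termination codons of a mitochondrial CDS
#'
#' The initiation codon is the first three bases. The termination is the
#' final complete codon when the length is a multiple of three and that
#' codon is a stop under the genetic code; otherwise the trailing one- or
#' two-base remainder is reported as an incomplete stop (`"T"` or `"TA"`,
#' completed to TAA by polyadenylation in vivo). The encoded amino-acid
#' count is `(length - stop_length) / 3` - the initiation codon encodes the
#' first residue.
#'
#' @param cds nucleotide string in coding orientation, length >= 6.
#' @param code a [geneticCode()] object.
#' @return list with `initiation`, `termination`, `stop_length` (3, 2, 1, or
#'   0 when no termination was detected), `complete_stop` (logical) and
#'   `n_aa`.
#' @examples
#' inferInitTerm("ATGAAATAA")  # ATG / TAA, 2 amino acids
#' @export
inferInitTerm <- function(cds, code = geneticCode(2L)) {
  cds <- .normSeq(cds, what = "cds")
  len <- nchar(cds)
  if (len < 6L) stop("cds shorter than 6 bases")
  initiation <- substring(cds, 1L, 3L)
  rem <- len %% 3L
  if (rem == 0L) {
    last <- substring(cds, len - 2L, len)
    if (.isStop(last, code)) {
      termination <- last
      stop_length <- 3L
    } else {
      warning("no termination detected: final codon ", last, " is not a stop")
      termination <- NA_character_
      stop_length <- 0L
    }
  } else {
    tail <- substring(cds, len - rem + 1L, len)
    if (rem == 2L && tail != "TA")
      stop("two-base remainder '", tail, "' is not the incomplete stop 'TA'")
    if (rem == 1L && tail != "T")
      warning("one-base remainder '", tail, "' is not the usual incomplete stop 'T'")
    termination <- tail
    stop_length <- rem
  }
  list(initiation = initiation, termination = termination,
       stop_length = stop_length, complete_stop = stop_length == 3L,
       n_aa = (len - stop_length) %/% 3L)
}

#' CodonUsage: codon counts over a set of protein-coding genes
#'
#' Holds the 64-codon count vector for a CDS set, the genetic-code id, and
#' the gene count. Complete terminal stop codons are included in the counts
#' and in the frequency denominator; incomplete trailing bases contribute
#' nothing.
#'
#' @slot counts named integer vector over the 64 codons.
#' @slot code_id NCBI translation table number.
#' @slot n_genes number of genes tallied.
#' @aliases CodonUsage
#' @exportClass CodonUsage
setClass("CodonUsage",
  slots = c(counts = "integer", code_id = "integer", n_genes = "integer"))

setValidity("CodonUsage", function(object) {
  if (length(object@counts) != 64L || !setequal(names(object@counts), .CODONS))
    return("counts must be named over the 64 codons")
  if (any(object@counts < 0L)) return("negative codon count")
  TRUE
})

#' Count codons across a CDS set
#'
#' Each CDS is validated through [inferInitTerm()]; all complete codons are
#' tallied, including a complete terminal stop where present, and excluding
#' incomplete trailing bases. An internal (premature) stop codon is an
#' error naming the gene and codon index; codons containing non-ACGT
#' characters are skipped with a warning. Initiation codons are tallied as
#' their literal codon (a GTG start counts in the Val family).
#'
#' @param cds_set character vector / list of coding-orientation CDS, or a
#'   `Biostrings::DNAStringSet`; names are used in error messages.
#' @param code a [geneticCode()] object.
#' @return a [CodonUsage-class] object.
#' @examples
#' u <- countCodons(c(gene1 = "ATGTAA"))
#' codonCounts(u)[c("ATG", "TAA")]
#' @export
countCodons <- function(cds_set, code = geneticCode(2L)) {
  if (is(cds_set, "DNAStringSet")) cds_set <- as.character(cds_set)
  cds_set <- as.list(cds_set)
  ids <- names(cds_set)
  if (is.null(ids)) ids <- paste0("gene", seq_along(cds_set))
  counts <- setNames(integer(64L), .CODONS)
  for (k in seq_along(cds_set)) {
    cds <- .normSeq(as.character(cds_set[[k]]), what = ids[k])
    info <- inferInitTerm(cds, code)
    body <- substring(cds, 1L, nchar(cds) - (nchar(cds) %% 3L))
    codons <- .splitCodons(body)
    internal <- which(.isStop(codons, code))
    internal <- internal[internal < length(codons)]
    if (length(internal))
      stop("internal stop codon ", codons[internal[1L]], " in ", ids[k],
           " at codon ", internal[1L])
    if (!info$complete_stop && length(codons) &&
        .isStop(codons[length(codons)], code))
      stop("internal stop codon at end of unterminated ", ids[k])
    ok <- codons %in% .CODONS
    if (any(!ok))
      warning(sum(!ok), " codon(s) with non-ACGT characters skipped in ", ids[k])
    tab <- table(factor(codons[ok], levels = .CODONS))
    counts <- counts + as.integer(tab)
  }
  new("CodonUsage", counts = counts, code_id = code$id,
      n_genes = length(cds_set))
}

#' @describeIn CodonUsage raw 64-codon count vector.
#' @param x a `CodonUsage` object.
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))

#' @export
setMethod("codonCounts", "CodonUsage", function(x) x@counts)

#' @describeIn CodonUsage total counted codons (complete stops included).
#' @export
setGeneric("countedCodons", function(x) standardGeneric("countedCodons"))

#' @export
setMethod("countedCodons", "CodonUsage", function(x) sum(x@counts))

#' @describeIn CodonUsage encoded amino acids: counted codons minus counted
#'   complete stop codons.
#' @export
setGeneric("encodedAminoAcids", function(x) standardGeneric("encodedAminoAcids"))

#' @export
setMethod("encodedAminoAcids", "CodonUsage", function(x) {
  code <- geneticCode(x@code_id)
  sum(x@counts) - sum(x@counts[code$stops])
})

setMethod("show", "CodonUsage", function(object) {
  cat(sprintf("CodonUsage: %d codons over %d gene(s), code table %d\n",
              sum(object@counts), object@n_genes, object@code_id))
  cat(sprintf("  encoded amino acids: %d\n", encodedAminoAcids(object)))
  invisible(NULL)
})

#' Relative synonymous codon usage
#'
#' For codon `c` in synonymous family `F`:
#' `RSCU(c) = count(c) * |F| / sum(count(F))`. Families follow the genetic
#' code (under table 2: Leu and Ser have six members, Met and Trp two); the
#' four stop codons form their own 4-member family. A family with zero total
#' gets RSCU 0 for all members.
#'
#' @param counts a [CodonUsage-class] object or a named numeric vector of
#'   codon counts (absent codons count as 0).
#' @param code a [geneticCode()] object (taken from the object when `counts`
#'   is a `CodonUsage`).
#' @return named numeric vector of RSCU values over the 64 codons.
#' @examples
#' rscu(c(GCC = 161, GCA = 100, GCT = 67, GCG = 8))[c("GCC", "GCG")]
#' @export
rscu <- function(counts, code = geneticCode(2L)) {
  if (is(counts, "CodonUsage")) {
    code <- geneticCode(counts@code_id)
    counts <- counts@counts
  }
  full <- setNames(numeric(64L), .CODONS)
  full[names(counts)] <- counts
  out <- setNames(numeric(64L), .CODONS)
  for (fam in code$families) {
    tot <- sum(full[fam])
    out[fam] <- if (tot > 0) full[fam] * length(fam) / tot else 0
  }
  out
}

#' Per-amino-acid usage shares
#'
#' Family totals as percentages of all counted codons; the stop family is
#' reported as its own `Stp` row.
#'
#' @inheritParams rscu
#' @return data.frame with columns `amino_acid` (three-letter), `count`,
#'   `pct`, sorted by decreasing share.
#' @export
aminoAcidUsage <- function(counts, code = geneticCode(2L)) {
  if (is(counts, "CodonUsage")) {
    code <- geneticCode(counts@code_id)
    counts <- counts@counts
  }
  full <- setNames(numeric(64L), .CODONS)
  full[names(counts)] <- counts
  tot <- sum(full)
  fam_tot <- vapply(code$families, function(fam) sum(full[fam]), 0)
  out <- data.frame(amino_acid = unname(.AA3[names(code$families)]),
                    count = unname(fam_tot),
                    pct = unname(100 * fam_tot / tot),
                    stringsAsFactors = FALSE)
  out[order(-out$pct), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Codon usage report table
#'
#' The standard per-codon report: amino acid, codon, count, frequency as a
#' percentage of all counted codons, and RSCU.
#'
#' @param x a [CodonUsage-class] object.
#' @param digits rounding for the frequency and RSCU columns (default 2, as
#'   conventionally printed); `NULL` for unrounded values.
#' @return data.frame with columns `amino_acid`, `codon`, `count`,
#'   `frequency_pct`, `rscu`, grouped by amino acid with codons in
#'   decreasing count order.
#' @export
usageTable <- function(x, digits = 2L) {
  stopifnot(is(x, "CodonUsage"))
  code <- geneticCode(x@code_id)
  counts <- x@counts
  r <- rscu(x)
  tot <- sum(counts)
  rows <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    fam <- fam[order(-counts[fam])]
    data.frame(amino_acid = unname(.AA3[aa]), codon = fam,
               count = unname(counts[fam]),
               frequency_pct = unname(100 * counts[fam] / tot),
               rscu = unname(r[fam]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$amino_acid), , drop = FALSE]
  if (!is.null(digits)) {
    out$frequency_pct <- round(out$frequency_pct, digits)
    out$rscu <- round(out$rscu, digits)
  }
  rownames(out) <- NULL
  out
}
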