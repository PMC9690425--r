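#' Genetic code used for codon analyses
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()]) into
#' the structure the codon-usage and Ka/Ks code consumes: the 64-entry
#' codon-to-amino-acid map, the initiation-codon set, and the synonymous
#' families (codons grouped by encoded amino acid, with the stop codons
#' forming their own family).
#'
#' The default is table 2, the vertebrate mitochondrial code, under which
#' AGA/AGG are stops, ATA encodes Met and TGA encodes Trp, giving a 6-member
#' Leu family, a 6-member Ser family, 2-member Met and Trp families and the
#' 4-member stop family.
#'
#' @param id NCBI translation table number (default 2).
#' @return an object of class `GeneticCode`: a list with elements `id`,
#'   `codon_aa` (named character of length 64, `"*"` for stops), `starts`
#'   (initiation codons), `stops`, and `families` (list of codon vectors
#'   named by amino-acid letter, `"*"` for the stop family).
#' @examples
#' code <- geneticCode(2)
#' code$codon_aa[c("AGA", "ATA", "TGA")]
#' @export
geneticCode <- function(id = 2L) {
  tab <- Biostrings::getGeneticCode(as.character(id))
  starts <- unique(c("ATG", attr(tab, "alt_init_codons")))
  fam <- split(names(tab), unname(tab))
  out <- list(
    id = as.integer(id),
    codon_aa = setNames(as.character(tab), names(tab)),
    starts = starts,
    stops = names(tab)[tab == "*"],
    families = fam
  )
  class(out) <- "GeneticCode"
  out
}

#' @export
print.GeneticCode <- function(x, ...) {
  cat("Genetic code table", x$id, "-", length(x$stops), "stop codons (",
      paste(x$stops, collapse = " "), ");", length(x$starts),
      "initiation codons\n")
  invisible(x)
}

.aa <- function(codons, code) unname(code$codon_aa[codons])

.isStop <- function(codons, code) codons %in% code$stops

# three-letter amino-acid labels for report layouts; "*" prints as Stp
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Stp")

.CODONS <- as.vector(t(outer(
  as.vector(t(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0))),
  c("T", "C", "A", "G"), paste0)))
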