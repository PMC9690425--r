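#' Published annotation of the Arius maculatus mitogenome
#'
#' The 38-feature annotation (13 protein-coding genes, 22 tRNAs, 2 rRNAs and
#' the control region) of the spotted-catfish mitochondrial genome deposited
#' as GenBank MN604079, transcribed as a feature table and shipped with the
#' package. No sequence is attached; all coordinate-derived statistics
#' (sizes, amino-acid counts, boundary offsets) work without it.
#'
#' @return a [MitoGenome-class] of length 16,710 bp.
#' @examples
#' g <- ariusMaculatusAnnotation()
#' table(features(g)$type)
#' @export
ariusMaculatusAnnotation <- function() {
  readFeatureTable(system.file("extdata", "arius_maculatus_features.tsv",
                               package = "mitoprofile"))
}

#' Published codon counts of the Arius maculatus protein-coding genes
#'
#' The 64-codon count table of the 13 protein-coding genes of GenBank
#' MN604079 (3,801 codons: 3,792 encoding amino acids plus 9 complete stop
#' codons), together with the frequency and RSCU values as originally
#' printed, for cross-checking recomputations.
#'
#' @return data.frame with columns `amino_acid`, `codon`, `count`,
#'   `frequency_pct`, `rscu`.
#' @examples
#' counts <- ariusMaculatusCodonCounts()
#' sum(counts$count)  # 3801
#' @export
ariusMaculatusCodonCounts <- function() {
  read.delim(system.file("extdata", "arius_maculatus_codon_counts.tsv",
                         package = "mitoprofile"),
             stringsAsFactors = FALSE)
}
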