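# shared fixtures: the published annotation, its raw TSV (for the printed
# derived columns), and one generated genome reused across test files
ARIUS <- ariusMaculatusAnnotation()
ARIUS_TSV <- read.delim(system.file("extdata", "arius_maculatus_features.tsv",
                                    package = "mitoprofile"),
                        na.strings = c("NA", ""))
ARIUS_CODONS <- ariusMaculatusCodonCounts()
CODE2 <- geneticCode(2L)
STOPS2 <- c("TAA", "TAG", "AGA", "AGG")

SIM <- suppressMessages(generateGenome(genomeSpec(seed = 42L)))

# small helper: a linear toy genome from a compact spec
toyGenome <- function(starts, ends, strands = "H", types = "PCG",
                      sequence = NULL, circular = FALSE, ...) {
  n <- length(starts)
  MitoGenome(data.frame(name = paste0("g", seq_len(n)), type = types,
                        start = starts, end = ends, strand = strands,
                        stringsAsFactors = FALSE),
             sequence = sequence, circular = circular, ...)
}
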