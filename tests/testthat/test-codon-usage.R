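test_that("the vertebrate mitochondrial code has its defining reassignments", {
  expect_equal(unname(CODE2$codon_aa[c("AGA", "AGG", "ATA", "TGA")]),
               c("*", "*", "M", "W"))
  expect_setequal(CODE2$stops, STOPS2)
  # synonymous families partition the 64 codons
  expect_equal(sort(unlist(CODE2$families, use.names = FALSE)),
               sort(mitoprofile:::.CODONS))
  expect_equal(sum(lengths(CODE2$families)), 64L)
  expect_equal(lengths(CODE2$families)[c("L", "S", "M", "W", "*")],
               c(L = 6L, S = 6L, M = 2L, W = 2L, `*` = 4L))
})

test_that("initiation/termination inference handles complete and incomplete stops", {
  r <- inferInitTerm("ATGAAATAA")
  expect_equal(r$initiation, "ATG")
  expect_equal(r$termination, "TAA")
  expect_equal(r$n_aa, 2L)

  # 691-bp CDS ending in a bare T after 230 complete codons
  cds <- paste0("ATG", strrep("GCC", 229), "T")
  r <- inferInitTerm(cds)
  expect_equal(nchar(cds), 691L)
  expect_equal(r$termination, "T")
  expect_false(r$complete_stop)
  expect_equal(r$n_aa, 230L)

  # 1381-bp ND4-like CDS: incomplete T, 460 residues
  cds <- paste0("ATG", strrep("CTA", 459), "T")
  expect_equal(nchar(cds), 1381L)
  expect_equal(inferInitTerm(cds)$n_aa, 460L)

  expect_error(inferInitTerm("ATG"), "shorter")
  expect_error(inferInitTerm(paste0("ATGAAACCC", "GG")), "TA")
  expect_warning(r <- inferInitTerm("ATGAAACCC"), "no termination")
  expect_true(is.na(r$termination))
  expect_equal(r$n_aa, 3L)
})

test_that("amino-acid accounting reproduces the published per-gene counts", {
  f <- features(ARIUS)
  p <- f[f$type == "PCG", ]
  stop_len <- ifelse(p$term_codon %in% STOPS2, 3L, nchar(p$term_codon))
  n_aa <- (p$size - stop_len) %/% 3L
  printed <- ARIUS_TSV[order(ARIUS_TSV$from), ]
  printed <- printed$n_aa[printed$type == "PCG"]
  expect_equal(n_aa, printed)
  expect_equal(sum(n_aa), 3792L)
})

test_that("codon counting includes complete stops and flags internal ones", {
  u <- countCodons(c(gene1 = "ATGTAA"))
  expect_equal(codonCounts(u)[["ATG"]], 1L)
  expect_equal(codonCounts(u)[["TAA"]], 1L)
  expect_equal(countedCodons(u), 2L)
  expect_equal(encodedAminoAcids(u), 1L)
  expect_error(countCodons(c(bad = "ATGTAAGCCTAA")), "internal stop.*codon 2")
  expect_warning(countCodons(c(gap = "ATGNNNGCCTAA")), "skipped")
})

test_that("codon usage is invariant to gene order and matches ground truth", {
  cds <- featureSequences(SIM$genome, "PCG")
  u1 <- countCodons(cds)
  u2 <- countCodons(rev(cds))
  expect_identical(codonCounts(u1), codonCounts(u2))
  expect_identical(codonCounts(u1), SIM$truth$codon_counts)
  # encoded amino acids = counted codons minus counted complete stops
  expect_equal(encodedAminoAcids(u1),
               countedCodons(u1) - sum(codonCounts(u1)[STOPS2]))
})

test_that("RSCU matches its definition on published family counts", {
  # alanine family, printed at 2 dp
  r <- rscu(c(GCC = 161, GCA = 100, GCT = 67, GCG = 8))
  expect_equal(round(unname(r[c("GCC", "GCA", "GCT", "GCG")]), 2),
               c(1.92, 1.19, 0.80, 0.10))
  # stop family is a 4-member family
  r <- rscu(c(TAA = 6, TAG = 3, AGA = 0, AGG = 0))
  expect_equal(round(unname(r[STOPS2]), 2), c(2.67, 1.33, 0.00, 0.00))
  # uniform counts in any family give RSCU 1
  r <- rscu(setNames(rep(5, 64), mitoprofile:::.CODONS))
  expect_true(all(abs(r - 1) < 1e-12))
  # zero-total family yields zeros
  expect_true(all(rscu(c(GCC = 10))[c("TTT", "TTC")] == 0))
})

test_that("recomputed RSCU and frequencies reproduce every published cell", {
  counts <- setNames(ARIUS_CODONS$count, ARIUS_CODONS$codon)
  expect_equal(sum(counts), 3801L)
  r <- rscu(counts)
  expect_equal(round(unname(r[ARIUS_CODONS$codon]), 2), ARIUS_CODONS$rscu)
  freq <- 100 * counts / sum(counts)
  expect_equal(round(unname(freq[ARIUS_CODONS$codon]), 2),
               ARIUS_CODONS$frequency_pct)
  # family RSCU sums equal family size whenever the family is used
  for (fam in CODE2$families) {
    full <- setNames(numeric(64), mitoprofile:::.CODONS)
    full[names(counts)] <- counts
    if (sum(full[fam]) > 0) expect_equal(sum(r[fam]), length(fam))
  }
})

test_that("amino-acid shares reproduce the published summary values", {
  counts <- setNames(ARIUS_CODONS$count, ARIUS_CODONS$codon)
  au <- aminoAcidUsage(counts)
  share <- function(aa) au$pct[au$amino_acid == aa]
  expect_equal(round(share("Leu"), 1), 17.1)
  expect_equal(round(share("Ala"), 2), 8.84)
  # printed as 8.07: truncated, not rounded, so compare at printed precision
  expect_lt(abs(share("Ile") - 8.07), 0.01)
  expect_equal(round(share("Thr"), 2), 7.68)
  expect_equal(round(share("Cys"), 2), 0.71)
  u <- countCodons(c(g = "ATGTAA"))
  au <- aminoAcidUsage(u)
  expect_equal(au$pct[au$amino_acid %in% c("Met", "Stp")], c(50, 50))
})

test_that("usage table is internally consistent", {
  u <- countCodons(featureSequences(SIM$genome, "PCG"))
  tab <- usageTable(u, digits = NULL)
  expect_equal(nrow(tab), 64L)
  expect_equal(sum(tab$count), countedCodons(u))
  expect_equal(sum(tab$frequency_pct), 100)
  expect_identical(setNames(tab$rscu, tab$codon)[names(rscu(u))], rscu(u))
})
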