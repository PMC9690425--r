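test_that("site counts for benchmark codons match hand enumeration", {
  # GCC: fourfold-degenerate third position
  expect_equal(ng86SiteCounts("GCC"), c(s = 1, n = 2))
  # TGG: TGA is Trp under the mitochondrial code, so position 3 is partly
  # synonymous
  s <- ng86SiteCounts("TGG")
  expect_gt(s[["s"]], 0)
  expect_error(ng86SiteCounts("TAA"), "stop")
  expect_error(ng86SiteCounts("GCN"), "ambiguous")
})

test_that("site counts agree with the brute-force oracle on all sense codons", {
  for (codon in SENSE_CODONS) {
    expect_equal(ng86SiteCounts(codon, exclude_stops = TRUE),
                 oracleSiteCounts(codon, exclude_stops = TRUE),
                 tolerance = 1e-12, label = codon)
    expect_equal(ng86SiteCounts(codon, exclude_stops = FALSE),
                 oracleSiteCounts(codon, exclude_stops = FALSE),
                 tolerance = 1e-12, label = codon)
    # each codon contributes exactly three sites
    expect_equal(sum(ng86SiteCounts(codon)), 3)
  }
})

test_that("pairwise distances behave on identical and single-change pairs", {
  a <- strrep("GCC", 11)
  r <- ng86Pairwise(a, a)
  expect_equal(c(r$Ka, r$Ks, r$Sd, r$Nd), c(0, 0, 0, 0))
  expect_true(is.na(r$ratio))
  expect_equal(r$selection, "undefined")

  # one synonymous change among 11 alanine codons
  b <- paste0(strrep("GCC", 10), "GCT")
  r <- ng86Pairwise(a, b)
  expect_equal(c(r$Sd, r$Nd), c(1, 0))
  expect_equal(r$S, 11) # every GCC/GCT contributes s = 1
  expect_equal(r$Ks, -0.75 * log(1 - 4 * (1 / 11) / 3))
  expect_equal(r$Ka, 0)
  expect_equal(r$ratio, 0)
  expect_equal(r$selection, "purifying")
})

test_that("multi-position codon differences average over permissible pathways", {
  set.seed(21)
  pairs <- list()
  while (length(pairs) < 40) {
    ca <- sample(SENSE_CODONS, 1)
    cb <- sample(SENSE_CODONS, 1)
    if (sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]]) >= 2)
      pairs[[length(pairs) + 1]] <- c(ca, cb)
  }
  for (p in pairs) {
    got <- mitoprofile:::.pathwayDiffs(p[1], p[2], CODE2, exclude_stops = TRUE)
    want <- oraclePathwayDiffs(p[1], p[2])
    expect_equal(unname(got[c("sd", "nd")]), unname(want[c("sd", "nd")]),
                 tolerance = 1e-12, label = paste(p, collapse = "->"))
  }
  # the worked two-position example embedded in a toy gene
  ctx <- strrep("ATG", 5)
  r <- ng86Pairwise(paste0(ctx, "TTT"), paste0(ctx, "GTA"), CODE2)
  want <- oraclePathwayDiffs("TTT", "GTA")
  expect_equal(c(r$Sd, r$Nd), unname(want[c("sd", "nd")]))
})

test_that("pairwise estimates are symmetric in their arguments", {
  set.seed(31)
  anc <- paste(sample(SENSE_CODONS, 200, replace = TRUE), collapse = "")
  der <- evolvePair(anc, omega = 0.5, t = 0.5, seed = 8)
  r1 <- ng86Pairwise(anc, der)
  r2 <- ng86Pairwise(der, anc)
  for (fld in c("S", "N", "Sd", "Nd", "Ka", "Ks", "ratio"))
    expect_equal(r1[[fld]], r2[[fld]], label = fld)
})

test_that("gap codons are dropped pairwise and stops rejected", {
  a <- "ATGGCC---CTA"
  b <- "ATGGCTAAACTA"
  r <- ng86Pairwise(a, b)
  expect_equal(r$n_codons, 3L)
  expect_equal(r$n_dropped, 1L)
  expect_error(ng86Pairwise("ATGTAAGCC", "ATGTAAGCC"), "stop")
  expect_error(ng86Pairwise("ATGGCC", "ATGGC"), "equal length")
})

test_that("the Jukes-Cantor correction expands proportions monotonically", {
  p <- seq(0, 0.74, by = 0.02)
  d <- mitoprofile:::.jc(p)
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1])) # correction only inflates
  expect_true(is.na(mitoprofile:::.jc(0.75)))
})

test_that("selection classes follow the ratio thresholds", {
  expect_equal(classifySelection(c(0.1747, 1.672, 1, 1 + 1e-12, NA)),
               c("purifying", "positive", "neutral", "neutral", "undefined"))
})

test_that("the pairwise grid covers all pairs and skips missing genes", {
  set.seed(41)
  genes <- paste0("gene", 1:3)
  anc <- setNames(lapply(1:3, function(i)
    paste(sample(SENSE_CODONS, 150, replace = TRUE), collapse = "")), genes)
  cds_sets <- list()
  for (sp in c("A", "B", "C")) {
    cds_sets[[sp]] <- lapply(anc, evolvePair, omega = 0.2, t = 0.4,
                             seed = match(sp, c("A", "B", "C")))
  }
  cds_sets$C$gene3 <- NULL
  res <- suppressMessages(kaksMatrix(cds_sets))
  # gene3 lacks species C, so both pairs involving C skip it: 9 - 2 cells
  expect_equal(nrow(res$results), 7L)
  expect_true(all(res$results$selection %in%
                  c("purifying", "neutral", "positive", "undefined")))
  expect_true(res$mean_ratio < 1) # strong purifying regime

  # identical species: all ratios undefined
  twin <- list(x = anc, y = anc)
  res <- kaksMatrix(twin)
  expect_true(all(is.na(res$results$ratio)))
  expect_true(all(res$results$selection == "undefined"))
  expect_true(is.na(res$mean_ratio))
})
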