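test_that("the published annotation parses to the expected genome structure", {
  f <- features(ARIUS)
  expect_equal(genomeLength(ARIUS), 16710L)
  expect_true(isCircular(ARIUS))
  expect_equal(unname(table(factor(f$type, levels = c("PCG", "tRNA", "rRNA",
                                                      "control_region")))),
               c(13L, 22L, 2L, 1L), ignore_attr = TRUE)
  # duplicated Ser/Leu tRNAs disambiguated by anticodon
  expect_true(all(c("tRNA-Ser(TGA)", "tRNA-Ser(GCT)", "tRNA-Leu(TAA)",
                    "tRNA-Leu(TAG)") %in% f$name))
  expect_false(anyDuplicated(f$name) > 0)
  # sizes recomputed from coordinates match the printed size column
  expect_equal(f$size, ARIUS_TSV$size[order(ARIUS_TSV$from)])
})

test_that("feature-table parsing validates its input", {
  expect_error(readFeatureTable("name\ttype\tfrom\tto\tstrand\n"), "no features")
  expect_error(readFeatureTable("name\ttype\tfrom\tto\ngeneX\tPCG\t1\t300\n"),
               "strand")
  expect_error(
    readFeatureTable("name\ttype\tfrom\tto\tstrand\ngeneX\tPCG\tone\t300\tH\n"),
    "non-numeric")
  expect_error(
    readFeatureTable(paste0("name\ttype\tfrom\tto\tstrand\tsize\n",
                            "geneX\tPCG\t1\t300\tH\t299\n")),
    "geneX")
  g <- readFeatureTable("name\ttype\tfrom\tto\tstrand\ngeneX\tPCG\t1\t300\tH\n")
  expect_equal(features(g)$size, 300L)
  expect_equal(genomeLength(g), 300L)
})

test_that("features are sorted by start regardless of input order", {
  txt <- paste("name\ttype\tfrom\tto\tstrand",
               "b\tPCG\t201\t400\tH", "a\tPCG\t1\t200\tH", sep = "\n")
  g <- readFeatureTable(txt)
  expect_equal(features(g)$name, c("a", "b"))
})

test_that("GenBank locations map to strands and wrapping features", {
  gb <- c("LOCUS       toy 6000 bp    DNA     circular   UNA",
          "FEATURES             Location/Qualifiers",
          "     source          1..6000",
          "     tRNA            complement(5157..5225)",
          '                     /gene="tRNA-Ala"',
          '                     /anticodon="TGC"',
          "     CDS             join(5500..6000,1..50)",
          '                     /gene="wrapper"',
          "//")
  g <- readGenBank(gb)
  f <- features(g)
  ala <- f[f$name == "tRNA-Ala", ]
  expect_equal(ala$strand, "L")
  expect_equal(c(ala$start, ala$end), c(5157L, 5225L))
  wrap <- f[f$name == "wrapper", ]
  expect_equal(c(wrap$start, wrap$end), c(5500L, 50L))
  expect_equal(wrap$size, 6000L - 5500L + 1L + 50L)
})

test_that("GenBank output round-trips generated genomes exactly", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(SIM$genome, path)
  back <- suppressMessages(readGenBank(path))
  expect_identical(features(back), features(SIM$genome))
  expect_identical(genomeSequence(back), genomeSequence(SIM$genome))
  expect_identical(isCircular(back), TRUE)

  # and the TSV dialect round-trips the annotation
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(SIM$genome, tsv)
  back2 <- readFeatureTable(tsv, genome_length = genomeLength(SIM$genome))
  expect_identical(features(back2), features(SIM$genome))
})

test_that("feature sequences come back in coding orientation", {
  g <- toyGenome(c(1, 4), c(3, 6), strands = c("H", "L"), sequence = "AAACCC")
  expect_equal(featureSequence(g, "g1"), "AAA")
  expect_equal(featureSequence(g, "g2"), "GGG")
  # wrapping feature on a circular toy: positions 5,6,1,2 of ACGTAC
  gw <- toyGenome(5, 2, sequence = "ACGTAC", circular = TRUE)
  expect_equal(featureSequence(gw, "g1"), "ACAC")
  expect_error(featureSequence(toyGenome(1, 3), "g1"), "no sequence")
})

test_that("extracted feature length equals feature size on both strands", {
  f <- features(SIM$genome)
  for (i in seq_len(nrow(f)))
    expect_equal(nchar(featureSequence(SIM$genome, i)), f$size[i])
})

test_that("boundary offsets reproduce the printed intergenic column", {
  off <- boundaryOffsets(ARIUS)
  f <- features(ARIUS)
  # printed column attributes each offset to the upstream row
  printed <- ARIUS_TSV$intergenic[order(ARIUS_TSV$from)]
  expect_equal(off$offset[match(f$name, off$upstream)], printed)
  expect_equal(off$offset[off$upstream == "ATP8"], -10L)
  expect_equal(off$offset[off$upstream == "tRNA-Asn"], 31L)
})

test_that("boundary offsets handle abutting genes and circular closure", {
  g <- toyGenome(c(1, 101), c(100, 200))
  expect_equal(boundaryOffsets(g)$offset, 0L)
  gc <- toyGenome(c(1, 101), c(100, 190), circular = TRUE, genome_length = 200)
  off <- boundaryOffsets(gc)
  expect_equal(off$offset, c(0L, 10L)) # closing spacer wraps to the start
})

test_that("sizes, offsets and genome length satisfy tiling closure", {
  # synthetic tiling genomes: sum(sizes) + sum(offsets) == genome length
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    sizes <- sample(60:900, n, replace = TRUE)
    offs <- sample(c(-10:-1, 0, 1:30), n, replace = TRUE)
    offs[n] <- max(0L, offs[n])
    starts <- ends <- integer(n)
    starts[1] <- 1L
    for (i in seq_len(n)) {
      ends[i] <- starts[i] + sizes[i] - 1L
      if (i < n) starts[i + 1] <- ends[i] + 1L + offs[i]
    }
    L <- ends[n] + offs[n]
    g <- toyGenome(starts, ends, circular = TRUE, genome_length = L)
    expect_equal(sum(features(g)$size) + sum(boundaryOffsets(g)$offset), L)
  }
  f <- features(ARIUS)
  expect_equal(sum(f$size) + sum(boundaryOffsets(ARIUS)$offset), 16710L)
})
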