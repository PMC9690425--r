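---
title: "Profiling annotated mitochondrial genomes with mitoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling annotated mitochondrial genomes with mitoprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## What the package computes

A newly sequenced vertebrate mitogenome is conventionally characterized by a
small, standard battery of statistics: base composition and strand skew per
region class, codon usage and relative synonymous codon usage (RSCU) of the
13 protein-coding genes (PCGs), initiation and termination codons (including
the incomplete `T`/`TA` stops completed by polyadenylation), the overlaps and
intergenic spacers between adjacent genes, and a pairwise Ka/Ks screen for
selection across related species. mitoprofile implements this battery as
reusable, tested functions over an explicit annotation container, the S4
class `MitoGenome`, plus a seeded generator of synthetic mitogenomes so that
every stage can be validated against known ground truth without downloading
any accession.

The package ships the published annotation of the spotted-catfish
(*Arius maculatus*) mitogenome (GenBank MN604079) as a worked reference: a
16,710-bp circular molecule with 13 PCGs, 22 tRNAs, 2 rRNAs and one control
region.

## Coordinates, strands, and the annotation model

All coordinates are 1-based inclusive, as in GenBank and in published
annotation tables; no 0-based convention ever appears at an interface. A
feature with `end < start` wraps the origin of a circular genome; its size is
`genome_length - start + 1 + end`. In GenBank output a wrapping feature is
written as `join(start..L, 1..end)`, and light-strand (L) features as
`complement(...)`. The duplicated tRNA-Ser and tRNA-Leu names are
disambiguated by appending the anticodon (`tRNA-Ser(TGA)`), which keeps
feature names unique without inventing labels.

Boundary offsets are defined as `next_start - current_end - 1` and attributed
to the *upstream* feature, matching the convention of published per-gene
tables (the row for tRNA-Leu carries the 1-bp gap before ND1). Offsets of
zero — abutting genes — count as neither overlap nor spacer, which is why the
overlap and spacer tallies of a 38-feature genome need not sum to 38.

## Composition and skew

AT skew is `(A - T)/(A + T)` and GC skew `(G - C)/(G + C)`. Region rows
(whole genome, PCG, tRNA, rRNA, control region) are computed from the
concatenation of the class's feature spans **on the published heavy-strand
reference, without reverse-complementing L-strand features**. This is the
convention under which the whole-genome figures of fish mitogenomes show
C far in excess of G (strongly negative GC skew), and it makes the class rows
directly comparable to the whole-genome row. A `coding_strand = TRUE` flag
exposes the alternative convention for sensitivity analysis. Bases shared by
overlapping genes are counted once per feature, so the PCG class size is the
plain sum of gene sizes (11,407 bp for the reference annotation) rather than
the smaller non-redundant span. N bases are excluded from both numerator and
denominator. Internally nothing is rounded; report writers round percentages
to 2 decimals and skews to 4, the precision at which such tables are
conventionally printed.

## Codon usage under translation table 2

The genetic code is NCBI table 2 (vertebrate mitochondrial) by default:
AGA/AGG are stops, ATA is Met, TGA is Trp, giving 6-member Leu and Ser
families and 2-member Met and Trp families. Only under this table do the
reference RSCU values reproduce (e.g. TCC = 86 x 6 / 232 = 2.22 requires the
6-member Ser family).

Three counting conventions matter and are fixed as follows:

* **Complete terminal stop codons are counted** in the codon totals and in
  the frequency denominator; incomplete `T`/`TA` terminators contribute
  nothing. For the reference PCG set this gives 3,801 counted codons = 3,792
  encoded amino acids + 9 complete stops, and it is the only convention that
  reproduces the printed frequencies (CTA: 274/3801 = 7.21%; 274/3792 would
  print 7.23%).
* **Initiation codons are tallied literally**: a GTG start (COXI) counts in
  the Val family, with no formyl-Met re-coding, because the published usage
  table shows GTG inside the Val family.
* **The stop "family" has four members** (TAA, TAG, AGA, AGG) for RSCU even
  though AGA/AGG may never occur.

RSCU of codon *c* in family *F* is `count(c) * |F| / sum(count(F))`; a family
with zero total yields zeros. Amino-acid counts follow the stop model:
`(length - stop_length)/3`, so a 691-bp gene ending in a bare `T` encodes 230
residues.

## Boundary accounting

`summarizeBoundaries()` classifies the offsets of `boundaryOffsets()`:
negative = overlap, positive = spacer, zero = neither. The closing boundary
of a circular genome (last feature back to the first) is included. Gene-order
comparison is rotation-invariant on circular genomes, since the choice of
origin is arbitrary; a strand flip shows up as a divergence at that gene.

## Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction

The selection screen reimplements the classic Nei-Gojobori (1986) counting
estimator rather than delegating to an external program, because the package
must run self-contained and the choice of convention must be explicit:

* **Site counting.** Each codon position contributes one site, split by the
  fraction of single-base changes preserving the amino acid. By default,
  changes creating a stop codon are excluded and the remaining fractions
  renormalized so each position still contributes exactly one site
  (`s + n = 3` always). A strict mode without stop exclusion is available
  behind `exclude_stops = FALSE`, since published pipelines differ on this
  point.
* **Pathway averaging.** Codon pairs differing at 2-3 positions average the
  synonymous/nonsynonymous step counts over all orderings of the changes
  that avoid stop intermediates (falling back to all orderings when none
  do), with equal weights.
* **Correction.** `ps = Sd/S` and `pn = Nd/N` are corrected by Jukes-Cantor,
  `d = -3/4 log(1 - 4p/3)`, undefined at `p >= 3/4`.
* **Classification.** Ka/Ks below 1 is purifying, above 1 positive, equal to
  1 (tolerance 1e-9) neutral; `Ks = 0` leaves the ratio undefined rather
  than infinite, and grid averaging skips undefined cells.

Terminal stop signals (complete or incomplete) are trimmed before analysis;
alignments must be codon-aligned, and codon pairs containing gaps are dropped
pairwise. Building the alignments themselves (e.g. with MUSCLE or MAFFT) is
out of scope — ungapped equal-length inputs are accepted directly.

## The synthetic mitogenome generator

`generateGenome()` turns a `genomeSpec()` into a fully sequenced, annotated
circular genome plus exact ground truth. The default spec *is* the reference
architecture: the canonical 37-gene vertebrate order plus control region with
the published lengths and boundary offsets (including the 10-bp ATP8/ATP6
overlap and the 31-bp tRNA-Asn/tRNA-Cys spacer, totalling 9 overlaps and 12
spacers of 66 bp), PCG codon bias drawn from the published 64-codon count
table, whole-genome base composition A/T/C/G = 29.63/25.42/29.65/15.30% for
RNA genes and spacers, and the A+T-rich published control-region composition
(A+T = 62.55%). The control-region target is specified as a full composition
vector rather than a single A+T percentage because the reference control
region also has strongly negative AT and GC skews that a scalar target could
not encode.

Protein-coding genes are built codon by codon on the coding strand: the
initiation codon first (ATG everywhere except GTG at the COXI slot), sense
codons sampled from the bias, and a terminator per the stop model (complete
stop for lengths divisible by three, trailing `T`/`TA` otherwise). Overlap
bases belong to the feature generated first; downstream codons falling on
already-written positions are sampled under those fixed-base constraints,
avoiding stops wherever any base is free. When constraints are unsatisfiable
— a fully fixed codon forced to a stop, or the antiparallel ND5/ND6 junction
demanding a base that was sampled otherwise — the whole genome is resampled
within the same seeded stream, so generation is deterministic per seed (a
few attempts typically suffice). Where a constraint overrides the template's
initiation or termination codon (ATP6 and ND4, whose starts sit inside the
upstream gene), the annotation records the codon actually generated; true
dual coding of overlaps is approximated, not enforced, a documented
limitation. All randomness flows through one seeded stream with the caller's
RNG state saved and restored.

Ground truth is tallied *during* generation — codon counts from the sampled
codons, base counts from the placed characters — so the test suite can
require the composition and codon-usage modules to reproduce it bit-exactly,
not merely approximately.

What the generator does not emulate: realistic tRNA/rRNA secondary
structure, within-genome rate heterogeneity, and phylogenetically correlated
multi-species evolution. Passing tests on generated genomes therefore
validate the *accounting* (coordinates, orientation, counting conventions,
estimator algebra), not biological realism of the sequence itself.

## The divergence simulator and estimator validation

`evolvePair()` evolves a coding sequence under a known dN/dS target `omega`:
substitution attempts arrive as a Poisson process with expected `t` attempts
per codon; each attempt picks a uniform codon position and a uniform
alternative base *among those not creating a stop*, then accepts the change
with relative rate `omega` for nonsynonymous versus 1 for synonymous
changes. Sampling among non-stop alternatives (rather than rejecting stop
proposals outright) makes the expected synonymous and nonsynonymous event
counts proportional to the stop-renormalized NG86 site counts, so the
estimator can recover `omega` without a systematic offset.

The validation battery (run routinely by the test suite) uses 500-codon
genes at `t = 0.7` attempts per codon — chosen to keep the synonymous
difference proportion below 0.3, comfortably inside the Jukes-Cantor range,
while leaving enough events for stable estimates — and 100 replicates per
setting: recovery of omega in {0.1, 0.2, 0.5} within ±25% relative error,
and a neutral run whose mean ratio must lie within three standard errors
of 1. A small positive bias of order 1-2% is expected for a ratio of noisy
estimates (Jensen's inequality) and stays well inside that band at these
settings. Site counts are additionally checked codon-by-codon against a
brute-force neighbor enumerator built on an unrelated translation engine.

## Numerical and degenerate-input choices

* `skew(0, 0)` is NaN with a warning, not an error.
* A final complete codon that is not a stop is flagged ("no termination
  detected") and the gene treated as all-sense; a two-base remainder other
  than `TA` is an error, since no polyadenylation could complete it to a
  stop.
* Internal stop codons abort codon counting with the gene and codon index
  named; codons containing N are skipped with a warning.
* An annotation whose `size` column disagrees with its coordinates is
  rejected with the offending row named; unsorted feature tables are sorted
  on construction.
* Reports are plain TSV with a two-line provenance header and no timestamps,
  so identical inputs yield byte-identical files.

## Worked example

```{r example, eval = FALSE}
g <- ariusMaculatusAnnotation()
summarizeBoundaries(g)
#> 9 overlaps (max 10 bp, total 30 bp); 12 spacers (max 31 bp, total 66 bp)

counts <- ariusMaculatusCodonCounts()
round(rscu(setNames(counts$count, counts$codon))[c("CTA", "TCC", "TAA")], 2)
#>  CTA  TCC  TAA
#> 2.53 2.22 2.67

sim <- generateGenome(genomeSpec(seed = 42))
identical(codonCounts(countCodons(featureSequences(sim$genome, "PCG"))),
          sim$truth$codon_counts)
#> TRUE
```

## Known limitations

* The GenBank reader covers the flat-file subset a mitogenome record uses
  (CDS/tRNA/rRNA/D-loop, complement/join locations); it is not a general
  GenBank parser.
* Cross-species composition tables and the published Ka/Ks figures for the
  four Ariidae mitogenomes require the external accessions and are therefore
  validated by simulation properties, not by number matching.
* NG86 with equal pathway weighting is the implemented estimator; maximum
  likelihood codon models are out of scope.
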