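#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Following Nei & Gojobori (1986), each codon position contributes one
#' site, split between synonymous and nonsynonymous according to the
#' fraction of single-base changes at that position that preserve the
#' amino acid. With `exclude_stops = TRUE` (the default) changes that create
#' a stop codon are removed from consideration and the remaining fractions
#' are renormalized so the position still contributes exactly one site;
#' with `exclude_stops = FALSE` (strict original counting) changes to stops
#' count as nonsynonymous. Either way `s + n = 3`.
#'
#' @param codon a sense codon (3 bases).
#' @param code a [geneticCode()] object.
#' @param exclude_stops see above.
#' @return named numeric `c(s = ..., n = ...)`.
#' @examples
#' ng86SiteCounts("GCC")  # fourfold-degenerate third position: s = 1
#' @export
ng86SiteCounts <- function(codon, code = geneticCode(2L),
                           exclude_stops = TRUE) {
  codon <- .normSeq(codon, what = "codon")
  if (nchar(codon) != 3L) stop("codon must have 3 bases")
  if (grepl("N", codon, fixed = TRUE)) stop("ambiguous base in codon")
  if (.isStop(codon, code)) stop("stop codon has no NG86 site counts")
  st <- .siteTable(code, exclude_stops)
  c(s = st[codon, "s"], n = st[codon, "n"])
}

# 64 x 2 lookup of per-codon site counts, cached per code/mode
.siteCache <- new.env(parent = emptyenv())

.siteTable <- function(code, exclude_stops) {
  key <- paste0(code$id, if (exclude_stops) "x" else "-")
  if (!is.null(.siteCache[[key]])) return(.siteCache[[key]])
  bases <- c("A", "C", "G", "T")
  st <- matrix(NA_real_, 64L, 2L, dimnames = list(.CODONS, c("s", "n")))
  for (codon in .CODONS) {
    if (.isStop(codon, code)) next
    ch <- .splitChars(codon)
    s <- 0
    for (p in 1:3) {
      alt <- vapply(setdiff(bases, ch[p]), function(b) {
        x <- ch; x[p] <- b; paste(x, collapse = "")
      }, "")
      if (exclude_stops) {
        alt_keep <- alt[!.isStop(alt, code)]
        s <- s + if (length(alt_keep))
          mean(.aa(alt_keep, code) == .aa(codon, code)) else 0
      } else {
        s <- s + mean(!.isStop(alt, code) & .aa(alt, code) == .aa(codon, code))
      }
    }
    st[codon, ] <- c(s, 3 - s)
  }
  .siteCache[[key]] <- st
  st
}

# average synonymous/nonsynonymous differences between two sense codons over
# all mutational pathways (orderings of the differing positions), excluding
# pathways through stop codons when possible
.pathwayDiffs <- function(ca, cb, code, exclude_stops = TRUE) {
  pos <- which(.splitChars(ca) != .splitChars(cb))
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(pos),
                  list(pos, pos[2:1]),
                  list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                       pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
  res <- lapply(perms, function(ord) {
    cur <- .splitChars(ca)
    tgt <- .splitChars(cb)
    sd <- nd <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- tgt[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (.isStop(c2, code)) ok <- FALSE
      if (!ok && exclude_stops) return(NULL)
      if (!.isStop(c2, code) && !.isStop(c1, code) &&
          .aa(c1, code) == .aa(c2, code)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) # every pathway passes a stop: fall back to all pathways
    return(.pathwayDiffs(ca, cb, code, exclude_stops = FALSE))
  colMeans(do.call(rbind, res))
}

.jc <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by the Nei-Gojobori method with Jukes-Cantor correction
#'
#' Inputs must be codon-aligned sequences of equal length (a multiple of
#' three) in coding orientation with terminal stops already trimmed (see
#' [trimTerminalStop()]). Codon pairs in which either codon contains a
#' non-ACGT character (alignment gaps, ambiguity codes) are dropped
#' pairwise. Synonymous (S) and nonsynonymous (N) site totals are averaged
#' over the two sequences; codons differing at more than one position are
#' resolved by unweighted averaging over all mutational pathways that avoid
#' stop codons (all pathways if none avoid them). Proportions `ps = Sd/S`
#' and `pn = Nd/N` are Jukes-Cantor corrected,
#' `d = -3/4 log(1 - 4p/3)`, to give Ks and Ka; a proportion of 3/4 or more
#' leaves the corrected rate undefined. The ratio Ka/Ks is undefined when
#' Ks = 0.
#'
#' @param cdsA,cdsB aligned coding sequences.
#' @param code a [geneticCode()] object.
#' @param exclude_stops stop-codon exclusion in site counting and pathway
#'   enumeration (default `TRUE`); `FALSE` gives strict original NG86
#'   counting.
#' @return list with `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ratio`
#'   (`NA` when undefined), `selection` (see [classifySelection()]),
#'   `n_codons` (aligned codons used) and `n_dropped`.
#' @examples
#' a <- paste(rep("GCC", 11), collapse = "")
#' b <- paste(c(rep("GCC", 10), "GCT"), collapse = "")
#' ng86Pairwise(a, b)$Ka  # 0: the single change is synonymous
#' @export
ng86Pairwise <- function(cdsA, cdsB, code = geneticCode(2L),
                         exclude_stops = TRUE) {
  cdsA <- .normSeq(cdsA, allow = "-", what = "cdsA")
  cdsB <- .normSeq(cdsB, allow = "-", what = "cdsB")
  if (nchar(cdsA) != nchar(cdsB)) stop("sequences must be aligned (equal length)")
  if (nchar(cdsA) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  ca <- .splitCodons(cdsA)
  cb <- .splitCodons(cdsB)
  clean <- ca %in% .CODONS & cb %in% .CODONS
  n_dropped <- sum(!clean)
  ca <- ca[clean]
  cb <- cb[clean]
  if (!length(ca)) stop("zero aligned codons after dropping gapped codons")
  if (any(.isStop(ca, code)) || any(.isStop(cb, code)))
    stop("stop codon in alignment; trim terminal stops first")
  st <- .siteTable(code, exclude_stops)
  S <- (sum(st[ca, "s"]) + sum(st[cb, "s"])) / 2
  N <- (sum(st[ca, "n"]) + sum(st[cb, "n"])) / 2
  Sd <- Nd <- 0
  for (i in which(ca != cb)) {
    d <- .pathwayDiffs(ca[i], cb[i], code, exclude_stops)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  if (isTRUE(ps >= 0.75) || isTRUE(pn >= 0.75))
    warning("difference proportion >= 3/4; corrected rate undefined")
  Ks <- .jc(ps)
  Ka <- .jc(pn)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn, Ks = Ks, Ka = Ka,
       ratio = ratio, selection = classifySelection(ratio),
       n_codons = length(ca), n_dropped = n_dropped)
}

#' Classify selection from a Ka/Ks ratio
#'
#' Ratios below 1 indicate purifying (negative) selection, ratios above 1
#' positive selection, and a ratio of exactly 1 (within 1e-9) neutral
#' evolution; an undefined ratio (`NA`, e.g. when Ks = 0) maps to
#' `"undefined"`.
#'
#' @param ratio numeric vector of Ka/Ks ratios (NA allowed).
#' @return character vector over
#'   `{"purifying", "neutral", "positive", "undefined"}`.
#' @examples
#' classifySelection(c(0.1747, 1.672, 1, NA))
#' @export
classifySelection <- function(ratio) {
  out <- rep("undefined", length(ratio))
  ok <- !is.na(ratio)
  out[ok & abs(ratio - 1) <= 1e-9] <- "neutral"
  out[ok & ratio < 1 & abs(ratio - 1) > 1e-9] <- "purifying"
  out[ok & ratio > 1 & abs(ratio - 1) > 1e-9] <- "positive"
  out
}

#' Trim terminal stop signal from a CDS
#'
#' Removes incomplete trailing bases (length not a multiple of three) and a
#' complete terminal stop codon, leaving sense codons only, as required by
#' [ng86Pairwise()].
#'
#' @param cds coding-orientation nucleotide string.
#' @param code a [geneticCode()] object.
#' @return the trimmed string.
#' @export
trimTerminalStop <- function(cds, code = geneticCode(2L)) {
  cds <- .normSeq(cds, allow = "-", what = "cds")
  len <- nchar(cds) - nchar(cds) %% 3L
  cds <- substring(cds, 1L, len)
  if (len >= 3L && .isStop(substring(cds, len - 2L, len), code))
    cds <- substring(cds, 1L, len - 3L)
  cds
}

#' Per-gene, per-pair Ka/Ks grid
#'
#' Runs [ng86Pairwise()] for every gene over every unordered pair of
#' species. Terminal stop signals are trimmed from each CDS first. Genes
#' missing from a species are reported and skipped for the pairs involving
#' it; the overall mean ratio averages all finite per-gene ratios across
#' pairs.
#'
#' @param cds_sets named list (species) of named lists/vectors (gene ->
#'   coding sequence); per-gene sequences must be codon-aligned across
#'   species (ungapped equal-length sequences qualify).
#' @param code a [geneticCode()] object.
#' @param exclude_stops passed to [ng86Pairwise()].
#' @return list with `results` (data.frame: `gene`, `speciesA`, `speciesB`,
#'   `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`, `ratio`, `selection`) and
#'   `mean_ratio`.
#' @export
kaksMatrix <- function(cds_sets, code = geneticCode(2L), exclude_stops = TRUE) {
  species <- names(cds_sets)
  if (is.null(species) || length(species) < 2L)
    stop("need a named list of at least two species")
  genes <- unique(unlist(lapply(cds_sets, names)))
  rows <- list()
  for (i in seq_len(length(species) - 1L)) for (j in (i + 1L):length(species)) {
    for (g in genes) {
      a <- cds_sets[[i]][[g]]
      b <- cds_sets[[j]][[g]]
      if (is.null(a) || is.null(b)) {
        message("gene ", g, " missing for pair ", species[i], "/", species[j],
                "; skipped")
        next
      }
      r <- ng86Pairwise(trimTerminalStop(as.character(a), code),
                        trimTerminalStop(as.character(b), code),
                        code, exclude_stops)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, speciesA = species[i], speciesB = species[j],
        S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, Ka = r$Ka, Ks = r$Ks,
        ratio = r$ratio, selection = r$selection, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  finite <- results$ratio[is.finite(results$ratio)]
  list(results = results,
       mean_ratio = if (length(finite)) mean(finite) else NA_real_)
}
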