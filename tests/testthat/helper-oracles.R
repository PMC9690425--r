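# Independent oracles for the NG86 machinery. Deliberately use a different
# code path from the package: translation goes through seqinr (numcode = 2)
# rather than Biostrings, and pathway enumeration is a plain recursive walk.

oracleTranslate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 2)
}

oracleIsStop <- function(codon) oracleTranslate(codon) == "*"

# per-codon site counts by explicit neighbor enumeration
oracleSiteCounts <- function(codon, exclude_stops = TRUE) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracleTranslate(codon)
  s <- 0
  for (p in 1:3) {
    ch <- strsplit(codon, "")[[1]]
    neigh <- sapply(setdiff(bases, ch[p]), function(b) {
      x <- ch; x[p] <- b; paste(x, collapse = "")
    })
    syn <- sapply(neigh, oracleTranslate) == aa0
    stops <- sapply(neigh, oracleIsStop)
    if (exclude_stops) {
      keep <- !stops
      s <- s + if (any(keep)) sum(syn[keep]) / sum(keep) else 0
    } else {
      s <- s + sum(syn & !stops) / 3
    }
  }
  c(s = s, n = 3 - s)
}

# all mutational pathways between two codons, depth-first; returns a matrix
# with one row (sd, nd, hits_stop) per complete pathway
oraclePathways <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  out <- list()
  walk <- function(cur, remaining, sd, nd, hit) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- c(sd = sd, nd = nd, hit = hit)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      syn <- !oracleIsStop(c1) && !oracleIsStop(c2) &&
        oracleTranslate(c1) == oracleTranslate(c2)
      walk(nxt, setdiff(remaining, p), sd + syn, nd + !syn,
           hit || oracleIsStop(c2))
    }
  }
  walk(a, which(a != b), 0, 0, FALSE)
  do.call(rbind, out)
}

# NG86 pathway-averaged differences with the same stop-exclusion convention
oraclePathwayDiffs <- function(ca, cb) {
  m <- oraclePathways(ca, cb)
  keep <- m[, "hit"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  colMeans(m[keep, c("sd", "nd"), drop = FALSE])
}

SENSE_CODONS <- setdiff(mitoprofile:::.CODONS, STOPS2)
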