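#' Specification for a synthetic mitogenome
#'
#' Describes the genome a [generateGenome()] call will produce: the gene
#' order with per-gene lengths, strands and codon metadata, the per-junction
#' boundary plan (negative = overlap, positive = spacer; the last entry
#' closes the circle), the codon bias used for protein-coding genes, and the
#' base composition used for RNA genes, spacers and the control region.
#'
#' The default emulates the structure of the Arius maculatus mitogenome:
#' the canonical 37-gene vertebrate order plus control region with the
#' published lengths and boundary offsets (including the 10-bp ATP8/ATP6
#' overlap), empirical codon bias from the published codon-usage table, the
#' published whole-genome base composition for RNA/spacer fill, and the
#' A+T-rich (62.55%) published control-region composition.
#'
#' @param genes data.frame with columns `name`, `type`, `strand`, `length`,
#'   `offset_after`, `anticodon`, `init_codon`, `term_codon`. PCG lengths
#'   must match the stop model: a multiple of three for complete stops, a
#'   remainder of 1 or 2 for incomplete `T` / `TA` terminators.
#' @param codon_bias named numeric weights over (sense) codons; stop weights
#'   are ignored except at terminal positions.
#' @param base_composition named numeric probabilities for `A`, `C`, `G`,
#'   `T` used outside protein-coding genes.
#' @param control_region_composition like `base_composition`, for the
#'   control region.
#' @param seed integer seed making generation deterministic.
#' @param code a [geneticCode()] object.
#' @return list of class `GenomeSpec`.
#' @export
genomeSpec <- function(genes = NULL, codon_bias = NULL,
                       base_composition = c(A = 0.2963, C = 0.2965,
                                            G = 0.1530, T = 0.2542),
                       control_region_composition = c(A = 0.2946, C = 0.2305,
                                                      G = 0.1441, T = 0.3309),
                       seed = 1L, code = geneticCode(2L)) {
  if (is.null(genes)) {
    ref <- ariusMaculatusAnnotation()
    f <- features(ref)
    off <- boundaryOffsets(ref)
    genes <- data.frame(name = f$name, type = f$type, strand = f$strand,
                        length = f$size,
                        offset_after = off$offset[match(f$name, off$upstream)],
                        anticodon = f$anticodon, init_codon = f$init_codon,
                        term_codon = f$term_codon, stringsAsFactors = FALSE)
  }
  if (is.null(codon_bias)) {
    cc <- ariusMaculatusCodonCounts()
    codon_bias <- setNames(as.numeric(cc$count), cc$codon)
  }
  pcg <- genes$type == "PCG"
  term <- genes$term_codon[pcg]
  rem <- genes$length[pcg] %% 3L
  stop_len <- ifelse(term %in% code$stops, 3L, nchar(term))
  bad <- !is.na(term) & rem != stop_len %% 3L
  if (any(bad))
    stop("PCG length inconsistent with terminator for: ",
         paste(genes$name[pcg][bad], collapse = ", "))
  spec <- list(genes = genes, codon_bias = codon_bias,
               base_composition = base_composition / sum(base_composition),
               control_region_composition =
                 control_region_composition / sum(control_region_composition),
               seed = seed, code = code)
  class(spec) <- "GenomeSpec"
  spec
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Lays the genes of the spec head to tail under its boundary plan (the
#' circle must close: total length = sum of gene lengths plus signed
#' offsets), then fills sequence: protein-coding genes are built codon by
#' codon from the codon bias - initiation codon first, no internal stops,
#' terminator per the stop model - on the coding strand (light-strand genes
#' are written back reverse-complemented); tRNA/rRNA genes, spacers and the
#' control region are filled i.i.d. from their base compositions.
#'
#' Overlap bases are owned by the feature written first (the upstream one):
#' codons of a downstream gene that fall on already-written positions are
#' sampled under those fixed-base constraints, avoiding stop codons wherever
#' a base is free. When the constraints force a stop (or an incompatible
#' terminator), the whole genome is resampled within the same seeded stream,
#' so generation stays deterministic per seed. Where a constraint overrides
#' the template's initiation/termination codon, the annotation records the
#' codon actually generated (dual coding of overlaps is approximated, not
#' enforced).
#'
#' @param spec a [genomeSpec()].
#' @return list with `genome` (a [MitoGenome-class] with sequence) and
#'   `truth`: `codon_counts` (64-codon tally of all PCG codons as sampled,
#'   terminal complete stops included), `codon_counts_by_gene`,
#'   `base_counts` (list of A/C/G/T tallies per region class and `whole`,
#'   reference strand, overlap bases counted once per feature),
#'   `boundary_offsets`, and `constrained` (genes whose initiation or
#'   termination codon was overridden by overlap constraints).
#' @examples
#' sim <- generateGenome(genomeSpec(seed = 7))
#' genomeLength(sim$genome)
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  withSeed(spec$seed, {
    for (attempt in 1:50) {
      res <- tryCatch(.buildGenome(spec), mitoprofileRetry = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stop("could not satisfy the overlap constraints after 50 attempts")
  })
}

.retry <- function(msg) {
  cond <- structure(class = c("mitoprofileRetry", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

.buildGenome <- function(spec) {
  g <- spec$genes
  code <- spec$code
  n <- nrow(g)
  start <- integer(n)
  end <- integer(n)
  start[1L] <- 1L
  for (i in seq_len(n)) {
    end[i] <- start[i] + g$length[i] - 1L
    if (i < n) start[i + 1L] <- end[i] + 1L + g$offset_after[i]
  }
  L <- end[n] + g$offset_after[n]
  if (any(start < 1L) || any(end > L))
    stop("boundary plan does not close into a consistent circle")

  chars <- rep(NA_character_, L)
  codon_counts <- setNames(integer(64L), .CODONS)
  by_gene <- list()
  constrained <- character(0)
  init_out <- g$init_codon
  term_out <- g$term_codon

  sense <- setdiff(.CODONS, code$stops)
  weights <- setNames(numeric(64L), .CODONS)
  w <- spec$codon_bias[names(spec$codon_bias) %in% .CODONS]
  weights[names(w)] <- w
  weights[code$stops] <- 0
  if (sum(weights) <= 0) weights[sense] <- 1
  codmat <- do.call(rbind, strsplit(.CODONS, ""))
  rownames(codmat) <- .CODONS

  for (i in seq_len(n)) {
    pos <- start[i]:end[i] # default plan never wraps
    if (g$type[i] == "PCG") {
      coding_pos <- if (g$strand[i] == "H") pos else rev(pos)
      fixed <- chars[coding_pos]
      if (g$strand[i] == "L") fixed <- ifelse(is.na(fixed), NA, .COMP[fixed])
      len <- g$length[i]
      m <- len %/% 3L
      rem <- len %% 3L
      term <- g$term_codon[i]
      if (is.na(term)) term <- if (rem == 0L) "TAA" else
        paste(rep("T", rem), collapse = "") # crude default; spec normally sets it
      if (rem == 2L) term <- "TA"
      gene_codons <- character(m)
      for (j in seq_len(m)) {
        fx <- fixed[(3L * j - 2L):(3L * j)]
        free <- is.na(fx)
        match_fixed <- setNames(rep(TRUE, 64L), .CODONS)
        for (p in 1:3) if (!free[p]) match_fixed <- match_fixed & codmat[, p] == fx[p]
        if (j == 1L) {
          init <- g$init_codon[i]
          if (is.na(init)) init <- "ATG"
          cand <- if (match_fixed[init]) init else {
            constrained <- c(constrained, g$name[i])
            .CODONS[match_fixed & .CODONS %in% sense]
          }
        } else if (j == m && rem == 0L) {
          cand <- if (match_fixed[term]) term else {
            constrained <- c(constrained, g$name[i])
            code$stops[match_fixed[code$stops]]
          }
        } else {
          cand <- .CODONS[match_fixed & .CODONS %in% sense]
        }
        if (!length(cand)) .retry(paste("no admissible codon for", g$name[i]))
        codon <- if (length(cand) == 1L) cand else {
          wc <- weights[cand]
          if (sum(wc) <= 0) wc <- rep(1, length(cand))
          sample(cand, 1L, prob = wc)
        }
        gene_codons[j] <- codon
        cc <- .splitChars(codon)
        out <- if (g$strand[i] == "H") cc else .COMP[cc]
        gp <- coding_pos[(3L * j - 2L):(3L * j)]
        chars[gp] <- ifelse(is.na(chars[gp]), out, chars[gp])
      }
      if (rem > 0L) { # incomplete stop: trailing T / TA in coding orientation
        tc <- .splitChars(term)
        gp <- coding_pos[(3L * m + 1L):len]
        fx <- fixed[(3L * m + 1L):len]
        if (any(!is.na(fx) & fx != tc))
          .retry(paste("terminator conflicts with overlap at", g$name[i]))
        out <- if (g$strand[i] == "H") tc else .COMP[tc]
        chars[gp] <- ifelse(is.na(chars[gp]), out, chars[gp])
        term_out[i] <- term
      } else {
        term_out[i] <- gene_codons[m]
      }
      init_out[i] <- gene_codons[1L]
      tab <- table(factor(gene_codons, levels = .CODONS))
      codon_counts <- codon_counts + as.integer(tab)
      by_gene[[g$name[i]]] <- setNames(as.integer(tab), .CODONS)
    } else {
      probs <- if (g$type[i] == "control_region")
        spec$control_region_composition else spec$base_composition
      empty <- pos[is.na(chars[pos])]
      if (length(empty))
        chars[empty] <- sample(names(probs), length(empty), replace = TRUE,
                               prob = probs)
    }
  }
  gap <- which(is.na(chars)) # intergenic spacer bases
  if (length(gap))
    chars[gap] <- sample(names(spec$base_composition), length(gap),
                         replace = TRUE, prob = spec$base_composition)

  feats <- data.frame(name = g$name, type = g$type, start = start, end = end,
                      strand = g$strand, anticodon = g$anticodon,
                      init_codon = init_out, term_codon = term_out,
                      stringsAsFactors = FALSE)
  genome <- MitoGenome(feats, sequence = paste(chars, collapse = ""))

  tally <- function(idx) {
    v <- unlist(lapply(idx, function(i) chars[start[i]:end[i]]))
    tab <- table(factor(v, levels = c("A", "C", "G", "T")))
    setNames(as.integer(tab), names(tab))
  }
  base_counts <- c(
    lapply(setNames(.FEATURE_TYPES, .FEATURE_TYPES),
           function(cls) tally(which(g$type == cls))),
    list(whole = setNames(as.integer(table(factor(chars,
      levels = c("A", "C", "G", "T")))), c("A", "C", "G", "T"))))

  list(genome = genome,
       truth = list(codon_counts = codon_counts,
                    codon_counts_by_gene = by_gene,
                    base_counts = base_counts,
                    boundary_offsets = setNames(g$offset_after, g$name),
                    constrained = unique(constrained)))
}

#' Evolve a diverged copy of a coding sequence
#'
#' Codon-level substitution simulator with a known nonsynonymous/synonymous
#' rate ratio. Substitution events arrive as a Poisson process with expected
#' `t` attempts per codon; each event picks a uniform codon position and a
#' uniform alternative base among those not creating a stop codon, then
#' accepts the change with relative rate `omega` for nonsynonymous changes
#' versus 1 for synonymous ones. Because proposals are uniform over the
#' non-stop alternatives, expected synonymous and nonsynonymous event counts
#' are proportional to the stop-renormalized NG86 site counts, making
#' `omega` recoverable by [ng86Pairwise()] on the (ancestor, copy) pair.
#'
#' @param cds sense-codon coding sequence (no stops; trim terminators
#'   first).
#' @param omega target dN/dS ratio, > 0.
#' @param t expected substitution attempts per codon, >= 0.
#' @param code a [geneticCode()] object.
#' @param seed integer seed (deterministic per seed); `NULL` uses the
#'   current RNG stream.
#' @return the diverged copy as a character string.
#' @examples
#' anc <- strrep("ATGGCCCTA", 10)
#' evolvePair(anc, omega = 0, t = 0, seed = 1) == anc  # TRUE at t = 0
#' @export
evolvePair <- function(cds, omega, t, code = geneticCode(2L), seed = NULL) {
  if (!is.numeric(omega) || omega < 0) stop("omega must be positive")
  if (omega == 0) omega <- 1e-12
  if (!is.numeric(t) || t < 0) stop("t must be non-negative")
  cds <- .normSeq(cds, what = "cds")
  if (nchar(cds) %% 3L != 0L) stop("cds length must be a multiple of 3")
  codons <- .splitCodons(cds)
  if (any(.isStop(codons, code))) stop("cds contains stop codons")
  withSeed(seed, {
    nc <- length(codons)
    n_events <- rpois(1L, t * nc)
    bases <- c("A", "C", "G", "T")
    for (e in seq_len(n_events)) {
      ci <- sample.int(nc, 1L)
      p <- sample.int(3L, 1L)
      cur <- .splitChars(codons[ci])
      alts <- vapply(setdiff(bases, cur[p]), function(b) {
        x <- cur; x[p] <- b; paste(x, collapse = "")
      }, "")
      alts <- alts[!.isStop(alts, code)]
      if (!length(alts)) next
      nxt <- if (length(alts) == 1L) alts else sample(alts, 1L)
      syn <- .aa(nxt, code) == .aa(codons[ci], code)
      acc <- if (omega <= 1) (if (syn) 1 else omega) else
        (if (syn) 1 / omega else 1)
      if (runif(1L) < acc) codons[ci] <- nxt
    }
    paste(codons, collapse = "")
  })
}
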