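#' Read a GenBank flat file into a MitoGenome
#'
#' Minimal flat-file reader covering what mitogenome records need: `CDS`,
#' `tRNA`, `rRNA` and `D-loop` features with plain, `complement(...)` and
#' `join(...)` locations (a join across the origin of a circular record maps
#' to one wrapping feature with `end < start`), `/gene` or `/product` names,
#' and `/anticodon`, `/note="init:..."`, `/note="term:..."` codon metadata as
#' written by [writeGenBank()]. The `ORIGIN` block, when present, becomes the
#' genome sequence.
#'
#' @param file path to a GenBank flat file (or character vector of its lines).
#' @return a [MitoGenome-class].
#' @export
readGenBank <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file)) readLines(file) else
    unlist(strsplit(file, "\n", fixed = TRUE))
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) && grepl("circular", locus[1L], ignore.case = TRUE)
  glen <- if (length(locus)) {
    m <- regmatches(locus[1L], regexpr("[0-9]+(?= bp)", locus[1L], perl = TRUE))
    if (length(m)) as.integer(m) else NA_integer_
  } else NA_integer_

  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend) else length(lines) + 1L
  feat_lines <- if (length(fstart)) lines[(fstart[1L] + 1L):(fend - 1L)] else character(0)

  # group feature blocks: a new feature starts with a key at column 6
  keyline <- grepl("^ {5}\\S", feat_lines)
  grp <- cumsum(keyline)
  rows <- list()
  for (g in setdiff(unique(grp), 0L)) {
    block <- feat_lines[grp == g]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "D_loop")) next
    loc <- sub("^ {5}\\S+\\s+", "", block[1L])
    quals <- paste(trimws(block[-1L]), collapse = " ")
    p <- .parseLocation(loc)
    if (is.null(p)) stop("unparseable location: ", loc)
    getq <- function(name) {
      m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', name), quals))
      if (length(m)) sub(sprintf('/%s="([^"]*)"', name), "\\1", m) else NA_character_
    }
    nm <- getq("gene")
    if (is.na(nm)) nm <- getq("product")
    note <- getq("note")
    init <- term <- NA_character_
    if (!is.na(note)) {
      mi <- regmatches(note, regexpr("init:[A-Z]+", note))
      mt <- regmatches(note, regexpr("term:[A-Z]+", note))
      if (length(mi)) init <- sub("init:", "", mi)
      if (length(mt)) term <- sub("term:", "", mt)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm,
      type = switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    "control_region"),
      start = p$start, end = p$end, strand = if (p$complement) "L" else "H",
      anticodon = getq("anticodon"), init_codon = init, term_codon = term,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no features")
  f <- do.call(rbind, rows)

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) min(oend[oend > ostart[1L]]) else length(lines) + 1L
    body <- lines[(ostart[1L] + 1L):(oend - 1L)]
    seq <- toupper(gsub("[ 0-9]", "", paste(body, collapse = "")))
    if (!nchar(seq)) seq <- NULL
  }
  MitoGenome(f, sequence = seq, circular = circular,
             genome_length = if (is.null(seq)) glen else NULL)
}

# "123..456", "complement(123..456)", "join(16500..16710,1..50)" and
# complement(join(...)); join across the origin -> one wrapping span
.parseLocation <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  if (complement) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
    if (any(lengths(m) != 3L)) return(NULL)
    starts <- as.integer(vapply(m, `[`, "", 2L))
    ends <- as.integer(vapply(m, `[`, "", 3L))
    # origin-spanning join: tail segment then head segment
    return(list(start = starts[1L], end = ends[length(ends)],
                complement = complement))
  }
  m <- regexec("^([0-9]+)\\.\\.([0-9]+)$", loc)[[1L]]
  mm <- regmatches(loc, list(m))[[1L]]
  if (length(mm) != 3L) return(NULL)
  list(start = as.integer(mm[2L]), end = as.integer(mm[3L]),
       complement = complement)
}

#' Write a MitoGenome as a GenBank flat file
#'
#' The output round-trips through [readGenBank()] to an equal annotation
#' (coordinates, strands, codon metadata) and, when a sequence is attached,
#' an identical sequence.
#'
#' @param genome a [MitoGenome-class].
#' @param file output path, or `NULL` to return the lines invisibly.
#' @param locus_name LOCUS identifier, default `"mitogenome"`.
#' @return invisibly, the character vector of file lines.
#' @export
writeGenBank <- function(genome, file = NULL, locus_name = "mitogenome") {
  f <- features(genome)
  L <- genomeLength(genome)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                     locus_name, L,
                     if (isCircular(genome)) "circular" else "linear"),
             sprintf("DEFINITION  %s annotation written by mitoprofile.",
                     locus_name),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(f))) {
    span <- if (f$end[i] >= f$start[i])
      sprintf("%d..%d", f$start[i], f$end[i])
    else
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    if (f$strand[i] == "L") span <- sprintf("complement(%s)", span)
    key <- switch(f$type[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop")
    lines <- c(lines, sprintf("     %-15s %s", key, span),
               sprintf('                     /gene="%s"', f$name[i]))
    if (!is.na(f$anticodon[i]))
      lines <- c(lines, sprintf('                     /anticodon="%s"',
                                f$anticodon[i]))
    note <- c(if (!is.na(f$init_codon[i])) paste0("init:", f$init_codon[i]),
              if (!is.na(f$term_codon[i])) paste0("term:", f$term_codon[i]))
    if (length(note))
      lines <- c(lines, sprintf('                     /note="%s"',
                                paste(note, collapse = " ")))
  }
  seq <- genomeSequence(genome)
  if (!is.null(seq)) {
    lines <- c(lines, "ORIGIN")
    starts <- seq.int(1L, nchar(seq), by = 60L)
    for (s in starts) {
      chunk <- substring(seq, s, min(s + 59L, nchar(seq)))
      tens <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))))
    }
  }
  lines <- c(lines, "//")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
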