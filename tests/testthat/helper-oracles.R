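# Brute-force reference implementations, deliberately independent of the
# package's scanning engine (plain substr loops, hand-written IUPAC sets,
# hand-written complementation).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

oracleRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

oracleWordMatches <- function(word, patword) {
  pl <- strsplit(patword, "")[[1]]
  wl <- strsplit(word, "")[[1]]
  if (length(pl) != length(wl)) return(FALSE)
  all(mapply(function(w, p) w %in% IUPAC_SETS[[p]], wl, pl))
}

# All (offset, strand, word) occurrences of the pattern in one insert, in
# scan order: forward offsets ascending, then reverse hits by forward offset.
oracleOccurrences <- function(insert, patword, strandMode = "both") {
  k <- nchar(patword)
  L <- nchar(insert)
  out <- list()
  if (L >= k) {
    for (o in seq_len(L - k + 1L)) {
      w <- substr(insert, o, o + k - 1L)
      if (oracleWordMatches(w, patword))
        out[[length(out) + 1L]] <- list(o, "+", w)
    }
    if (strandMode == "both") {
      for (o in seq_len(L - k + 1L)) {
        w <- oracleRevComp(substr(insert, o, o + k - 1L))
        if (oracleWordMatches(w, patword))
          out[[length(out) + 1L]] <- list(o, "-", w)
      }
    }
  }
  if (!length(out))
    return(data.frame(offset = integer(0), strand = character(0),
                      word = character(0), stringsAsFactors = FALSE))
  data.frame(offset = vapply(out, function(x) x[[1]], integer(1)),
             strand = vapply(out, function(x) x[[2]], character(1)),
             word = vapply(out, function(x) x[[3]], character(1)),
             stringsAsFactors = FALSE)
}

# Census counts by exhaustive window testing.
oracleCensusCounts <- function(inserts, patword, countMode = "per_read",
                               strandMode = "both") {
  words <- character(0)
  for (ins in inserts) {
    occ <- oracleOccurrences(ins, patword, strandMode)
    if (!nrow(occ)) next
    words <- c(words, if (countMode == "per_read") occ$word[1L] else occ$word)
  }
  if (!length(words)) return(integer(0))
  tab <- table(words)
  stats::setNames(as.integer(tab), names(tab))
}

# All concrete realizations of a gapped motif (left x gap strings x right).
oracleMotifRealizations <- function(left, gapMin, gapMax, gapAlphabet,
                                    right) {
  expandIupac <- function(word) {
    if (!nchar(word)) return("")
    sets <- lapply(strsplit(word, "")[[1]], function(l) IUPAC_SETS[[l]])
    grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
    do.call(paste0, rev(grid))
  }
  lefts <- expandIupac(left)
  rights <- expandIupac(right)
  words <- character(0)
  for (g in seq.int(gapMin, gapMax)) {
    gaps <- if (g == 0L) "" else {
      sets <- rep(list(gapAlphabet), g)
      grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
      do.call(paste0, rev(grid))
    }
    for (l in lefts) for (gp in gaps) for (r in rights)
      words <- c(words, paste0(l, gp, r))
  }
  unique(words)
}

# Does the insert contain any realization, on either strand?
oracleMotifHit <- function(insert, realizations, strandMode = "both") {
  targets <- if (strandMode == "both")
    c(insert, oracleRevComp(insert)) else insert
  for (t in targets)
    for (w in realizations)
      if (grepl(w, t, fixed = TRUE)) return(TRUE)
  FALSE
}

# Two-pass covariance Pearson oracle.
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Random A/C/G/T inserts.
randomInserts <- function(n, len = 35L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# An insert with a site embedded at a fixed offset in a C background (C's
# cannot create extra census-pattern or catalog-motif matches).
paddedInsert <- function(site, len = 35L, at = 11L) {
  paste0(strrep("C", at - 1L), site,
         strrep("C", len - at + 1L - nchar(site)))
}
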