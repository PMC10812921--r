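# Internal helpers: base encoding, IUPAC expansion, reverse complement.

.BASES <- c("A", "C", "G", "T")

# Integer-encode equal-length DNA strings as an n x width matrix (A=1..T=4).
encodeDNA <- function(seqs, width) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), nrow = 0L, ncol = width))
  raw <- charToRaw(paste0(seqs, collapse = ""))
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("A")) + 1L] <- 1L
  lut[as.integer(charToRaw("C")) + 1L] <- 2L
  lut[as.integer(charToRaw("G")) + 1L] <- 3L
  lut[as.integer(charToRaw("T")) + 1L] <- 4L
  idx <- lut[as.integer(raw) + 1L]
  if (anyNA(idx))
    stop("sequences must contain only A/C/G/T")
  matrix(idx, nrow = n, ncol = width, byrow = TRUE)
}

# Reverse complement of plain character DNA (vectorised).
rcChar <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Letters allowed by one IUPAC code, sorted.
iupacLetters <- function(code) {
  sort(strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]])
}

# Does each word (plain ACGT) match the IUPAC pattern? Vectorised over words.
wordMatchesPattern <- function(words, pattern) {
  k <- pattern@k
  if (!length(words)) return(logical(0))
  if (any(nchar(words) != k)) return(rep(FALSE, length(words)))
  pat <- strsplit(pattern@word, "")[[1]]
  ok <- rep(TRUE, length(words))
  for (p in seq_len(k)) {
    allowed <- iupacLetters(pat[p])
    ok <- ok & substr(words, p, p) %in% allowed
  }
  ok
}

# IUPAC code for a set of bases (e.g. c("A","T") -> "W").
basesToIupac <- function(bases) {
  Biostrings::mergeIUPACLetters(paste(sort(unique(toupper(bases))),
                                      collapse = ""))
}

# Concrete IUPAC words realising a gapped motif, one per gap length.
motifIupacWords <- function(motif) {
  gaps <- seq.int(motif@gapMin, motif@gapMax)
  if (identical(gaps, 0L) || motif@gapMax == 0L)
    return(stats::setNames(paste0(motif@left, motif@right), motif@name))
  code <- basesToIupac(motif@gapAlphabet)
  words <- vapply(gaps, function(g)
    paste0(motif@left, strrep(code, g), motif@right), character(1))
  stats::setNames(words, paste0(motif@name, "_gap", gaps))
}

# Maximal span of a motif on the read.
motifSpan <- function(motif) {
  nchar(motif@left) + motif@gapMax + nchar(motif@right)
}
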