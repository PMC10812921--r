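#' Enumerate all concrete words of a degenerate pattern
#'
#' @param pattern a [DegeneratePattern-class].
#' @return character vector of all matching A/C/G/T words, lexicographic
#'   order, no duplicates.
#' @examples
#' length(enumeratePattern(DegeneratePattern("ANNNNAAN")))  # 1024
#' enumeratePattern(DegeneratePattern("AN"))
#' @export
enumeratePattern <- function(pattern) {
  methods::validObject(pattern)
  letters <- strsplit(pattern@word, "")[[1]]
  sets <- lapply(letters, iupacLetters)
  # expand.grid varies its first factor fastest; feed positions in reverse so
  # that position 1 is most significant, i.e. lexicographic output order
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, rev(grid))
}

# Shared scanning engine: all pattern occurrences in a set of inserts.
# Returns a data.frame(read, offset, strand, word) where offset is the
# 1-based start of the window on the forward read, strand is "+"/"-", and
# word is the matched 8-mer in pattern orientation (reverse-complemented for
# minus-strand hits).  Rows are in scan order per read: forward 5'->3' first,
# then minus-strand hits by ascending forward offset.
.patternOccurrences <- function(dna, pattern, strandMode) {
  k <- pattern@k
  if (length(dna) == 0L)
    return(data.frame(read = integer(0), offset = integer(0),
                      strand = character(0), word = character(0),
                      stringsAsFactors = FALSE))
  seqs <- as.character(dna)
  collect <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, dna, fixed = FALSE)
    starts <- Biostrings::startIndex(m)
    nhit <- IRanges::elementNROWS(m)
    read <- rep.int(seq_along(dna), nhit)
    offset <- unlist(starts[nhit > 0L], use.names = FALSE)
    if (is.null(offset)) offset <- integer(0)
    word <- substring(seqs[read], offset, offset + k - 1L)
    if (strand == "-") word <- rcChar(word)
    data.frame(read = read, offset = offset,
               strand = rep_len(strand, length(read)), word = word,
               stringsAsFactors = FALSE)
  }
  fwd <- collect(pattern@word, "+")
  if (strandMode == "both") {
    rcword <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern@word)))
    rev <- collect(rcword, "-")
    occ <- rbind(fwd, rev)
  } else {
    occ <- fwd
  }
  occ[order(occ$read, occ$strand == "-", occ$offset), , drop = FALSE]
}

#' Find occurrences of a degenerate pattern in one insert
#'
#' Tests every length-k window of the insert on the forward strand and, with
#' `strandMode = "both"`, on the reverse complement.  Minus-strand hits are
#' reported at their forward-strand offset with the matched word given in
#' pattern orientation.
#'
#' @param insert a single A/C/G/T string.
#' @param pattern a [DegeneratePattern-class].
#' @param strandMode "both" (default) or "forward".
#' @return data.frame(offset, strand, word) in scan order (forward hits
#'   first); zero rows if the insert is shorter than the pattern or nothing
#'   matches.
#' @examples
#' findPatternMatches("CCATGCAAATCC", DegeneratePattern("ANNNNAAN"))
#' @export
findPatternMatches <- function(insert, pattern,
                               strandMode = c("both", "forward")) {
  strandMode <- match.arg(strandMode)
  stopifnot(length(insert) == 1L)
  insert <- toupper(insert)
  if (nchar(insert) < pattern@k)
    return(data.frame(offset = integer(0), strand = character(0),
                      word = character(0), stringsAsFactors = FALSE))
  occ <- .patternOccurrences(Biostrings::DNAStringSet(insert), pattern,
                             strandMode)
  occ$read <- NULL
  rownames(occ) <- NULL
  occ
}

#' Census of a degenerate pattern over a read set
#'
#' Counts concrete pattern words across all inserts of a set and converts the
#' counts to relative frequencies in percent.  In `per_read` mode each read
#' contributes at most one word, its first occurrence in scan order (a 35-mer
#' enriched by one binding event is counted once); `per_occurrence` counts
#' every window.  Percentages are normalised over all matched words, so they
#' sum to 100; the matched-read fraction is kept separately.
#'
#' @param readset a [SelexReadSet-class].
#' @param pattern a [DegeneratePattern-class] (default ANNNNAAN).
#' @param countMode "per_read" (default) or "per_occurrence".
#' @param strandMode "both" (default) or "forward".
#' @return A [FrequencyTable-class].
#' @examples
#' rs <- SelexReadSet(c("CCATGCAAATCC", "CCATGCTAATCC"), "toy",
#'                    insertLength = 12)
#' patternCensus(rs)
#' @export
patternCensus <- function(readset, pattern = DegeneratePattern(),
                          countMode = c("per_read", "per_occurrence"),
                          strandMode = c("both", "forward")) {
  countMode <- match.arg(countMode)
  strandMode <- match.arg(strandMode)
  words <- .censusWords(readset, pattern, countMode, strandMode)
  n <- length(readset@inserts)
  if (!length(words$word)) {
    return(new("FrequencyTable", pattern = pattern,
               setLabel = readset@condition,
               counts = stats::setNames(integer(0), character(0)),
               relFreq = stats::setNames(numeric(0), character(0)),
               matchedReads = 0L, totalReads = as.integer(n)))
  }
  tab <- table(words$word)
  counts <- stats::setNames(as.integer(tab), names(tab))
  o <- order(-counts, names(counts))
  counts <- counts[o]
  rel <- 100 * counts / sum(counts)
  new("FrequencyTable", pattern = pattern, setLabel = readset@condition,
      counts = counts, relFreq = rel,
      matchedReads = as.integer(words$matchedReads),
      totalReads = as.integer(n))
}

# Matched words of a census (one per read in per_read mode) plus the number
# of reads with at least one occurrence.
.censusWords <- function(readset, pattern, countMode, strandMode) {
  occ <- .patternOccurrences(readset@inserts, pattern, strandMode)
  matchedReads <- length(unique(occ$read))
  word <- if (countMode == "per_read")
    occ$word[!duplicated(occ$read)] else occ$word
  list(word = word, matchedReads = matchedReads)
}

#' Top-ranked census words
#'
#' Ranks words by descending relative frequency, breaking ties
#' lexicographically, and reports the cumulative share of the returned list.
#'
#' @param table a [FrequencyTable-class].
#' @param n maximum number of words to return (default 100).
#' @return data.frame(word, rel_freq_percent, cumulative_percent) with at
#'   most `min(n, number of non-zero words)` rows; the cumulative share of
#'   the whole list is also attached as attribute `"cumulativeShare"`.
#' @export
topWords <- function(table, n = 100L) {
  stopifnot(n >= 1L)
  o <- order(-table@relFreq, names(table@relFreq))
  o <- utils::head(o, n)
  out <- data.frame(word = names(table@relFreq)[o],
                    rel_freq_percent = unname(table@relFreq[o]),
                    stringsAsFactors = FALSE)
  out$cumulative_percent <- cumsum(out$rel_freq_percent)
  attr(out, "cumulativeShare") <-
    if (nrow(out)) out$cumulative_percent[nrow(out)] else 0
  out
}

#' Per-position base composition of matched census words
#'
#' Base percentages at each pattern position, computed over the words matched
#' in the set (one word per read in `per_read` mode).  With no matches the
#' composition is undefined (`nSites == 0`) rather than divided by zero.
#'
#' @inheritParams patternCensus
#' @return A [PositionalComposition-class].
#' @export
positionalComposition <- function(readset, pattern = DegeneratePattern(),
                                  countMode = c("per_read",
                                                "per_occurrence"),
                                  strandMode = c("both", "forward")) {
  countMode <- match.arg(countMode)
  strandMode <- match.arg(strandMode)
  words <- .censusWords(readset, pattern, countMode, strandMode)$word
  if (!length(words))
    return(new("PositionalComposition", composition = NULL, nSites = 0L))
  k <- pattern@k
  M <- encodeDNA(words, k)
  comp <- t(apply(M, 2L, tabulate, nbins = 4L))
  dimnames(comp) <- list(NULL, c("A", "C", "G", "T"))
  comp <- 100 * comp / length(words)
  new("PositionalComposition", composition = comp,
      nSites = length(words))
}
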