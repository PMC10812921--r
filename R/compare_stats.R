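#' Pairwise comparison of two census frequency tables
#'
#' Aligns the two tables over the union of their top-`n` word lists (union,
#' not intersection, so that words collapsing to zero in one condition — the
#' most informative cases — are retained), and reports per-word differences
#' in percentage points and fold changes.  The fold change a/b is flagged
#' undefined when the denominator frequency is 0; the reduction-style
#' magnitude `max(a,b)/min(a,b)` with its direction is reported alongside the
#' raw ratio.
#'
#' @param a,b [FrequencyTable-class] objects counted with the same pattern.
#' @param n top-list size per table (default 100).
#' @return data.frame(word, freq_a, freq_b, diff_points, fold,
#'   fold_undefined, fold_direction, fold_magnitude), ordered by descending
#'   absolute difference (ties broken by word).
#' @export
compareFrequencyTables <- function(a, b, n = 100L) {
  if (!identical(a@pattern@word, b@pattern@word))
    stop("frequency tables were counted with different patterns: ",
         a@pattern@word, " vs ", b@pattern@word)
  wordsA <- topWords(a, n)$word
  wordsB <- topWords(b, n)$word
  words <- sort(union(wordsA, wordsB))
  fa <- ifelse(words %in% names(a@relFreq), a@relFreq[words], 0)
  fb <- ifelse(words %in% names(b@relFreq), b@relFreq[words], 0)
  fa[is.na(fa)] <- 0
  fb[is.na(fb)] <- 0
  diff <- fa - fb
  undef <- fb == 0
  fold <- ifelse(undef, NA_real_, fa / fb)
  dir <- ifelse(fa > fb, "up", ifelse(fa < fb, "down", "equal"))
  mag <- ifelse(fa == 0 | fb == 0, NA_real_, pmax(fa, fb) / pmin(fa, fb))
  out <- data.frame(word = words, freq_a = unname(fa), freq_b = unname(fb),
                    diff_points = unname(diff), fold = unname(fold),
                    fold_undefined = unname(undef),
                    fold_direction = unname(dir),
                    fold_magnitude = unname(mag),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$diff_points), out$word), , drop = FALSE]
}

#' Fold change of one word between two frequency tables
#'
#' @param a,b [FrequencyTable-class] objects sharing a pattern.
#' @param word a concrete word of the pattern.
#' @return list with `ratio` (freq in a / freq in b, NA when undefined),
#'   `undefined` flag (denominator 0), `direction` ("up"/"down"/"equal") and
#'   `magnitude` (`max/min`, the "x-fold reduction/increase" convention; NA
#'   if either frequency is 0).
#' @examples
#' # 2% vs 8% is reported as ratio 0.25: a 4-fold reduction
#' @export
foldChange <- function(a, b, word) {
  if (!identical(a@pattern@word, b@pattern@word))
    stop("frequency tables were counted with different patterns")
  if (!wordMatchesPattern(word, a@pattern))
    stop("word ", word, " does not match the census pattern ",
         a@pattern@word)
  fa <- if (word %in% names(a@relFreq)) unname(a@relFreq[word]) else 0
  fb <- if (word %in% names(b@relFreq)) unname(b@relFreq[word]) else 0
  undef <- fb == 0
  list(ratio = if (undef) NA_real_ else fa / fb,
       undefined = undef,
       direction = if (fa > fb) "up" else if (fa < fb) "down" else "equal",
       magnitude = if (fa == 0 || fb == 0) NA_real_
                   else max(fa, fb) / min(fa, fb))
}

#' Difference of two positional compositions
#'
#' Elementwise percentage-point difference a - b; every position's four
#' entries sum to exactly 0 because both inputs sum to 100.
#'
#' @param a,b [PositionalComposition-class] objects over the same pattern
#'   length, both non-empty.
#' @return k x 4 numeric matrix of percentage-point differences.
#' @export
compositionDelta <- function(a, b) {
  if (a@nSites == 0L || b@nSites == 0L)
    stop("both compositions must be computed over at least one site")
  if (!identical(dim(a@composition), dim(b@composition)))
    stop("compositions have different dimensions")
  a@composition - b@composition
}

#' Pearson product-moment correlation
#'
#' Standard correlation coefficient via [stats::cor()], with the input
#' validation the comparison workflow needs: equal lengths, at least three
#' points, and an undefined result (NA) when either vector has zero
#' variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the coefficient in `[-1, 1]`, or NA when undefined.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))  # about 0.982
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Correlate census frequencies with EMSA band intensities
#'
#' Pairs the relative frequencies of sequences in a census table with
#' densitometry signals measured for the same sequences in one condition, and
#' computes the Pearson correlation, returning the paired rows for audit.
#' A probed sequence that matches the census pattern but was never observed
#' has relative frequency 0 (the census is defined over the whole pattern
#' universe); probe labels that do not match the pattern are dropped.
#'
#' @param table a [FrequencyTable-class].
#' @param intensities data.frame with columns `sequence`, `condition`,
#'   `signal` (non-negative; unique sequence/condition pairs).
#' @param condition which condition's signals to use.
#' @return list with `r`, `n` (pairs used) and `pairs`, a
#'   data.frame(sequence, rel_freq_percent, signal).
#' @export
correlateIntensities <- function(table, intensities, condition) {
  need <- c("sequence", "condition", "signal")
  if (!all(need %in% names(intensities)))
    stop("intensities needs columns sequence/condition/signal")
  if (any(intensities$signal < 0))
    stop("intensity signals must be non-negative")
  if (anyDuplicated(intensities[, c("sequence", "condition")]))
    stop("duplicate (sequence, condition) pairs in the intensity table")
  sub <- intensities[intensities$condition == condition, , drop = FALSE]
  shared <- sub$sequence[wordMatchesPattern(sub$sequence, table@pattern)]
  if (length(shared) < 3L)
    stop("insufficient data: need >= 3 sequences shared between the ",
         "frequency table and the intensity table for '", condition, "'")
  freq <- ifelse(shared %in% names(table@relFreq),
                 table@relFreq[shared], 0)
  freq[is.na(freq)] <- 0
  freq <- unname(freq)
  sig <- sub$signal[match(shared, sub$sequence)]
  list(r = pearsonR(freq, sig), n = length(shared),
       pairs = data.frame(sequence = shared, rel_freq_percent = freq,
                          signal = sig, stringsAsFactors = FALSE))
}
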