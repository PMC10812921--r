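mkTable <- function(counts, label = "x", pattern = "ANNNNAAN") {
  counts <- counts[order(-counts, names(counts))]
  new("FrequencyTable", pattern = DegeneratePattern(pattern),
      setLabel = label, counts = counts,
      relFreq = 100 * counts / sum(counts),
      matchedReads = sum(counts), totalReads = sum(counts))
}

test_that("table comparison aligns top-word unions with differences and folds", {
  a <- mkTable(c(ATGCAAAT = 40L, ATGCTAAT = 40L, ATTTAAAT = 20L), "a")
  b <- mkTable(c(ATGCAAAT = 80L, ATGCTAAT = 10L, ATTCAAAT = 10L), "b")

  self <- compareFrequencyTables(a, a, 10L)
  expect_true(all(self$diff_points == 0))
  expect_true(all(self$fold == 1))

  cmp <- compareFrequencyTables(a, b, 10L)
  expect_setequal(cmp$word,
                  c("ATGCAAAT", "ATGCTAAT", "ATTTAAAT", "ATTCAAAT"))
  row <- cmp[cmp$word == "ATGCTAAT", ]
  expect_equal(row$diff_points, 30)
  expect_equal(row$fold, 4)
  # word absent from b: difference equals freq in a, fold flagged undefined
  row <- cmp[cmp$word == "ATTTAAAT", ]
  expect_true(row$fold_undefined)
  expect_equal(row$diff_points, row$freq_a)
  # ordered by descending absolute difference
  expect_false(is.unsorted(rev(abs(cmp$diff_points))))

  expect_error(compareFrequencyTables(a, mkTable(c(AA = 1L), "c", "NN")),
               "pattern")
})

test_that("comparison is antisymmetric in its two arguments", {
  set.seed(31)
  words <- enumeratePattern(DegeneratePattern("ANNNNAAN"))
  for (i in 1:5) {
    a <- mkTable(stats::setNames(
      as.integer(sample(1:50, 30L, TRUE)), sample(words, 30L)), "a")
    b <- mkTable(stats::setNames(
      as.integer(sample(1:50, 30L, TRUE)), sample(words, 30L)), "b")
    ab <- compareFrequencyTables(a, b, 20L)
    ba <- compareFrequencyTables(b, a, 20L)
    ba <- ba[match(ab$word, ba$word), ]
    expect_equal(ab$diff_points, -ba$diff_points)
    both <- !ab$fold_undefined & !ba$fold_undefined
    expect_equal(ab$fold[both], 1 / ba$fold[both])
  }
})

test_that("fold changes follow the reduction-magnitude convention", {
  a <- mkTable(c(ATGCAAAT = 2L, ATGCTAAT = 98L), "a")
  b <- mkTable(c(ATGCAAAT = 8L, ATGCTAAT = 92L), "b")
  fc <- foldChange(a, b, "ATGCAAAT")
  expect_equal(fc$ratio, 0.25)
  expect_identical(fc$direction, "down")
  expect_equal(fc$magnitude, 4)  # "a 4-fold reduction"
  expect_false(fc$undefined)

  same <- foldChange(a, a, "ATGCAAAT")
  expect_equal(same$ratio, 1)
  expect_identical(same$direction, "equal")

  fc0 <- foldChange(a, mkTable(c(ATGCTAAT = 5L), "z"), "ATGCAAAT")
  expect_true(fc0$undefined)
  expect_error(foldChange(a, b, "CTGCAAAT"), "does not match")
})

test_that("composition deltas subtract elementwise and sum to zero per position", {
  mkPC <- function(a5, t5) {
    m <- matrix(rep(c(25, 25, 25, 25), each = 8L), 8L, 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m[5L, ] <- c(a5, (100 - a5 - t5) / 2, (100 - a5 - t5) / 2, t5)
    new("PositionalComposition", composition = m, nSites = 100L)
  }
  a <- mkPC(98, 1)
  b <- mkPC(82, 12)
  d <- compositionDelta(a, b)
  expect_equal(unname(d[5L, "A"]), 16)  # A5 98% vs 82% -> +16 points
  expect_equal(unname(rowSums(d)), rep(0, 8L))
  expect_true(all(compositionDelta(a, a) == 0))
  small <- new("PositionalComposition",
               composition = matrix(c(100, 0, 0, 0), 1L, 4L,
                                    dimnames = list(NULL,
                                                    c("A", "C", "G", "T"))),
               nSites = 1L)
  expect_error(compositionDelta(a, small), "dimensions")
  empty <- new("PositionalComposition", composition = NULL, nSites = 0L)
  expect_error(compositionDelta(a, empty), "at least one site")
})

test_that("Pearson correlation matches the closed form and flags degeneracy", {
  expect_equal(pearsonR(1:10, 1:10), 1)
  expect_equal(pearsonR(1:10, 10:1), -1)
  # hand-evaluated closed form: r = 3 / sqrt(2 * 14/3... computed directly
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(pearsonR(x, y), oraclePearson(x, y))
  expect_equal(pearsonR(x, y), 0.9819805, tolerance = 1e-6)
  expect_true(is.na(pearsonR(c(1, 1, 1), 1:3)))
  expect_error(pearsonR(1:4, 1:5), "equal length")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("Pearson agrees with the two-pass covariance oracle on random data", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:100, 1L)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    expect_equal(pearsonR(x, y), oraclePearson(x, y), tolerance = 1e-12)
  }
})

test_that("frequency-intensity correlation pairs sequences and audits them", {
  ft <- mkTable(c(ATGCAAAT = 60L, ATGCTAAT = 30L, ATTTAAAT = 10L), "cond")
  intens <- data.frame(
    sequence = c("ATGCAAAT", "ATGCTAAT", "ATTTAAAT"),
    condition = "cond",
    signal = c(600, 300, 100) * 2)  # proportional to frequencies
  res <- correlateIntensities(ft, intens, "cond")
  expect_equal(res$r, 1)
  expect_identical(res$n, 3L)
  expect_identical(sort(res$pairs$sequence), sort(intens$sequence))

  flat <- transform(intens, signal = 5)
  expect_true(is.na(correlateIntensities(ft, flat, "cond")$r))

  expect_error(correlateIntensities(ft, intens[1:2, ], "cond"),
               "insufficient")
  dup <- rbind(intens, intens[1, ])
  expect_error(correlateIntensities(ft, dup, "cond"), "duplicate")
  neg <- transform(intens, signal = c(-1, 2, 3))
  expect_error(correlateIntensities(ft, neg, "cond"), "non-negative")
})
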