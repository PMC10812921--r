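test_that("pattern enumeration is exhaustive, ordered and validated", {
  expect_length(enumeratePattern(DegeneratePattern("ANNNNAAN")), 1024L)
  expect_identical(enumeratePattern(DegeneratePattern("ATGCAAAT")),
                   "ATGCAAAT")
  expect_identical(enumeratePattern(DegeneratePattern("AN")),
                   c("AA", "AC", "AG", "AT"))
  w <- enumeratePattern(DegeneratePattern("ANNNNAAN"))
  expect_false(is.unsorted(w))
  expect_identical(anyDuplicated(w), 0L)
  expect_identical(patternCardinality(DegeneratePattern("ANNNNAAN")), 1024)
  expect_error(DegeneratePattern("AXN"), "IUPAC")
})

test_that("pattern matching finds occurrences on both strands in scan order", {
  pat <- DegeneratePattern("ANNNNAAN")
  ins <- paddedInsert("ATGCAAAT", at = 11L)
  m <- findPatternMatches(ins, pat)
  expect_identical(m$offset, 11L)
  expect_identical(m$strand, "+")
  expect_identical(m$word, "ATGCAAAT")

  # poly-A: every one of 35-8+1 forward windows matches
  m <- findPatternMatches(strrep("A", 35L), pat, "forward")
  expect_identical(nrow(m), 28L)
  expect_true(all(m$word == "AAAAAAAA"))

  # reverse complement of the octamer fails forward (position 6 is C) but is
  # found on the minus strand, reported in pattern orientation
  ins <- paddedInsert("ATTTGCAT", at = 5L)
  expect_identical(nrow(findPatternMatches(ins, pat, "forward")), 0L)
  m <- findPatternMatches(ins, pat, "both")
  expect_identical(m$strand, "-")
  expect_identical(m$word, "ATGCAAAT")

  # insert shorter than the pattern: empty result, not an error
  expect_identical(nrow(findPatternMatches("ATGCA", pat)), 0L)
})

test_that("census counts per read or per occurrence with correct percentages", {
  pat <- DegeneratePattern("ANNNNAAN")
  rs <- SelexReadSet(c(paddedInsert("ATGCAAAT"), paddedInsert("ATGCAAAT"),
                       paddedInsert("ATGCAAAT"), paddedInsert("ATGCTAAT")),
                     "toy")
  ft <- patternCensus(rs, pat, "per_read")
  expect_identical(unname(wordCounts(ft)[c("ATGCAAAT", "ATGCTAAT")]),
                   c(3L, 1L))
  expect_equal(unname(relFreq(ft)[c("ATGCAAAT", "ATGCTAAT")]), c(75, 25))
  expect_identical(matchedReads(ft), 4L)
  expect_identical(totalReads(ft), 4L)

  # no matches at all: empty table, zero matched reads
  none <- SelexReadSet(rep(strrep("C", 35L), 3L), "none")
  ft0 <- patternCensus(none, pat)
  expect_length(wordCounts(ft0), 0L)
  expect_identical(matchedReads(ft0), 0L)

  # per-occurrence counts disjoint copies twice
  two <- SelexReadSet(paste0(strrep("C", 5), "ATGCAAAT", strrep("C", 9),
                             "ATGCAAAT", strrep("C", 5)), "two")
  expect_identical(
    unname(wordCounts(patternCensus(two, pat, "per_occurrence"))["ATGCAAAT"]),
    2L)
  expect_identical(
    unname(wordCounts(patternCensus(two, pat, "per_read"))["ATGCAAAT"]), 1L)
})

test_that("census relative frequencies always normalise to 100%", {
  pat <- DegeneratePattern("ANNNNAAN")
  set.seed(123)
  for (i in 1:10) {
    rs <- SelexReadSet(randomInserts(60, 35L), paste0("rnd", i))
    for (mode in c("per_read", "per_occurrence")) {
      ft <- patternCensus(rs, pat, mode)
      if (sum(wordCounts(ft)) > 0L)
        expect_equal(sum(relFreq(ft)), 100, tolerance = 1e-9)
    }
  }
})

test_that("census agrees with the exhaustive window-testing oracle", {
  pat <- DegeneratePattern("ANNNNAAN")
  set.seed(99)
  for (i in 1:4) {
    seqs <- c(randomInserts(40, 35L),
              paddedInsert("ATGCAAAT"), paddedInsert("ATTTGCAT"))
    rs <- SelexReadSet(seqs, paste0("oracle", i))
    for (mode in c("per_read", "per_occurrence")) {
      for (strands in c("both", "forward")) {
        got <- wordCounts(patternCensus(rs, pat, mode, strands))
        want <- oracleCensusCounts(seqs, "ANNNNAAN", mode, strands)
        expect_identical(got[order(names(got))], want[order(names(want))],
                         info = paste(mode, strands, i))
      }
    }
  }
})

test_that("per-insert matches equal the oracle's occurrence list", {
  pat <- DegeneratePattern("ANNNNAAN")
  set.seed(5)
  for (ins in c(randomInserts(30, 35L), strrep("A", 35L))) {
    got <- findPatternMatches(ins, pat, "both")
    want <- oracleOccurrences(ins, "ANNNNAAN", "both")
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, info = ins)
  }
})

test_that("top-word ranking is frequency-descending with lexicographic ties", {
  mk <- function(counts) {
    new("FrequencyTable", pattern = DegeneratePattern("NNNNNNNN"),
        setLabel = "x", counts = counts,
        relFreq = 100 * counts / sum(counts),
        matchedReads = sum(counts), totalReads = sum(counts))
  }
  ft <- mk(c(AAAAAAAA = 50L, CCCCCCCC = 30L, GGGGGGGG = 20L))
  tw <- topWords(ft, 2L)
  expect_identical(tw$word, c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(attr(tw, "cumulativeShare"), 80)

  # tie at 25%: lexicographically smaller word ranks first
  ft <- mk(c(TTTTTTTT = 25L, ACGTACGT = 25L, AAAAAAAA = 50L))
  expect_identical(topWords(ft, 3L)$word,
                   c("AAAAAAAA", "ACGTACGT", "TTTTTTTT"))

  # n beyond the number of non-zero words truncates
  expect_identical(nrow(topWords(ft, 100L)), 3L)
})

test_that("positional composition reflects matched words and handles no matches", {
  pat <- DegeneratePattern("ANNNNAAN")
  rs <- SelexReadSet(rep(paddedInsert("ATGCAAAT"), 4L), "uni")
  pc <- positionalComposition(rs, pat)
  expect_identical(nSites(pc), 4L)
  expect_equal(unname(composition(pc)[5L, "A"]), 100)
  expect_equal(unname(composition(pc)[2L, "T"]), 100)
  expect_equal(unname(rowSums(composition(pc))), rep(100, 8L))

  rs2 <- SelexReadSet(c(paddedInsert("ATGCAAAT"), paddedInsert("ATGCTAAT")),
                      "split")
  pc2 <- positionalComposition(rs2, pat)
  expect_equal(unname(composition(pc2)[5L, "A"]), 50)
  expect_equal(unname(composition(pc2)[5L, "T"]), 50)
  expect_equal(unname(composition(pc2)[2L, "T"]), 100)

  pc0 <- positionalComposition(SelexReadSet(strrep("C", 35L), "none"), pat)
  expect_identical(nSites(pc0), 0L)
  expect_null(composition(pc0))
})

test_that("fixed adenines at positions 1, 6, 7 suppress frame-shifted matches", {
  words <- enumeratePattern(DegeneratePattern("ANNNNAAN"))
  # Shifts of 2-7 nt: a co-match always needs an adenine beyond the word, so
  # a non-A continuation blocks it for every one of the 1024 words.
  for (s in 2:7) {
    shifted <- vapply(words, function(w) {
      read <- paste0(w, strrep("C", 7L))
      any(oracleOccurrences(read, "ANNNNAAN", "forward")$offset == 1L + s)
    }, logical(1))
    expect_false(any(shifted), info = paste("shift", s))
  }
  # Shift of 1 nt: forced precisely when the word has A at positions 2 and 8
  # (the shifted window then reuses the guaranteed A6/A7); exactly 64/1024
  # words allow it, so shifted double counting is suppressed 16-fold there.
  forced <- vapply(words, function(w) {
    read <- paste0(w, "C")
    any(oracleOccurrences(read, "ANNNNAAN", "forward")$offset == 2L)
  }, logical(1))
  expect_identical(sum(forced), 64L)
  expect_identical(unname(which(forced)),
                   which(substr(words, 2, 2) == "A" &
                         substr(words, 8, 8) == "A"))
})

test_that("reverse complements of census words are excluded except palindromic coincidences", {
  words <- enumeratePattern(DegeneratePattern("ANNNNAAN"))
  rcAlso <- vapply(words, function(w)
    oracleWordMatches(oracleRevComp(w), "ANNNNAAN"), logical(1))
  # rc(w) matches iff w has T at positions 2, 3 and 8: exactly 16 words
  expect_identical(sum(rcAlso), 16L)
  expect_identical(unname(which(rcAlso)),
                   which(substr(words, 2, 2) == "T" &
                         substr(words, 3, 3) == "T" &
                         substr(words, 8, 8) == "T"))
  expect_true("ATTTAAAT" %in% words[rcAlso])  # itself an RC coincidence
})
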