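flatModel <- function() {
  m <- matrix(1, 8L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  new("BindingModel", psam = Psam(m), clamp = ClampRule(),
      dimerMotifs = list(), dimerAffinities = numeric(0))
}

test_that("selection retains identical molecules at the occupancy rate", {
  model <- defaultBindingModel()
  pool <- rep(paddedInsert("ATGCAAAT"), 4000L)
  set.seed(3)
  sel <- selectRound(pool, model, bob1 = FALSE, band = "monomer",
                     stringency = 1)
  # a = 1 for every molecule, so the retained fraction is Binomial(n, 1/2)
  frac <- length(sel$selected) / length(pool)
  expect_lt(abs(frac - 0.5), 0.03)
  expect_true(all(sel$assignments$band == "monomer"))
  expect_identical(sum(sel$assignments$retained), length(sel$selected))
})

test_that("selection is deterministic under a fixed seed and collapses on a dead pool", {
  model <- defaultBindingModel()
  set.seed(21)
  pool <- randomInserts(500, 35L)
  set.seed(99); a <- selectRound(pool, model, band = "monomer")
  set.seed(99); b <- selectRound(pool, model, band = "monomer")
  expect_identical(a, b)

  # a model under which no molecule has any channel weight
  m <- matrix(1, 8L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[1L, c("C", "G", "T")] <- 0
  dead <- new("BindingModel", psam = Psam(m), clamp = ClampRule(),
              dimerMotifs = list(), dimerAffinities = numeric(0))
  set.seed(1)
  expect_error(selectRound(rep(strrep("C", 35L), 50L), dead,
                           band = "monomer"),
               "collapse")
})

test_that("band partitioning isolates dimer-bound molecules in the dimer band", {
  model <- defaultBindingModel()
  moreRead <- paste0(strrep("G", 10L), "ATGCATATGCAT", strrep("G", 13L))
  set.seed(8)
  pool <- c(rep(moreRead, 200L), randomInserts(800, 35L))
  sel <- selectRound(pool, model, bob1 = FALSE, band = "dimer")
  expect_gt(length(sel$selected), 0L)
  expect_true(all(sel$selected == moreRead))
})

test_that("amplification resamples to target size preserving proportions", {
  a <- strrep("A", 35L); c_ <- strrep("C", 35L)
  set.seed(12)
  expect_identical(amplifyPool(a, 7L), rep(a, 7L))
  out <- amplifyPool(c(a, c_), 10000L)
  expect_length(out, 10000L)
  tab <- table(factor(out, levels = c(a, c_)))
  p <- stats::chisq.test(as.integer(tab), p = c(0.5, 0.5))$p.value
  expect_gt(p, 0.01)
})

test_that("the full simulation is deterministic end-to-end", {
  cfg <- SimulationConfig(librarySize = 2000L, rounds = 2L, seed = 7L,
                          conditions = defaultConditions()[1:2, ])
  s1 <- runSelex(cfg)
  s2 <- runSelex(cfg)
  for (cond in names(s1$readsets))
    expect_identical(as.character(inserts(s1$readsets[[cond]])),
                     as.character(inserts(s2$readsets[[cond]])))
  expect_identical(s1$groundTruth$selectionLog, s2$groundTruth$selectionLog)

  # zero rounds returns the initial library unchanged
  cfg0 <- SimulationConfig(librarySize = 100L, rounds = 0L, seed = 7L,
                           conditions = defaultConditions()[1, ])
  s0a <- runSelex(cfg0)
  s0b <- runSelex(cfg0)
  expect_length(inserts(s0a$readsets[["POU1"]]), 100L)
  expect_identical(as.character(inserts(s0a$readsets[["POU1"]])),
                   as.character(inserts(s0b$readsets[["POU1"]])))
})

test_that("a flat model selects without regard to sequence content", {
  # under a flat Psam every molecule has channel weight 1, so selection is a
  # content-blind coin flip: the base composition of the selected molecules
  # is indistinguishable from that of the rest of the pool
  set.seed(5)
  pool <- randomInserts(4000, 35L)
  sel <- selectRound(pool, flatModel(), band = "monomer", stringency = 1)
  keep <- sel$assignments$retained
  cnt <- function(seqs) colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs), baseOnly = TRUE)[, 1:4])
  tab <- rbind(cnt(pool[keep]), cnt(pool[!keep]))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  expect_lt(abs(mean(keep) - 0.5), 0.03)
})

test_that("ternary-band selection enriches the consensus word round over round", {
  sim <- cachedSim("tern20k", function() {
    runSelex(SimulationConfig(librarySize = 20000L, rounds = 4L, seed = 1L,
                              conditions = defaultConditions()[2, ,
                                                               drop = FALSE]))
  })
  consensus <- vapply(sim$perRound[["POU1+BOB1"]], function(rs) {
    rf <- relFreq(patternCensus(rs))
    if ("ATGCAAAT" %in% names(rf)) unname(rf[["ATGCAAAT"]]) else 0
  }, numeric(1))
  expect_identical(length(consensus), 4L)
  expect_true(all(diff(consensus) > 0))
  a5 <- vapply(sim$perRound[["POU1+BOB1"]], function(rs)
    composition(positionalComposition(rs))[5L, "A"], numeric(1))
  expect_true(all(diff(a5) > 0))
})

test_that("the simulation log accounts for every molecule and round", {
  sim <- deskSim()
  log <- sim$groundTruth$selectionLog
  expect_identical(nrow(log), 16L)  # 4 conditions x 4 rounds
  expect_true(all(log$selected <= log$input))
  expect_true(all(log$fraction > 0 & log$fraction < 1))
  for (cond in names(sim$readsets)) {
    expect_identical(length(inserts(sim$readsets[[cond]])), 20000L)
    asg <- sim$groundTruth$finalAssignments[[cond]]
    expect_identical(nrow(asg), 20000L)
    expect_true(all(c("monomer", "dimer", "ternary", "bestClass") %in%
                    names(asg)))
  }
})
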