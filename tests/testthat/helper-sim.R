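# Shared simulation cache so that several test files (and the acceptance
# suite) can reuse the same deterministic runs instead of re-simulating.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, maker) {
  if (is.null(.simCache[[key]])) .simCache[[key]] <- maker()
  .simCache[[key]]
}

# Desk-scale reference run: all four default conditions, library 2e4,
# 4 rounds, seed 1.
deskSim <- function() {
  cachedSim("desk", function() {
    runSelex(SimulationConfig(librarySize = 20000L, rounds = 4L, seed = 1L))
  })
}

# Study-scale run of the POU1 pair (monomer band vs ternary band) at the
# generator's default library size.
studySimPOU1 <- function() {
  cachedSim("study_pou1", function() {
    runSelex(SimulationConfig(librarySize = 150000L, rounds = 4L, seed = 1L,
                              conditions = defaultConditions()[1:2, ]),
             keepRounds = FALSE)
  })
}

cachedCensus <- function(readset) {
  key <- paste0("census_", condition(readset), "_",
                length(inserts(readset)))
  cachedSim(key, function() patternCensus(readset))
}
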