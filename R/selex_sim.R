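#' One round of band-specific selection
#'
#' Each molecule is first partitioned to exactly one band — a molecule runs at
#' a single mobility in a gel lane — by sampling among the monomer, dimer and
#' ternary channels proportionally to their weights (molecules with all
#' channels at 0 stay unbound).  A molecule assigned to the requested band is
#' then retained with the occupancy probability `a / (a + stringency)`, where
#' `a` is that channel's affinity.  Uses the current R random-number state, so
#' results are deterministic after `set.seed()`.
#'
#' @param pool character vector of inserts.
#' @param model a [BindingModel-class].
#' @param bob1 coactivator present in the reaction?
#' @param band which band is excised: "monomer", "dimer" or "ternary".
#' @param stringency occupancy scale s (> 0).
#' @return list with `selected` (retained inserts), and `assignments`, a
#'   data.frame(band, affinity, retained) over the input pool.
#' @export
selectRound <- function(pool, model, bob1 = FALSE,
                        band = c("monomer", "dimer", "ternary"),
                        stringency = 1) {
  band <- match.arg(band)
  stopifnot(length(pool) > 0L, stringency > 0)
  ch <- channelAffinities(pool, model, bob1 = bob1)
  W <- cbind(ch$monomer, ch$dimer, ch$ternary)
  tot <- rowSums(W)
  n <- length(pool)
  u <- stats::runif(n) * tot
  bandIdx <- 1L + (u > W[, 1L]) + (u > W[, 1L] + W[, 2L])
  bandIdx[tot == 0] <- 0L
  reqIdx <- match(band, c("monomer", "dimer", "ternary"))
  inBand <- bandIdx == reqIdx
  a <- rep(0, n)
  a[inBand] <- W[cbind(which(inBand), reqIdx)]
  retained <- inBand & (stats::runif(n) < a / (a + stringency))
  if (!any(retained))
    stop("simulation collapse: no molecule survived selection in the '",
         band, "' band")
  assignments <- data.frame(
    band = c("unbound", "monomer", "dimer", "ternary")[bandIdx + 1L],
    affinity = a, retained = retained, stringsAsFactors = FALSE)
  list(selected = pool[retained], assignments = assignments)
}

#' PCR amplification of a selected pool
#'
#' Multinomial resampling with replacement back to `targetSize` molecules.
#' By default no sequence errors are introduced; a per-base substitution rate
#' can be switched on.
#'
#' @param selected character vector of inserts (non-empty).
#' @param targetSize pool size after amplification.
#' @param errorRate per-base substitution probability (default 0).
#' @return character vector of `targetSize` inserts.
#' @export
amplifyPool <- function(selected, targetSize, errorRate = 0) {
  stopifnot(length(selected) > 0L, targetSize >= 1L)
  out <- selected[sample.int(length(selected), targetSize, replace = TRUE)]
  if (errorRate > 0) {
    L <- nchar(out[1L])
    nerr <- stats::rbinom(1L, targetSize * L, errorRate)
    if (nerr > 0L) {
      pos <- sample.int(targetSize * L, nerr)
      readIdx <- (pos - 1L) %/% L + 1L
      baseIdx <- (pos - 1L) %% L + 1L
      for (j in seq_len(nerr)) {
        old <- substr(out[readIdx[j]], baseIdx[j], baseIdx[j])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(out[readIdx[j]], baseIdx[j], baseIdx[j]) <- new
      }
    }
  }
  out
}

#' Run a full in silico EMSA-SELEX experiment
#'
#' Draws an initial library uniformly at random over the 4^L insert space and
#' subjects it, independently per condition, to `rounds` cycles of band
#' partitioning, occupancy selection and PCR amplification.  All randomness
#' derives from the config seed; each condition uses a child seed derived
#' from it (`seed + 7919 * condition index`), so conditions are reproducible
#' independently of one another.
#'
#' @param config a [SimulationConfig-class].
#' @param keepRounds keep the per-round pools (default TRUE)?
#' @return list with elements
#'   \describe{
#'     \item{readsets}{named list of final-round [SelexReadSet-class]s.}
#'     \item{perRound}{per condition, a list of [SelexReadSet-class]s, one per
#'       round (present when `keepRounds = TRUE`).}
#'     \item{groundTruth}{list with the model, the per-round selection log
#'       (condition, round, input, selected, fraction) and the final-pool
#'       channel assignments per condition.}
#'     \item{config}{the config echo.}
#'   }
#' @examples
#' cfg <- SimulationConfig(librarySize = 500, rounds = 1,
#'                         conditions = defaultConditions()[1, ])
#' sim <- runSelex(cfg)
#' sim$readsets[["POU1"]]
#' @export
runSelex <- function(config, keepRounds = TRUE) {
  methods::validObject(config)
  set.seed(config@seed)
  L <- config@insertLength
  n0 <- config@librarySize
  initial <- drawRandomLibrary(n0, L)
  readsets <- list()
  perRound <- list()
  log <- list()
  finalAssignments <- list()
  conds <- config@conditions
  for (i in seq_len(nrow(conds))) {
    cond <- conds$condition[i]
    set.seed(config@seed + 7919L * i)
    pool <- initial
    roundSets <- list()
    for (r in seq_len(config@rounds)) {
      sel <- selectRound(pool, config@model, bob1 = conds$bob1[i],
                         band = conds$band[i],
                         stringency = config@stringency)
      log[[length(log) + 1L]] <- data.frame(
        condition = cond, round = r, input = length(pool),
        selected = length(sel$selected),
        fraction = length(sel$selected) / length(pool),
        stringsAsFactors = FALSE)
      pool <- amplifyPool(sel$selected, config@pcrCopyTarget)
      if (keepRounds)
        roundSets[[r]] <- SelexReadSet(
          pool, condition = paste0(cond, "_r", r),
          factorName = conds$factorName[i], bob1 = conds$bob1[i],
          band = conds$band[i], insertLength = L)
    }
    readsets[[cond]] <- SelexReadSet(
      pool, condition = cond, factorName = conds$factorName[i],
      bob1 = conds$bob1[i], band = conds$band[i], insertLength = L)
    if (keepRounds) perRound[[cond]] <- roundSets
    finalAssignments[[cond]] <-
      channelAffinities(pool, config@model, bob1 = conds$bob1[i])
  }
  list(
    readsets = readsets,
    perRound = if (keepRounds) perRound else NULL,
    groundTruth = list(
      model = config@model,
      selectionLog = do.call(rbind, log),
      finalAssignments = finalAssignments),
    config = config
  )
}

#' Draw a uniform random insert library
#'
#' @param n number of molecules.
#' @param insertLength insert length (nt).
#' @return character vector of random A/C/G/T strings.
#' @export
drawRandomLibrary <- function(n, insertLength = 35L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * insertLength,
                     replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write a read set as raw flanked reads
#'
#' Re-attaches the constant flanks around every insert and writes FASTQ (with
#' constant qualities) or FASTA with deterministic record ids.  With the
#' default flanks each record is 18 + 35 + 19 = 72 nt, and trimming the file
#' with the matching [TrimPolicy()] recovers every insert exactly.
#'
#' @param readset a [SelexReadSet-class].
#' @param path output file.
#' @param flank5,flank3 constant flanks (defaults match [TrimPolicy()]).
#' @param format "fastq" (default) or "fasta".
#' @return `path`, invisibly.
#' @export
emitRawReads <- function(readset, path,
                         flank5 = "ACGACGCTCTTCCGATCT",
                         flank3 = "GATCGGAAGAGCACACGTC",
                         format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ins <- as.character(readset@inserts)
  seqs <- if (length(ins))
    Biostrings::DNAStringSet(paste0(flank5, ins, flank3))
  else Biostrings::DNAStringSet()
  if (length(seqs))
    names(seqs) <- sprintf("%s_read%06d", gsub("[^A-Za-z0-9+_.-]", "_",
                                               readset@condition),
                           seq_along(seqs))
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}
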