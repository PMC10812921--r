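#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement IUPAC_CODE_MAP
#'   vmatchPattern vcountPattern matchPattern readDNAStringSet writeXStringSet
#'   BStringSet width alphabetFrequency mergeIUPACLetters startIndex endIndex
#' @importFrom IRanges elementNROWS
#' @importFrom S4Vectors mcols
#' @importFrom stats runif rbinom rnorm cor sd setNames
#' @importFrom utils write.table read.delim head
#' @importFrom tools md5sum file_ext
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TrimPolicy: how raw SELEX reads are reduced to fixed-length inserts
#'
#' A raw SELEX read is a random insert embedded between two constant adapter
#' flanks.  Trimming anchors on the terminal `anchorLength` bases of the 5'
#' flank and the leading `anchorLength` bases of the 3' flank, each allowing up
#' to `maxAnchorMismatches` mismatches, and accepts the enclosed insert only if
#' it has exactly `requiredInsertLength` bases and no ambiguity codes.
#'
#' @slot flank5 constant 5' flank sequence.
#' @slot flank3 constant 3' flank sequence.
#' @slot anchorLength number of flank bases used as the anchor (>= 6).
#' @slot maxAnchorMismatches mismatches tolerated per anchor.
#' @slot requiredInsertLength accepted insert length (nt).
#' @exportClass TrimPolicy
setClass("TrimPolicy",
  representation(
    flank5 = "character",
    flank3 = "character",
    anchorLength = "integer",
    maxAnchorMismatches = "integer",
    requiredInsertLength = "integer"
  )
)

setValidity("TrimPolicy", function(object) {
  msg <- character(0)
  if (object@anchorLength < 6L)
    msg <- c(msg, "anchorLength must be >= 6")
  if (object@anchorLength > nchar(object@flank5) ||
      object@anchorLength > nchar(object@flank3))
    msg <- c(msg, "anchorLength must not exceed either flank length")
  if (object@maxAnchorMismatches < 0L)
    msg <- c(msg, "maxAnchorMismatches must be >= 0")
  if (object@requiredInsertLength <= 0L)
    msg <- c(msg, "requiredInsertLength must be > 0")
  if (!all(strsplit(paste0(object@flank5, object@flank3), "")[[1]] %in%
           c("A", "C", "G", "T")))
    msg <- c(msg, "flanks must be plain A/C/G/T sequences")
  if (length(msg)) msg else TRUE
})

#' Construct a TrimPolicy
#'
#' Defaults correspond to the 72-nt SELEX oligonucleotide design
#' 5'-ACGACGCTCTTCCGATCT-N35-GATCGGAAGAGCACACGTC-3'.
#'
#' @param flank5,flank3 constant flank sequences.
#' @param anchorLength anchor width in bases (default 8).
#' @param maxAnchorMismatches mismatches tolerated per anchor (default 1).
#' @param requiredInsertLength accepted insert length (default 35).
#' @return A [TrimPolicy-class] object.
#' @examples
#' TrimPolicy()
#' @export
TrimPolicy <- function(flank5 = "ACGACGCTCTTCCGATCT",
                       flank3 = "GATCGGAAGAGCACACGTC",
                       anchorLength = 8L,
                       maxAnchorMismatches = 1L,
                       requiredInsertLength = 35L) {
  new("TrimPolicy",
      flank5 = toupper(flank5), flank3 = toupper(flank3),
      anchorLength = as.integer(anchorLength),
      maxAnchorMismatches = as.integer(maxAnchorMismatches),
      requiredInsertLength = as.integer(requiredInsertLength))
}

#' SelexReadSet: fixed-length inserts selected in one EMSA band
#'
#' Container for the trimmed inserts of one condition/band: which POU factor
#' was in the binding reaction, whether the BOB1 coactivator was present, and
#' which electrophoretic band (monomer, dimer or ternary complex) was excised.
#'
#' @slot inserts a [Biostrings::DNAStringSet] of equal-length A/C/G/T inserts.
#' @slot condition unique label for the set (e.g. "POU1+BOB1").
#' @slot factorName POU factor label ("POU1" or "POU2").
#' @slot bob1 logical, coactivator present in the binding reaction.
#' @slot band excised band class: "monomer", "dimer" or "ternary".
#' @slot insertLength common insert length (nt).
#' @exportClass SelexReadSet
setClass("SelexReadSet",
  representation(
    inserts = "DNAStringSet",
    condition = "character",
    factorName = "character",
    bob1 = "logical",
    band = "character",
    insertLength = "integer"
  )
)

setValidity("SelexReadSet", function(object) {
  msg <- character(0)
  if (length(object@condition) != 1L || !nzchar(object@condition))
    msg <- c(msg, "condition must be a single non-empty label")
  if (!object@band %in% c("monomer", "dimer", "ternary"))
    msg <- c(msg, "band must be one of monomer/dimer/ternary")
  if (length(object@inserts) > 0L) {
    if (!all(Biostrings::width(object@inserts) == object@insertLength))
      msg <- c(msg, "all inserts must have length == insertLength")
    af <- Biostrings::alphabetFrequency(object@inserts, baseOnly = TRUE)
    if (any(af[, "other"] > 0L))
      msg <- c(msg, "inserts must contain only A/C/G/T after trimming")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SelexReadSet
#'
#' @param inserts character vector or `DNAStringSet` of equal-length inserts.
#' @param condition set label, unique within an experiment.
#' @param factorName "POU1" or "POU2".
#' @param bob1 was BOB1 present in the binding reaction?
#' @param band excised EMSA band: "monomer", "dimer" or "ternary".
#' @param insertLength expected insert length (default 35).
#' @return A [SelexReadSet-class].
#' @examples
#' SelexReadSet(c("ATGCAAAT", "ATGCTAAT"), "toy", insertLength = 8)
#' @export
SelexReadSet <- function(inserts, condition = "sample", factorName = "POU1",
                         bob1 = FALSE, band = "monomer", insertLength = 35L) {
  if (!methods::is(inserts, "DNAStringSet"))
    inserts <- Biostrings::DNAStringSet(toupper(as.character(inserts)))
  new("SelexReadSet", inserts = inserts, condition = condition,
      factorName = factorName, bob1 = bob1, band = band,
      insertLength = as.integer(insertLength))
}

setMethod("show", "SelexReadSet", function(object) {
  cat("SelexReadSet '", object@condition, "': ",
      length(object@inserts), " inserts of ", object@insertLength, " nt (",
      object@factorName, if (object@bob1) "+BOB1" else "", ", ",
      object@band, " band)\n", sep = "")
})

#' DegeneratePattern: an IUPAC census word
#'
#' A degenerate k-mer used to tabulate binding-site variants.  The default,
#' ANNNNAAN, fixes the highly conserved adenines at octamer positions 1, 6 and
#' 7 while leaving positions 2-5 and 8 free, which suppresses double counting
#' of frame-shifted and reverse-complement occurrences.
#'
#' @slot word IUPAC string.
#' @slot k pattern length.
#' @exportClass DegeneratePattern
setClass("DegeneratePattern",
  representation(word = "character", k = "integer"))

setValidity("DegeneratePattern", function(object) {
  msg <- character(0)
  letters <- strsplit(object@word, "")[[1]]
  if (!all(letters %in% names(Biostrings::IUPAC_CODE_MAP)))
    msg <- c(msg, "word must consist of IUPAC nucleotide codes")
  if (object@k != nchar(object@word))
    msg <- c(msg, "k must equal nchar(word)")
  if (length(msg)) msg else TRUE
})

#' Construct a DegeneratePattern
#'
#' @param word IUPAC word (default "ANNNNAAN").
#' @return A [DegeneratePattern-class].
#' @examples
#' patternCardinality(DegeneratePattern("ANNNNAAN"))  # 1024
#' @export
DegeneratePattern <- function(word = "ANNNNAAN") {
  word <- toupper(word)
  new("DegeneratePattern", word = word, k = nchar(word))
}

setMethod("show", "DegeneratePattern", function(object) {
  cat("DegeneratePattern ", object@word, " (k = ", object@k,
      ", ", patternCardinality(object), " concrete words)\n", sep = "")
})

#' FrequencyTable: per-word counts and relative frequencies for one set
#'
#' Counts of concrete census-pattern words in one read set, together with
#' relative frequencies expressed as percentages of all matched words (so the
#' frequencies sum to 100 whenever anything matched).  The matched-read
#' fraction is reported separately via `matchedReads`/`totalReads`.
#'
#' @slot pattern the [DegeneratePattern-class] that was counted.
#' @slot setLabel condition label of the counted set.
#' @slot counts named integer vector (words with count > 0).
#' @slot relFreq named numeric vector of percentages, same names as counts.
#' @slot matchedReads number of reads contributing at least one occurrence.
#' @slot totalReads reads in the set.
#' @exportClass FrequencyTable
setClass("FrequencyTable",
  representation(
    pattern = "DegeneratePattern",
    setLabel = "character",
    counts = "integer",
    relFreq = "numeric",
    matchedReads = "integer",
    totalReads = "integer"
  )
)

setValidity("FrequencyTable", function(object) {
  msg <- character(0)
  if (length(object@counts) != length(object@relFreq) ||
      !identical(names(object@counts), names(object@relFreq)))
    msg <- c(msg, "counts and relFreq must share names")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@counts) &&
      !all(wordMatchesPattern(names(object@counts), object@pattern)))
    msg <- c(msg, "every counted word must match the pattern")
  if (sum(object@counts) > 0L &&
      abs(sum(object@relFreq) - 100) > 1e-9)
    msg <- c(msg, "relative frequencies must sum to 100%")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable for ", object@pattern@word, " in '", object@setLabel,
      "': ", length(object@counts), " distinct words, ",
      object@matchedReads, "/", object@totalReads, " reads matched\n",
      sep = "")
  if (length(object@counts)) {
    top <- utils::head(order(-object@relFreq, names(object@relFreq)), 5L)
    for (i in top)
      cat(sprintf("  %s %8d  %6.2f%%\n", names(object@counts)[i],
                  object@counts[i], object@relFreq[i]))
  }
})

#' PositionalComposition: per-position base percentages of matched words
#'
#' @slot composition k x 4 matrix of percentages (columns A, C, G, T); each
#'   row sums to 100 when `nSites > 0`, otherwise the matrix is NULL.
#' @slot nSites number of matched words the matrix was computed over.
#' @exportClass PositionalComposition
setClass("PositionalComposition",
  representation(composition = "matrixOrNULL", nSites = "integer"))

setValidity("PositionalComposition", function(object) {
  if (object@nSites > 0L) {
    if (is.null(object@composition))
      return("composition must be present when nSites > 0")
    if (ncol(object@composition) != 4L ||
        !identical(colnames(object@composition), c("A", "C", "G", "T")))
      return("composition must have columns A, C, G, T")
    if (any(abs(rowSums(object@composition) - 100) > 1e-9))
      return("each position's percentages must sum to 100")
  }
  TRUE
})

setMethod("show", "PositionalComposition", function(object) {
  cat("PositionalComposition over", object@nSites, "sites\n")
  if (object@nSites > 0L) print(round(object@composition, 1))
})

#' MotifDefinition: a POU-element consensus with optional internal gap
#'
#' Describes one motif class: a left IUPAC half-site, an optional internal gap
#' of `gapMin`..`gapMax` bases drawn from `gapAlphabet`, and a right IUPAC
#' half-site.  Monomeric motifs have an empty right part and zero gap.
#' `clampPermissive` records whether the bound complex can recruit the BOB1
#' coactivator (the MORE dimer configuration cannot).
#'
#' @slot name motif label.
#' @slot left left half-site (IUPAC).
#' @slot gapMin,gapMax inclusive gap-length range.
#' @slot gapAlphabet allowed gap bases.
#' @slot right right half-site (IUPAC), "" for monomer motifs.
#' @slot complexClass "monomer" or "dimer".
#' @slot clampPermissive can BOB1 clamp onto the complex?
#' @exportClass MotifDefinition
setClass("MotifDefinition",
  representation(
    name = "character",
    left = "character",
    gapMin = "integer",
    gapMax = "integer",
    gapAlphabet = "character",
    right = "character",
    complexClass = "character",
    clampPermissive = "logical"
  )
)

setValidity("MotifDefinition", function(object) {
  msg <- character(0)
  if (object@gapMin < 0L) msg <- c(msg, "gapMin must be >= 0")
  if (object@gapMax < object@gapMin) msg <- c(msg, "gapMax must be >= gapMin")
  if (!object@complexClass %in% c("monomer", "dimer"))
    msg <- c(msg, "complexClass must be monomer or dimer")
  if (object@complexClass == "monomer" &&
      (nzchar(object@right) || object@gapMax > 0L))
    msg <- c(msg, "monomer motifs must have empty right part and zero gap")
  if (object@gapMax > 0L && !length(object@gapAlphabet))
    msg <- c(msg, "gapped motifs need a non-empty gapAlphabet")
  if (length(msg)) msg else TRUE
})

#' Construct a MotifDefinition
#'
#' @param name motif label.
#' @param left,right IUPAC half-sites (right = "" for monomers).
#' @param gapMin,gapMax inclusive gap-length range (default 0, 0).
#' @param gapAlphabet allowed gap bases (default c("A","T")).
#' @param complexClass "monomer" or "dimer".
#' @param clampPermissive can BOB1 join the complex on this motif?
#' @return A [MotifDefinition-class].
#' @export
MotifDefinition <- function(name, left, right = "", gapMin = 0L, gapMax = 0L,
                            gapAlphabet = c("A", "T"),
                            complexClass = "monomer",
                            clampPermissive = TRUE) {
  new("MotifDefinition", name = name, left = toupper(left),
      right = toupper(right), gapMin = as.integer(gapMin),
      gapMax = as.integer(gapMax), gapAlphabet = toupper(gapAlphabet),
      complexClass = complexClass, clampPermissive = clampPermissive)
}

setMethod("show", "MotifDefinition", function(object) {
  gap <- if (object@gapMax > 0L)
    paste0("[", paste(object@gapAlphabet, collapse = "/"), "]{",
           object@gapMin, ",", object@gapMax, "}") else ""
  cat("MotifDefinition ", object@name, ": ", object@left, gap, object@right,
      " (", object@complexClass,
      if (object@clampPermissive) ", clamp-permissive" else
        ", clamp-refractory",
      ")\n", sep = "")
})

#' Psam: position-specific affinity matrix
#'
#' Multiplicative relative affinities, one row per binding-site position and
#' one column per base; the best base at each position has affinity 1, so the
#' consensus word scores exactly 1 under the product model.
#'
#' @slot affinities k x 4 numeric matrix, columns A, C, G, T.
#' @exportClass Psam
setClass("Psam", representation(affinities = "matrix"))

setValidity("Psam", function(object) {
  m <- object@affinities
  if (ncol(m) != 4L || !identical(colnames(m), c("A", "C", "G", "T")))
    return("affinities must have columns A, C, G, T")
  if (any(m < 0)) return("affinities must be non-negative")
  if (any(abs(apply(m, 1L, max) - 1) > 1e-12))
    return("the best base at each position must have affinity 1")
  TRUE
})

#' Construct a Psam
#'
#' @param affinities k x 4 matrix (columns A, C, G, T), row maxima 1.
#' @return A [Psam-class].
#' @export
Psam <- function(affinities) {
  colnames(affinities) <- c("A", "C", "G", "T")
  new("Psam", affinities = affinities)
}

setMethod("show", "Psam", function(object) {
  cat("Psam over", nrow(object@affinities), "positions (consensus",
      psamConsensus(object), ")\n")
  print(round(object@affinities, 3))
})

#' ClampRule: how the BOB1 coactivator reweights a monomer site
#'
#' The coactivator acts as a molecular clamp on the POU-DNA complex: binding
#' is stabilised by a multiplicative `clampGain` (> 1), but only on sites whose
#' sequence the clamp tolerates.  `multipliers` is a k x 4 matrix applied
#' elementwise on top of the Psam: 0 forbids a base at a position (default:
#' T at position 5), values in (0,1) disfavour it (default: T at positions 3
#' and 4 at 0.25), and 1 leaves it unchanged.
#'
#' @slot clampGain stabilisation factor (> 1) for clamp-permissive complexes.
#' @slot multipliers k x 4 non-negative matrix, columns A, C, G, T.
#' @exportClass ClampRule
setClass("ClampRule",
  representation(clampGain = "numeric", multipliers = "matrix"))

setValidity("ClampRule", function(object) {
  if (object@clampGain <= 1) return("clampGain must be > 1")
  m <- object@multipliers
  if (ncol(m) != 4L || !identical(colnames(m), c("A", "C", "G", "T")))
    return("multipliers must have columns A, C, G, T")
  if (any(m < 0)) return("multipliers must be non-negative")
  TRUE
})

#' Construct a ClampRule
#'
#' @param clampGain stabilisation factor (default 5).
#' @param multipliers k x 4 matrix; by default position 5 forbids T (weight 0)
#'   and positions 3 and 4 disfavour T (weight 0.25), all else 1.
#' @param k site length used to build the default multipliers (default 8).
#' @return A [ClampRule-class].
#' @export
ClampRule <- function(clampGain = 5, multipliers = NULL, k = 8L) {
  if (is.null(multipliers)) {
    multipliers <- matrix(1, nrow = k, ncol = 4L,
                          dimnames = list(NULL, c("A", "C", "G", "T")))
    multipliers[5L, "T"] <- 0
    multipliers[3L, "T"] <- 0.25
    multipliers[4L, "T"] <- 0.25
  }
  colnames(multipliers) <- c("A", "C", "G", "T")
  new("ClampRule", clampGain = clampGain, multipliers = multipliers)
}

setMethod("show", "ClampRule", function(object) {
  cat("ClampRule: gain", object@clampGain, "\n")
  alt <- which(object@multipliers != 1, arr.ind = TRUE)
  if (nrow(alt)) {
    for (i in seq_len(nrow(alt)))
      cat("  position ", alt[i, 1L], " ",
          colnames(object@multipliers)[alt[i, 2L]], " x ",
          object@multipliers[alt[i, 1L], alt[i, 2L]], "\n", sep = "")
  }
})

#' BindingModel: ground-truth binding rules for the simulator
#'
#' @slot psam monomer-site [Psam-class].
#' @slot clamp [ClampRule-class] for ternary-complex formation.
#' @slot dimerMotifs list of dimeric [MotifDefinition-class]s (MORE family,
#'   PORE).
#' @slot dimerAffinities named relative affinities of the dimer motifs.
#' @exportClass BindingModel
setClass("BindingModel",
  representation(
    psam = "Psam",
    clamp = "ClampRule",
    dimerMotifs = "list",
    dimerAffinities = "numeric"
  )
)

setValidity("BindingModel", function(object) {
  msg <- character(0)
  nm <- vapply(object@dimerMotifs, function(m) m@name, character(1))
  if (!all(nm %in% names(object@dimerAffinities)))
    msg <- c(msg, "every dimer motif needs a named affinity")
  if (any(object@dimerAffinities < 0))
    msg <- c(msg, "dimer affinities must be non-negative")
  if (!all(vapply(object@dimerMotifs, function(m)
      m@complexClass == "dimer", logical(1))))
    msg <- c(msg, "dimerMotifs must all have complexClass 'dimer'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BindingModel", function(object) {
  cat("BindingModel: ", nrow(object@psam@affinities),
      "-mer Psam (consensus ", psamConsensus(object@psam), "), clamp gain ",
      object@clamp@clampGain, ", ", length(object@dimerMotifs),
      " dimer motifs\n", sep = "")
})

#' SimulationConfig: one full in silico EMSA-SELEX experiment
#'
#' @slot librarySize molecules in the initial random library and after each
#'   amplification.
#' @slot insertLength random-insert length (nt).
#' @slot rounds selection rounds (default 4).
#' @slot conditions data.frame with columns condition, factorName, bob1, band.
#' @slot stringency occupancy scale s in the retention probability a/(a+s).
#' @slot pcrCopyTarget pool size restored by each amplification.
#' @slot seed integer seed fixing all randomness end-to-end.
#' @slot model the ground-truth [BindingModel-class].
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    librarySize = "integer",
    insertLength = "integer",
    rounds = "integer",
    conditions = "data.frame",
    stringency = "numeric",
    pcrCopyTarget = "integer",
    seed = "integer",
    model = "BindingModel"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@librarySize < 1L) msg <- c(msg, "librarySize must be >= 1")
  if (object@rounds < 0L) msg <- c(msg, "rounds must be >= 0")
  need <- c("condition", "factorName", "bob1", "band")
  if (!all(need %in% names(object@conditions)))
    msg <- c(msg, "conditions needs columns condition/factorName/bob1/band")
  else {
    if (anyDuplicated(object@conditions$condition))
      msg <- c(msg, "condition labels must be unique")
    if (!all(object@conditions$band %in% c("monomer", "dimer", "ternary")))
      msg <- c(msg, "band must be monomer/dimer/ternary")
    if (any(object@conditions$band == "ternary" & !object@conditions$bob1))
      msg <- c(msg, "a ternary band requires bob1 = TRUE")
  }
  if (object@stringency <= 0) msg <- c(msg, "stringency must be > 0")
  if (length(msg)) msg else TRUE
})

#' Default experimental design: four conditions, band-matched
#'
#' POU1 and POU2 alone are followed through their monomer band; with BOB1 the
#' ternary-complex band is excised instead, mirroring the band layout of the
#' gel-shift selection.
#'
#' @return data.frame with columns condition, factorName, bob1, band.
#' @export
defaultConditions <- function() {
  data.frame(
    condition = c("POU1", "POU1+BOB1", "POU2", "POU2+BOB1"),
    factorName = c("POU1", "POU1", "POU2", "POU2"),
    bob1 = c(FALSE, TRUE, FALSE, TRUE),
    band = c("monomer", "ternary", "monomer", "ternary"),
    stringsAsFactors = FALSE
  )
}

#' Construct a SimulationConfig
#'
#' @param librarySize initial library size (default 150000, the scale of the
#'   sequenced sets the design emulates).
#' @param insertLength insert length (default 35).
#' @param rounds selection rounds (default 4).
#' @param conditions design table (default [defaultConditions()]).
#' @param stringency occupancy scale (default 1).
#' @param pcrCopyTarget pool size after amplification (default librarySize).
#' @param seed integer seed (default 1).
#' @param model ground-truth model (default [defaultBindingModel()]).
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(librarySize = 150000L, insertLength = 35L,
                             rounds = 4L, conditions = defaultConditions(),
                             stringency = 1, pcrCopyTarget = librarySize,
                             seed = 1L, model = defaultBindingModel()) {
  new("SimulationConfig",
      librarySize = as.integer(librarySize),
      insertLength = as.integer(insertLength),
      rounds = as.integer(rounds), conditions = conditions,
      stringency = stringency, pcrCopyTarget = as.integer(pcrCopyTarget),
      seed = as.integer(seed), model = model)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: library ", object@librarySize, " x ",
      object@insertLength, " nt, ", object@rounds, " rounds, ",
      nrow(object@conditions), " conditions, stringency ",
      object@stringency, ", seed ", object@seed, "\n", sep = "")
})
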