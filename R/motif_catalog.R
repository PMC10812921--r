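#' The default motif catalog: octamer, MORE family, PORE
#'
#' Five motif classes characterised for POU-domain complexes:
#' \itemize{
#'   \item \strong{octamer} ATGCAAAT — the canonical monomeric site;
#'     clamp-permissive (BOB1 can join the complex).
#'   \item \strong{MORE}, \strong{MORE+1}, \strong{MORE+2} — the dimeric
#'     element ATG[C/A]AT + 0/1/2 A/T gap bases + AT[T/G]CAT, split into three
#'     fixed-gap variants; the MORE dimer configuration is refractory to BOB1.
#'   \item \strong{PORE} ATTTGAAATGCAAAT (15 nt) — the palindromic dimeric
#'     element; clamp-permissive.
#' }
#'
#' @return list of five [MotifDefinition-class] objects.
#' @examples
#' names(defaultMotifCatalog())
#' @export
defaultMotifCatalog <- function() {
  catalog <- list(
    MotifDefinition("octamer", "ATGCAAAT", complexClass = "monomer",
                    clampPermissive = TRUE),
    MotifDefinition("MORE", "ATGMAT", right = "ATKCAT",
                    gapMin = 0L, gapMax = 0L, gapAlphabet = c("A", "T"),
                    complexClass = "dimer", clampPermissive = FALSE),
    MotifDefinition("MORE+1", "ATGMAT", right = "ATKCAT",
                    gapMin = 1L, gapMax = 1L, gapAlphabet = c("A", "T"),
                    complexClass = "dimer", clampPermissive = FALSE),
    MotifDefinition("MORE+2", "ATGMAT", right = "ATKCAT",
                    gapMin = 2L, gapMax = 2L, gapAlphabet = c("A", "T"),
                    complexClass = "dimer", clampPermissive = FALSE),
    MotifDefinition("PORE", "ATTTGAAATGCAAAT", complexClass = "dimer",
                    clampPermissive = TRUE)
  )
  stats::setNames(catalog, vapply(catalog, function(m) m@name, character(1)))
}

# Logical vector: which inserts contain >= 1 match of the motif?
# Also returns total occurrence count and example matched substrings.
.scanMotifHits <- function(dna, motif, strandMode, maxMismatch = 0L) {
  pats <- motifIupacWords(motif)
  n <- length(dna)
  hit <- rep(FALSE, n)
  total <- 0L
  examples <- character(0)
  for (pat in pats) {
    cnt <- Biostrings::vcountPattern(pat, dna, fixed = FALSE,
                                     max.mismatch = maxMismatch)
    if (strandMode == "both") {
      rcpat <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(pat)))
      cnt <- cnt + Biostrings::vcountPattern(rcpat, dna, fixed = FALSE,
                                             max.mismatch = maxMismatch)
    }
    total <- total + sum(cnt)
    newhit <- cnt > 0L
    if (length(examples) < 3L && any(newhit)) {
      i <- which(newhit)[1L]
      m <- Biostrings::matchPattern(pat, dna[[i]], fixed = FALSE,
                                    max.mismatch = maxMismatch)
      if (length(m))
        examples <- unique(c(examples, as.character(m[1L])))
    }
    hit <- hit | newhit
  }
  list(hit = hit, total = total, examples = utils::head(examples, 3L))
}

#' Scan one motif against a read set
#'
#' A read matches if any window, on either strand for `strandMode = "both"`,
#' realises left half-site + gap (length within the gap range, bases from the
#' gap alphabet) + right half-site.  The reported frequency is the percentage
#' of reads with at least one match, i.e. computed over the whole set.
#'
#' @param readset a [SelexReadSet-class].
#' @param motif a [MotifDefinition-class].
#' @param strandMode "both" (default) or "forward".
#' @param maxMismatch per-window mismatch budget (default 0, exact consensus
#'   matching).
#' @return list with elements `name`, `frequency` (percent of reads),
#'   `matchedReads`, `totalReads`, `matchCount` (total occurrences) and
#'   `examples` (up to three matched substrings).
#' @examples
#' rs <- SelexReadSet("CCATGCATATGCATCC", "toy", insertLength = 16)
#' scanMotif(rs, defaultMotifCatalog()$MORE)$frequency
#' @export
scanMotif <- function(readset, motif, strandMode = c("both", "forward"),
                      maxMismatch = 0L) {
  strandMode <- match.arg(strandMode)
  methods::validObject(motif)
  if (length(readset@inserts) &&
      readset@insertLength < motifSpan(motif))
    stop("insert length ", readset@insertLength,
         " is shorter than the maximal motif span ", motifSpan(motif))
  n <- length(readset@inserts)
  if (n == 0L)
    return(list(name = motif@name, frequency = 0, matchedReads = 0L,
                totalReads = 0L, matchCount = 0L, examples = character(0)))
  res <- .scanMotifHits(readset@inserts, motif, strandMode, maxMismatch)
  list(name = motif@name,
       frequency = 100 * sum(res$hit) / n,
       matchedReads = as.integer(sum(res$hit)),
       totalReads = as.integer(n),
       matchCount = as.integer(res$total),
       examples = res$examples)
}

#' Motif frequencies across several read sets
#'
#' One row per motif, one column per set; each cell is the percentage of
#' reads in that set containing at least one match of the motif, computed
#' independently per cell.
#'
#' @param readsets list of [SelexReadSet-class] objects sharing an insert
#'   length.
#' @param catalog list of [MotifDefinition-class] (default
#'   [defaultMotifCatalog()]).
#' @param strandMode "both" (default) or "forward".
#' @param maxMismatch per-window mismatch budget (default 0).
#' @return numeric matrix, motifs x sets, in catalog and input order.
#' @export
motifFrequencyMatrix <- function(readsets, catalog = defaultMotifCatalog(),
                                 strandMode = c("both", "forward"),
                                 maxMismatch = 0L) {
  strandMode <- match.arg(strandMode)
  lens <- unique(vapply(readsets, function(r) r@insertLength, integer(1)))
  if (length(lens) > 1L)
    stop("all read sets must share the same insert length")
  setNames <- vapply(readsets, function(r) r@condition, character(1))
  motifNames <- vapply(catalog, function(m) m@name, character(1))
  out <- matrix(NA_real_, nrow = length(catalog), ncol = length(readsets),
                dimnames = list(motifNames, setNames))
  for (i in seq_along(catalog))
    for (j in seq_along(readsets))
      out[i, j] <- scanMotif(readsets[[j]], catalog[[i]], strandMode,
                             maxMismatch)$frequency
  out
}
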