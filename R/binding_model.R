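#' Default position-specific affinity matrix for the POU monomer site
#'
#' Qualitative encoding of the octamer preferences A1 T2 G3 C4 A5 A6 A7 T8:
#' adenines at positions 1, 6 and 7 are near-obligatory, positions 2-5 and 8
#' are variable, and thymines at positions 3-5 are explicitly permissive for
#' the POU factor alone (they are penalised only by the coactivator clamp,
#' see [ClampRule()]).  Consensus ATGCAAAT scores exactly 1 under the product
#' model.
#'
#' @return A [Psam-class] of 8 positions.
#' @examples
#' siteAffinity("ATGCAAAT", defaultPsam())  # 1
#' @export
defaultPsam <- function() {
  m <- rbind(
    c(1.00, 0.05, 0.05, 0.10),  # A1 highly conserved
    c(0.40, 0.40, 0.30, 1.00),  # T2 preferred, substitutable
    c(0.25, 0.25, 1.00, 0.80),  # G3; T3 nearly neutral for POU alone
    c(0.35, 1.00, 0.15, 0.80),  # C4; T4 nearly neutral for POU alone
    c(1.00, 0.10, 0.10, 0.70),  # A5 preferred; T5 tolerated by POU alone
    c(1.00, 0.05, 0.05, 0.05),  # A6 highly conserved
    c(1.00, 0.05, 0.05, 0.05),  # A7 highly conserved
    c(0.60, 0.40, 0.40, 1.00)   # T8 variable
  )
  colnames(m) <- c("A", "C", "G", "T")
  Psam(m)
}

#' Consensus word of a Psam
#'
#' @param psam a [Psam-class].
#' @return the word of per-position best bases (ties broken A<C<G<T).
#' @export
psamConsensus <- function(psam) {
  paste0(c("A", "C", "G", "T")[apply(psam@affinities, 1L, which.max)],
         collapse = "")
}

#' Default ground-truth binding model
#'
#' Combines [defaultPsam()], the default [ClampRule()] (gain 5; T5 forbidden,
#' T3/T4 disfavoured at 0.25 in the ternary complex) and the dimeric motifs
#' of [defaultMotifCatalog()] with fixed relative affinities (MORE family
#' 0.7-0.8, PORE 0.5).  The same monomer matrix is shared by POU1 and POU2,
#' reflecting their near-identical site recognition.
#'
#' @param psam monomer Psam (default [defaultPsam()]).
#' @param clamp clamp rule (default [ClampRule()]).
#' @param dimerAffinities named affinities for MORE/MORE+1/MORE+2/PORE.
#' @return A [BindingModel-class].
#' @export
defaultBindingModel <- function(psam = defaultPsam(), clamp = ClampRule(),
                                dimerAffinities = c("MORE" = 0.8,
                                                    "MORE+1" = 0.7,
                                                    "MORE+2" = 0.7,
                                                    "PORE" = 0.5)) {
  catalog <- defaultMotifCatalog()
  dimers <- catalog[vapply(catalog, function(m)
    m@complexClass == "dimer", logical(1))]
  new("BindingModel", psam = psam, clamp = clamp,
      dimerMotifs = unname(dimers), dimerAffinities = dimerAffinities)
}

#' Relative affinity of a binding-site word under a Psam
#'
#' Product over positions of the per-base relative affinities; the consensus
#' word scores 1, any zero-weight base zeroes the site.
#'
#' @param words character vector of k-mers over A/C/G/T.
#' @param psam a [Psam-class].
#' @return numeric vector of affinities in `[0, 1]`.
#' @examples
#' siteAffinity(c("ATGCAAAT", "ATGCTAAT"), defaultPsam())
#' @export
siteAffinity <- function(words, psam) {
  pm <- psam@affinities
  k <- nrow(pm)
  if (!length(words)) return(numeric(0))
  if (any(nchar(words) != k))
    stop("all words must have length ", k)
  M <- encodeDNA(words, k)
  aff <- rep(1, length(words))
  for (p in seq_len(k))
    aff <- aff * pm[cbind(p, M[, p])]
  aff
}

# Best sliding-window score of each encoded insert under a k x 4 matrix.
# Returns list(score, offset) of the per-read best window.
.bestWindow <- function(M, pm) {
  n <- nrow(M)
  k <- nrow(pm)
  L <- ncol(M)
  best <- rep(-1, n)
  bestOff <- rep(NA_integer_, n)
  for (o in seq_len(L - k + 1L)) {
    s <- rep(1, n)
    for (p in seq_len(k))
      s <- s * pm[cbind(p, M[, o + p - 1L])]
    upd <- s > best
    best[upd] <- s[upd]
    bestOff[upd] <- o
  }
  list(score = best, offset = bestOff)
}

#' Channel affinities of a pool of inserts
#'
#' For every insert, computes the relative binding weight of the three EMSA
#' channels of the model:
#' \itemize{
#'   \item \strong{monomer}: best sliding-window Psam score over both strands;
#'   \item \strong{dimer}: highest configured affinity among MORE/PORE motifs
#'     present in the insert (either strand);
#'   \item \strong{ternary} (only when `bob1 = TRUE`): the coactivator clamps
#'     onto the monomer complex at its best site, so the channel weight is
#'     that site's Psam score times the clamp multipliers times the clamp
#'     gain; a PORE dimer can also recruit the clamp (PORE weight times
#'     gain), while the MORE configuration is refractory and contributes 0.
#' }
#'
#' @param inserts character vector or `DNAStringSet` of equal-length inserts.
#' @param model a [BindingModel-class].
#' @param bob1 is the coactivator present in the binding reaction?
#' @return data.frame with columns monomer, dimer, ternary, bestClass (the
#'   argmax channel, ties resolved monomer < dimer < ternary), bestSite (the
#'   best monomer window in site orientation).
#' @export
channelAffinities <- function(inserts, model, bob1 = FALSE) {
  if (methods::is(inserts, "DNAStringSet")) {
    dna <- inserts
    seqs <- as.character(inserts)
  } else {
    seqs <- toupper(as.character(inserts))
    dna <- Biostrings::DNAStringSet(seqs)
  }
  n <- length(seqs)
  if (n == 0L)
    return(data.frame(monomer = numeric(0), dimer = numeric(0),
                      ternary = numeric(0), bestClass = character(0),
                      bestSite = character(0), stringsAsFactors = FALSE))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("inserts must share one length")
  pm <- model@psam@affinities
  k <- nrow(pm)
  if (L < k) stop("inserts must be at least as long as the Psam")
  M <- encodeDNA(seqs, L)
  rseqs <- rcChar(seqs)
  Mr <- encodeDNA(rseqs, L)

  fwd <- .bestWindow(M, pm)
  rev <- .bestWindow(Mr, pm)
  useRev <- rev$score > fwd$score
  monomer <- ifelse(useRev, rev$score, fwd$score)
  off <- ifelse(useRev, rev$offset, fwd$offset)
  src <- ifelse(useRev, rseqs, seqs)
  bestSite <- substring(src, off, off + k - 1L)

  # ternary octamer channel: the clamp joins the monomer complex at its best
  # site, so the site's clamped weight (not a free max over windows) applies
  ternary <- rep(0, n)
  if (bob1) {
    cm <- pm * model@clamp@multipliers
    Msite <- encodeDNA(bestSite, k)
    clamped <- rep(1, n)
    for (p in seq_len(k))
      clamped <- clamped * cm[cbind(p, Msite[, p])]
    ternary <- model@clamp@clampGain * clamped
  }

  # dimer channel: best configured affinity among motifs present
  dimer <- rep(0, n)
  poreHit <- rep(FALSE, n)
  for (motif in model@dimerMotifs) {
    hit <- .scanMotifHits(dna, motif, "both")$hit
    aff <- model@dimerAffinities[[motif@name]]
    dimer <- pmax(dimer, ifelse(hit, aff, 0))
    if (bob1 && motif@clampPermissive)
      ternary <- pmax(ternary,
                      ifelse(hit, model@clamp@clampGain * aff, 0))
  }

  W <- cbind(monomer = monomer, dimer = dimer, ternary = ternary)
  bestClass <- colnames(W)[max.col(W, ties.method = "first")]
  data.frame(monomer = monomer, dimer = dimer, ternary = ternary,
             bestClass = bestClass, bestSite = bestSite,
             stringsAsFactors = FALSE)
}

#' Binding affinity and complex class of one insert
#'
#' Single-insert convenience wrapper around [channelAffinities()].
#'
#' @param insert one A/C/G/T string of length >= the Psam width.
#' @param model a [BindingModel-class].
#' @param bob1 is the coactivator present?
#' @return list with `affinity` (value of the strongest channel),
#'   `bestClass`, `bestSite` and the full `channels` vector.
#' @examples
#' readAffinity(paste0(strrep("C", 10), "ATGCAAAT", strrep("C", 17)),
#'              defaultBindingModel(), bob1 = TRUE)
#' @export
readAffinity <- function(insert, model, bob1 = FALSE) {
  ch <- channelAffinities(insert, model, bob1 = bob1)
  channels <- c(monomer = ch$monomer, dimer = ch$dimer,
                ternary = ch$ternary)
  list(affinity = unname(channels[ch$bestClass]),
       bestClass = ch$bestClass,
       bestSite = ch$bestSite,
       channels = channels)
}

#' Ground-truth word weight in a given band channel
#'
#' The simulator's true relative weight of an isolated site word: the Psam
#' product for the monomer channel, or the clamp-reweighted product times the
#' clamp gain for the ternary channel.  Used to compare census rankings
#' against the truth the data were generated from.
#'
#' @param words character vector of site words.
#' @param model a [BindingModel-class].
#' @param channel "monomer" (default) or "ternary".
#' @return numeric vector of weights.
#' @export
trueWordAffinity <- function(words, model, channel = c("monomer",
                                                       "ternary")) {
  channel <- match.arg(channel)
  if (channel == "monomer") return(siteAffinity(words, model@psam))
  # unnormalised product, with the gain, on the clamp-reweighted matrix
  raw <- model@psam@affinities * model@clamp@multipliers
  k <- nrow(raw)
  M <- encodeDNA(words, k)
  aff <- rep(model@clamp@clampGain, length(words))
  for (p in seq_len(k))
    aff <- aff * raw[cbind(p, M[, p])]
  aff
}
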