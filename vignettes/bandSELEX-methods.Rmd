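---
title: "bandSELEX: model, parameters and design notes"
author: "bandSELEX authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bandSELEX: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandSELEX)
```

## What the package models

Band-specific SELEX couples in vitro selection to an electrophoretic
mobility shift assay: a random-insert DNA library is incubated with a
POU-domain factor (OCT1 or OCT2), optionally with the coactivator BOB1, the
complexes are separated on a native gel, one band — monomeric, dimeric or
ternary (DNA + POU + BOB1) — is excised, and the recovered DNA is amplified
and re-selected. After several rounds the surviving inserts carry the
sequence signature of whatever complex the excised band contains.

`bandSELEX` has two halves: a generative model (`runSelex()` and friends)
that produces read sets under known ground truth, and an analysis surface
(trimming, degenerate-pattern census, motif scanning, comparison,
correlation) that recovers sequence preferences from read sets, simulated
or real.

## The binding model

**Monomer channel.** A position-specific affinity matrix (PSAM) assigns
each 8-mer window `w` the weight `a(w) = prod_p M[p, w_p]`, consensus
`ATGCAAAT` = 1. The default matrix (`defaultPsam()`) is a qualitative
encoding of the octamer literature rather than a fit: adenines at positions
1, 6 and 7 are near-obligatory (off-bases 0.05–0.10); positions 2 and 8 are
variable; and thymines at positions 3–5 are deliberately mild
(T3 = T4 = 0.8, T5 = 0.7) because they are permissive for the POU factor
alone — `ATTTAAAT` must remain a competitive site in BOB1-free selections,
where it is reported among the top enriched words. A read's monomer weight
is its best window over both strands.

**Ternary channel.** BOB1 clamps onto the *already formed* monomer complex:
the ternary weight is the best monomer site's PSAM product times the clamp
multipliers times the clamp gain. The default `ClampRule()` sets gain 5,
forbids T at position 5 (multiplier 0) and disfavours T at positions 3 and 4
(0.25 each). Consequently a read whose best POU site carries T5 has ternary
weight exactly 0 — it can be bound, but not clamped.

**Dimer channel.** The MORE family (`ATG[C/A]AT + 0–2 A/T gap bases +
AT[T/G]CAT`, split into fixed-gap variants MORE, MORE+1, MORE+2) and the
PORE (`ATTTGAAATGCAAAT`) are matched as consensus words; the A/T gap
alphabet makes each MORE variant a single IUPAC word (`ATGMAT W{g} ATKCAT`).
Matches carry fixed weights (MORE 0.8, MORE+1/+2 0.7, PORE 0.5). The MORE
dimer configuration is refractory to the clamp and contributes nothing to
the ternary channel; the PORE is clamp-permissive (PORE weight x gain).

**Selection.** Per round, each molecule partitions to exactly one band,
sampled proportionally to its channel weights — a molecule runs at a single
mobility in a gel lane. A molecule in the requested band is retained with
the occupancy probability `a / (a + s)`; the stringency `s` (default 1) is
the single dial standing in for protein concentration and wash losses.
Amplification is multinomial resampling back to the pool size, error-free
by default (a per-base substitution rate is config-exposed). If no molecule
survives a round the simulation raises a collapse error rather than
fabricating a pool.

## Default study conditions

`defaultConditions()` follows the four-arm design: POU1 and POU2 alone
followed through the monomer band, POU1+BOB1 and POU2+BOB1 through the
ternary band. POU1 and POU2 share the default PSAM, reflecting their
near-identical site recognition. The default library size is 150,000
molecules — the scale of the sequenced read sets the design emulates
(roughly 1.4–2.8 x 10^5 per condition) — with four rounds of selection.
The test suite and the acceptance script run the same design at 20,000
molecules so that the full suite completes in minutes; the between-condition
direction checks additionally use the 150,000 default, where systematic
effects are better resolved against founder noise.

## The census and its numerical conventions

The degenerate pattern `ANNNNAAN` (1024 concrete words) fixes the conserved
adenines A1/A6/A7 and leaves positions 2–5 and 8 free. Two exhaustively
verified properties motivate it: a frame-shifted co-match always requires at
least one adenine that a match does not itself guarantee (shifts of 2–7 nt
can never be forced by the matched word; a 1-nt shift only for the 64 words
with spare adenines at positions 2 and 8), and the reverse complement of a
matching word fails the pattern except for the 16 palindromic coincidences
with T at positions 2, 3 and 8.

Conventions, chosen where the underlying publications are silent:

* `per_read` counting (default): one word per read, the first occurrence in
  scan order (forward 5'→3' first, then minus-strand hits by forward
  offset) — one binding event per enriched 35-mer. `per_occurrence` is
  available.
* both strands are scanned by default (the selected molecule is
  double-stranded); minus-strand words are reported in pattern orientation.
* relative frequencies are percentages over all matched words, so each
  census sums to 100; the matched-read fraction is kept separately.
* rankings break frequency ties lexicographically, for determinism.
* the top-N "cumulative share" is the sum of the returned words' relative
  frequencies.
* fold changes report the raw ratio a/b plus a direction and the
  reduction-style magnitude `max/min`; a zero denominator sets an
  "undefined" flag instead of dividing.
* a probed sequence absent from a census but matching the pattern has
  frequency 0 (the census is defined over the whole 1024-word universe).

Trimming anchors on the terminal 8 bases of each constant flank with at
most 1 mismatch per anchor (tolerating single sequencing errors without
admitting frame-shifted inserts). Among 3' anchor hits, the one consistent
with the designed insert length is preferred: roughly 1 in 500 random
35-mers contains an anchor-like subsequence, and the geometric preference
makes trimming of intact reads lossless. Inserts containing N are rejected
because the census assumes a 4-letter alphabet; rejection is data, not an
error, and accepted + rejected always equals the input count.

## What the simulator does and does not emulate

Emulated: band-specific capture, occupancy-style retention, PCR resampling
noise, seeded end-to-end determinism (one seed fans out to per-condition
child seeds, `seed + 7919 x condition index`), ground-truth logging
sufficient to audit every selection decision.

Not emulated: thermodynamic detail (salt, temperature, cooperativity),
gel-mobility physics, sequencing error, and — most importantly — the
complexity of a bench library. A real selection starts from ~10^12–10^13
molecules; a desk-scale run starts from 2 x 10^4–1.5 x 10^5. Three visible
consequences, worth keeping in mind when interpreting simulated censuses:

1. **Founder lottery.** Any specific 8-mer site is present in only ~17
   reads per 20,000; which variants dominate after four rounds depends
   strongly on which founders survive round one. Rankings among
   similar-affinity variants are noisy at this scale.
2. **First-occurrence artifacts.** In `per_read` mode the counted word is
   not always the binding site: whenever a site is preceded by an adenine,
   the one-left-shifted window matches the pattern and scans first (~25% of
   site reads), and random flank windows match `ANNNNAAN` at (1/4)^3 per
   window (~0.9 expected matches per 35-mer over both strands). Census-level
   position-5 compositions therefore plateau well below the purity of
   motif-logo readouts, and a few percent of ternary-band census mass
   carries T5 even though no clamped complex tolerates it. The same
   artifacts exist in real censuses; site-calling tools avoid them at the
   cost of a model.
3. **Gain saturation.** With clamp gain 5 and stringency 1, all strongly
   clampable sites are retained at 0.55–0.7 per round, compressing their
   differences; the clamp's *narrowing* of the tolerated palette (T-variant
   exclusion) is robust, while the *concentration* of the consensus word
   relative to the BOB1-free arm is a small systematic effect easily
   obscured by founder noise at desk scale.

These are stated as limitations rather than tuned away: the defaults are
the package's fixed study conditions, and the acceptance script reports
whatever they produce.

## Degenerate inputs and tie-breaks

Empty read sets produce empty census tables (no division by zero); positional
composition with zero matched sites is flagged undefined (`nSites = 0`).
Channel argmax ties resolve monomer < dimer < ternary. Enumeration of a
degenerate pattern is lexicographic and duplicate-free. The Pearson helper
refuses vectors shorter than 3 and returns NA (undefined) on zero variance
rather than propagating NaN.

## Synthetic densitometry

`syntheticIntensityTable()` emulates the gel-shift validation step: an
experimenter-chosen probe panel (default: the consensus and four
single-substitution variants spanning clamp-permissive to clamp-refractory)
is assigned signals proportional to the ground-truth channel weight with
5% multiplicative log-normal noise. It is synthetic by construction and is
labelled as such; it stands in for real densitometry measurements, which
the analysis consumes as a plain TSV of (sequence, condition, signal).

## Problem sizes used by the tests

Module tests run on constructed reads and random sets of tens to hundreds
of inserts. The stochastic suites use library 20,000 with four rounds and
seed 1; the between-condition direction checks also use the 150,000-insert
default; the pipeline smoke test uses 3,000 inserts and two rounds. The
full suite runs in about two minutes on one CPU.
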