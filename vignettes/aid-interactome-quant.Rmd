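---
title: "Quantitative analyses for AID variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analyses for AID variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidquant)
```

## The scientific problem

Activation-induced deaminase (AID) initiates somatic hypermutation (SHM) and
class switch recombination (CSR) by deaminating deoxycytidine on single-
stranded DNA at immunoglobulin loci, preferentially within WRC hotspot motifs
(W = A/T, R = A/G). Separation-of-function mutants of the arginine-rich
surface of AID retain catalysis but lose biological activity, and the central
question is which protein interactions they lose inside live B cells. This
package implements the quantitative machinery for that programme:

1. a four-method consensus procedure for calling preys whose BioID
   (proximity-labelling) spectral counts are reduced with both mutant baits
   relative to wild type;
2. mutation calling and WRC/GYW hotspot classification of Sanger-sequenced
   clones against a reference, with spectrum summaries;
3. reporter-assay statistics (fluctuation-assay mutation frequencies,
   background-subtracted switching percentages, competitive growth, nuclear
   signal fractions, damage-foci proportions);
4. ChIP-qPCR percent-input quantification from per-amplicon standard curves
   with IgG-control subtraction.

Each stage has a matched synthetic-data generator with known ground truth, so
the whole pipeline is testable end to end without any external data.

## The BioID consensus model

The input is a prey-by-sample table of spectral counts for four baits: the
wild-type bait (`WT`), two mutants (`MUT1`, `MUT2`) and a paralogue control
(`A2`) that shares the fold but not the biology, used as a specificity
filter. All counts are first normalised to the BirA* self-biotinylation row
of the same sample, which absorbs differences in labelling activity and
expression between samples; the BirA* row becomes exactly 1 everywhere, so
normalisation is idempotent.

Four methods then score each prey, and a prey is a consensus hit when at
least one (union) or at least two (core) of them call it reduced in **both**
mutants:

* **Fold** — mean normalised counts with a pseudocount; a prey is called when
  WT/mutant fold is at least 2.5 for both mutants and WT/A2 fold is at least
  5 (thresholds inclusive). The mutant-enriched direction (both folds at or
  below 1/2.5) is reported but never enters the consensus.
* **Normz** — a global Z-score of the log2 fold enrichments (per mutant),
  flagging preys at 2 or more sample standard deviations above the mean.
* **Maz** — a local Z-score in a ratio-intensity (R-I) plot: for each prey
  the window is the `max(5, ceiling(0.10 n))` preys nearest in log2 mean
  abundance (candidate included, intensity ties broken by prey-id order), and
  the prey's log2 fold is standardised against that window. With a full
  window this reduces exactly to Normz, which the test suite asserts.
  A neighbourhood *in intensity* (rather than a rank-adjacent slice after
  sorting) was chosen because the window is meant to capture preys of
  comparable abundance around the candidate.
* **Deseq** — a negative-binomial Wald test on the raw counts, WT versus the
  two mutants pooled as the reference level, with Benjamini-Hochberg
  correction; flagged at adjusted p < 0.1 with a positive WT coefficient.
  Pooling follows the original contrast design in which the two mutants
  jointly form the reference condition.

### The negative-binomial test and its calibration

The NB test is authored in this package rather than delegated. Counts for
prey *g* in sample *i* are modelled as NB with mean `s_i * q_{g,c(i)}` and
variance `mu + alpha_g mu^2`; size factors `s_i` come from the
median-of-ratios over preys observed in every sample. Group means are fitted
by Newton iteration on the log scale; the Wald statistic for the WT
coefficient uses the Fisher information of the two group means.

Per-prey dispersion is estimated by Cox-Reid-adjusted profile maximum
likelihood (floor 1e-8), **moderated** toward the dispersion supported by the
whole matrix through a weighted likelihood with 10 prior degrees of freedom
— the conventional empirical-Bayes stabilisation for count data at small
replicate numbers. This choice is load-bearing: at 3+3 replicates the bare
per-prey maximum-likelihood dispersion is noisy enough that the Wald test
rejects far too often under the null, while plugging in the true dispersion
gives near-nominal size. Moderation recovers most of that gap without
fitting any mean-dispersion trend and without shrinking fold changes. No
independent-filtering or outlier-replacement steps are applied.

Because the design is an identical two-group contrast for every prey, the
whole fit (Newton steps, likelihood evaluation over a dispersion grid,
parabolic refinement) is vectorised across preys; a 2000-prey matrix fits in
about a second.

## The synthetic BioID experiment

`sim_bioid()` defines the simulated study conditions: negative-binomial
counts (`variance = mu + alpha mu^2`, the same parameterisation the test
uses), default dispersion 0.05, base mean 50, three replicates per bait,
planted preys reduced 8-fold in both mutants, and an A2 background of 10% of
the WT signal. Per-prey expected WT counts are drawn log-normally (sdlog
0.8) around the base mean so abundances span the one-to-two orders of
magnitude typical of spectral-count data and the R-I plot is non-degenerate.
The BirA* anchor row is drawn around its own mean and resampled away from
zero — the bait fusion always self-biotinylates, and the anchor must be
positive for normalisation to exist. Replicate number is configurable; three
per bait is this package's default for simulation, not a claim about any
particular experiment.

What the generator does *not* emulate: peptide-to-protein inference,
correlated preys (complex co-members), sample-to-sample contamination, or
compositional effects of a few dominant proteins. Passing the recovery
criteria therefore demonstrates the statistical machinery under the stated
count model, not robustness to those real-data pathologies.

```{r bioid-example}
sim <- sim_bioid(n_preys = 300, n_planted = 12, effect_size = 8, seed = 1)
fit <- bioid_diff(sim$counts, sim$meta)
fit
glance(fit)
mean(sim$truth$planted_preys %in% tidy(fit)$prey_id[tidy(fit)$in_core])
```

## Hypermutation spectra

Clones are aligned to the reference by global (Needleman-Wunsch) alignment
(+1 match, -2 mismatch, -5 gap open, -1 gap extend; equal-length pairs above
95% identity take a gapless fast path, which those scores make exactly
optimal). Clones under 80% identity are rejected as wrong amplicons.
Mismatch columns become substitution records; gap runs are counted as indel
events and excluded from the mutations-per-bp frequency, which follows the
substitution-profile convention; N columns are excluded from calling and
subtracted from the denominator when they exceed 1% of it. Every clone is
counted independently — no clonal-duplicate collapsing is attempted.

Classification is purely motif-based on the top strand: a mutated C is a
hotspot mutation iff its (p-2, p-1) context is W then R; a mutated G iff its
(p+1, p+2) context is Y then W (the bottom-strand WRC read on the top
strand); A/T mutations form the third class. A C or G whose context runs off
the sequence end is conservatively non-hotspot, with a warning. The
generator (`sim_shm_clones()`) uses the same classifier to place its
hotspot-biased rates, so the round trip — analyse the generated clones,
recover the planted truth exactly — is a strict identity check, and the whole
pipeline is invariant under reverse-complementing all inputs.

```{r shm-example}
ref <- withr::with_seed(99,
  paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
clones <- sim_shm_clones(ref, n_clones = 30, per_base_rate = 2e-3,
                         hotspot_multiplier = 5, seed = 2)
res <- shm_analyze(clones$clones, ref)
res$spectrum
```

## Reporter-assay statistics

Fluctuation experiments are summarised as the median (mean of the two
central order statistics for even n) of per-culture Rif-R cfu per 1e9 Amp-R
cfu; medians, not means, because the Luria-Delbruck mutant-count
distribution is heavy-tailed. Only the *frequency* is estimated — no
mutation-*rate* (maximum-likelihood Luria-Delbruck) estimation is attempted.
Cross-construct comparisons normalise each construct to the reference
construct within an experiment and then average the normalised values across
experiments. The remaining operations are deliberately small, exact
conveniences: background-subtracted percentages (floored at zero, flagged),
growth-ratio series normalised to day 0 or the maximum, nuclear/total signal
percentages, and the proportion of cells with at least k (default 5) damage
foci.

## ChIP-qPCR quantification

Per amplicon and per plate, a standard curve `Ct = a + b log10(q)` is fitted
to an input dilution series (at least 3 points; quantity 1 is the undiluted
input aliquot). The IP quantity is read off the curve and expressed as
percent of the chromatin used per IP via the input fraction, which is a
required user parameter; the IgG-control percent input is subtracted, and
negative net values are retained with a flag rather than clamped, so that
background-level signals remain visible. Efficiency outside [0.8, 1.1] and
r-squared below 0.98 are warnings, not errors. Quantities live on an
arbitrary per-plate scale; the tests assert that rescaling all standard
quantities leaves percent input unchanged once the anchoring is respected.

```{r chip-example}
plate <- sim_qpcr(c(Smu = 1.2, Ctrl = 0.2), noise_sd = 0, seed = 3)
chip_quantify(plate$plate, input_fraction = 0.1)$results
```

## Numerical choices and degenerate inputs

* Log base 2 throughout; stated in output headers and column docs.
* Fold pseudocount: half the smallest nonzero normalised value (zeros are
  common in spectral counts); configurable.
* Sample (n-1) standard deviations in both Z-score methods; zero-sd windows
  or vectors give Z = 0 with a warning, never NaN.
* Dispersion search on a log-spaced grid over [1e-8, 20] with parabolic
  refinement; all-zero preys are excluded from testing and reported as
  untested; groups with all-zero counts get information-bounded (near-zero)
  Wald statistics rather than divergent estimates.
* Prey identifiers are compared case-insensitively after trimming;
  duplicates are an error.
* Determinism: every generator takes an explicit seed and restores the
  global RNG state afterwards.

## Problem sizes used in validation

The shipped validation runs simulate at the sizes the analyses are designed
for: NB calibration on 200 null matrices of 2000 preys (3+3 replicates,
dispersion 0.05) and 200 planted matrices of 500 preys; consensus recovery
over 20 seeds of the 500-prey / 20-planted / 8-fold configuration; spectrum
round trips on 50 clones of 500 bp. The acceptance script uses 50-run
versions of the two NB simulations.

## Known limitations

* The NB test reports Wald p-values; at very low counts (group means below
  ~5) these are approximate and the test is intentionally conservative there.
* The consensus procedure treats methods symmetrically; no weighting by
  method reliability is attempted.
* The aligner targets Sanger-quality clones; it is not a read mapper and has
  no quality-score model.
* ChIP quantification assumes the standard curve is linear across the IP
  range; saturation or inhibition outside the dilution series is only
  surfaced as an extrapolation warning.
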