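---
title: "proxitome: models and methods"
author: "proxitome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxitome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

# Scope

`proxitome` implements the computational arm of a comparative BioID
(proximity-dependent biotin identification) study of a membrane protein —
the motivating system is CFTR and its trafficking-defective ΔF508 mutant,
with and without corrector therapy — together with the two quantitative
functional assays that typically accompany such studies: ratiometric
surface:total imaging and FLIPR membrane-potential traces. Every stage
consumes and produces plain tab-delimited files (plus 16-bit TIFF for
images), and every stage has a synthetic-data generator with known ground
truth, so the whole pipeline is testable without any external data.

# Interaction scoring

## The data

A BioID experiment yields, per run, spectral counts for every prey protein
identified. A bait condition contributes several runs (by default 2
biological × 2 technical replicates, i.e. n = 4), and tag-alone control
runs capture background biotinylation. `SpectralCountTable` stores these in
long form; absent (prey, run) pairs are zeros.

## Replicate QC

`replicateQC` computes squared Pearson correlations of raw per-prey counts
between all run pairs of a condition (union of preys, absent = 0) and
passes when the mean R² exceeds 0.9, the conventional reproducibility gate
for BioID replicates. No transformation is applied — spectral counts are
compared as they stand, which makes the gate sensitive to the abundant
preys that dominate such libraries. Because R² hides the sign, pairs with
negative correlation are flagged separately.

## The scoring model

SAINT-style scorers assign each prey a probability that its bait-run counts
exceed what the control runs explain. `scoreInteractions` is a documented,
fully specified stand-in with the same interface and qualitative behaviour:

* **Control model.** For each prey, the control counts
  $c_1,\dots,c_m$ update a weak symmetric Gamma prior
  $\lambda_0 \sim \mathrm{Gamma}(\alpha,\alpha)$ (default $\alpha = 0.1$,
  the `pseudoRate`), giving the posterior
  $\mathrm{Gamma}(a_0, b_0)$ with $a_0 = \sum_j c_j + \alpha$ and
  $b_0 = m + \alpha$. The bait-run likelihood under the null is the
  corresponding negative-binomial predictive, i.e. the Poisson likelihood
  marginalized over $\lambda_0$.
* **Alternative model.** A genuine proximity interactor is modelled as
  labelled at a fixed fold-enrichment $\varphi$ over background
  ($\lambda_1 = \varphi\,\lambda_0$, default $\varphi = 20$), marginalized
  over the same posterior. In BioID data, true interactors of a
  well-expressed bait are enriched over the tag-alone background by an
  order of magnitude or more, so a stringent $\varphi$ captures "clear
  enrichment" while staying robust to fluctuations of abundant
  contaminants.
* **Posterior probability.** With $S = \sum_i x_i$ the summed bait counts
  over $n$ runs, the log Bayes factor reduces to
  $$\log \mathrm{BF} = -a_0\log\varphi +
    (a_0 + S)\,\log\frac{b_0+n}{b_0/\varphi+n},$$
  which is *linear and increasing* in $S$: the reported probability is
  monotone non-decreasing in the bait counts for fixed controls, by
  construction. The probability is
  $\Pr(\text{interaction}) = w\,\mathrm{BF} / (w\,\mathrm{BF} + 1 - w)$
  where the mixture weight $w$ — the prior fraction of true
  interactions — is estimated per bait condition by maximizing the
  two-component mixture likelihood over $w \in [0.02, 0.5]$ (the objective
  is concave, so a 1-D search suffices).

Two design points deserve emphasis. First, we deliberately avoid the
simpler plug-in construction (Poisson likelihood at the bait-run MLE
against a point estimate of the control rate with equal priors): the
maximized alternative likelihood always dominates, point-estimating the
control rate from two runs ignores most of its uncertainty, and equal
priors ignore that contaminants outnumber true interactors roughly ten to
one. Together those three shortcuts produce confidence probabilities far
too close to 1 for ordinary contaminants, and the false discovery rate
gate downstream inherits the damage. Marginalizing both models over the
control-rate posterior and estimating the mixture weight empirically is
what keeps the gate honest; the planted-truth calibration test in the
suite (false-discovery proportion at the 1% gate below 5% over 20
simulations) verifies this end to end. Second, the fixed-$\varphi$
alternative is what makes the score monotone; a vague free-rate
alternative is attracted to *depleted* preys as well, and its Bayes factor
is non-monotone around the control rate.

Preys with zero counts in all bait runs are omitted (they carry no
evidence and would only dilute the FDR estimate). Ties in probability are
broken by higher average count, then prey name, so rankings are
deterministic.

## BFDR and the high-confidence gate

`computeBFDR` follows the SAINT convention: after ranking by decreasing
probability, the Bayesian FDR at rank $k$ is the mean of $(1-p)$ over the
top $k$. This is a consistent FDR estimate precisely because the $p$ are
posterior probabilities (see above); it is non-decreasing down the ranking
by construction and asserted on every call. `filterHighConfidence` keeps
preys with BFDR ≤ 1% by default — the standard high-confidence gate.

# Comparative analysis

## Bait normalization

A stabilized mutant bait can label itself (and its neighbourhood) more
than the wild type — in the motivating study about 2× more — so raw prey
counts are not comparable across conditions. `normalizeByBait` rescales
each condition's average prey counts by the ratio of the reference
condition's mean bait self-count to its own; `normalizeCountTable` applies
the same factor run-wise when per-replicate statistics (volcano,
re-scoring) are wanted. Normalization is exact under the model in which
labelling scales with bait abundance; background contaminants do *not*
scale with the bait, so normalization slightly shifts their apparent fold
changes — a caveat shared with the experimental practice this mirrors.

## Gained / lost / restored classification

`classifyPairwise` labels preys (high-confidence in at least one of the two
conditions) by the log2 fold change of their normalized counts with a
pseudocount of 0.5: gained at ≥ +1, lost at ≤ −1, boundaries inclusive
(a threshold of "±1.0" reads as attainment). The pseudocount is a common
spectral-count convention and keeps presence/absence contrasts finite.
Gained and lost are exactly antisymmetric under swapping the conditions.

`classifyRestored` compares wild type, mutant and mutant-plus-drug:
*restored* preys are in the wild-type high-confidence set, lost from the
mutant (not high-confidence there, or down by ≥ 1 log2), and
high-confidence again under drug; *attenuated* preys are mutant gains
(≥ +1 log2 vs wild type) reduced by drug (≤ −1 log2 vs mutant);
*non-responsive* preys are mutant gains the drug leaves essentially
unchanged (|log2FC| < 1). Labels are assigned in that priority order, so
the restored and attenuated sets are disjoint by construction.

## Volcano statistics and enrichment

`volcanoStats` computes, per prey, the log2 fold change of mean counts and
a two-sided t-test on log2(count + 1) across replicates. We default to the
Welch (unequal-variance) form — the safer reading when the variance
assumption is unstated — and report raw p-values (volcano plots
conventionally show unadjusted −log10 p) with Benjamini–Hochberg q-values
alongside. Preys are flagged red/green at |log2FC| ≥ 0.4, the conventional
flagging threshold for such plots. Degenerate cases are explicit: zero
variance in both groups with equal means gives p = 1; with unequal means
the p-value is floored at the machine minimum with a warning. Under a
no-effect Poisson simulation the p-value distribution is close to uniform
(Kolmogorov–Smirnov statistic below 0.1 at 500 preys, 4 vs 4 replicates);
the residual deviation reflects count discreteness at small n.

`enrichmentTest` is a generic over-representation test (one-sided
hypergeometric with BH correction) over user-supplied category files — a
deliberate stand-in for web-service GO enrichment, so analyses remain
offline and reproducible.

# Localization by prey-profile similarity

`rankCompartments` compares a bait's high-confidence prey set against each
marker bait of a compartment compendium by Jaccard distance
$1 - |A\cap B|/|A\cup B|$ and ranks compartments ascending. Genes on a
user-supplied exclusion list (preys with no annotated function or
localization — a manual curation step consumed as data) are removed from
both sides first. We compare *sets*, the literal reading of "prey
profiles"; a count-weighted variant would be a natural extension but
changes the question from overlap to abundance concordance. Ties are
broken lexicographically for determinism.

# Surface:total image quantification

Input fields are projected 16-bit TIFFs with a surface-label channel and a
total-reporter channel. Per field:

1. **Background** per channel is the centre of the most populated
   histogram bin (bin width 1 intensity unit by default) of a demarcated
   cell-free region, or of the whole image when no mask is supplied —
   valid whenever cells cover a minority of pixels. The mode is robust to
   the bright cell tail in a way the mean is not; dark noise is absorbed
   into the same term rather than subtracted separately.
2. **Thresholding** keeps pixels whose *background-subtracted* value
   strictly exceeds k × background — a stringent k = 7 for the surface
   channel and k = 20 for the total channel, each relative to its own
   channel's background. "k-fold over background" is ambiguous between
   raw > k·bg and (raw − bg) > k·bg; we implement the latter ("over" =
   above background). With a zero background every positive pixel is
   retained, with a warning.
3. **Field ratio** is the mean retained surface intensity divided by the
   mean retained total intensity — one ratio per field, not a mean of
   pixel-wise ratios, matching the "25 ratios per set" convention and
   keeping the estimator stable where the total signal is locally dim.

`aggregateExperiment` then averages fields within an experiment,
experiments within a condition, normalizes to the control condition
(control ≡ 1 exactly), and tests each condition against control with a
two-sided t-test *on experiment-level means* — the hierarchy
pixels → field → experiment → condition mirrors how error bars over n = 3
experiments are drawn, and avoids pseudo-replication over fields. Fields
in which either channel retains no pixels are flagged invalid and excluded
with a warning.

Ratios are invariant to rescaling both channels by a constant. Note that
*offsetting* all pixels is only neutral while the thresholds do not bite:
the cutoffs scale with the estimated background, so a large offset can
push dim structures below threshold — a real property of fold-over-
background thresholding, not an artifact.

# FLIPR trace quantification

Traces are baseline-normalized as ΔF/F0 with F0 the mean over the first
180 s (the conventional 3-minute pre-agonist read); F0 must be positive.
The agonist peak is the maximum raw normalized sample in the window after
forskolin addition up to and including the inhibitor addition — no
smoothing by default (an optional moving average is available for noisy
traces; note that the raw maximum is biased upward by roughly the noise SD
times the expected extreme of the window's sample count). The
post-inhibitor level is the mean over the final 20% of post-inhibitor
samples — late enough that first-order decay has essentially completed at
realistic time constants — and the inhibitor-sensitive fraction is
(peak − post)/peak. A non-positive peak flags "no agonist response" (the
uninduced or trafficking-defective phenotype); a fraction near zero with a
clear peak is the inhibitor-insensitive phenotype. ΔF/F0 is invariant to
positive rescaling of the raw trace.

# Synthetic data: what it emulates, and what it does not

The generators exist so that every consumer has inputs with known truth.

**Counts** (`simulateBioidCounts`). Default scenario: three conditions
(reference WT, mutant, mutant + drug) with bait self-count rates 300, 600
(the ~2× self-labelling of a stabilized mutant) and 450; 2×2 replicates
and 2 controls; 60 true preys with base rates drawn log-uniformly on
[5, 300] — spectral-count libraries are heavy-tailed, and this spread is
what makes replicate R² > 0.9 attainable with Poisson counting noise —
absent from controls; 600 contaminants at rate 5 in every run; a per-prey
biological-replicate log-normal effect of SD 0.2 shared by technical
replicates, which exercises the QC gate realistically while keeping mean
R² above it. Planted effects of |log2FC| = 3 define six ten-prey groups
(gained, lost, restored, attenuated, non-responsive, stable), and bait-run
rates scale with the condition's bait abundance — the assumption bait
normalization inverts. The truth table records pairwise classes for all
preys and trio classes for the planted trios. Not modelled: peptide-level
identification, shared-peptide ambiguity, run-order batch effects, and
contaminants correlated with bait abundance.

**Images** (`simulateFieldImage`). Non-overlapping disk cells (interior =
total channel, intensity 4000) with membrane rings (surface channel,
intensity ratio × 4000), uniform background 100 on both channels,
optional Poisson shot noise, 96 × 96 px and 6 cells per field by default
(a scaled-down field that preserves the cell/background area balance of
real 25–40-cell fields while keeping a 25-field × 20-seed recovery test
fast). The cell-free region is recorded as the background mask. Not
modelled: point-spread blur, intracellular texture, cell-to-cell intensity
variation, segmentation errors.

**Traces** (`simulateFliprTrace`). Flat baseline 1000, first-order rise
(τ = 20 s) to baseline × (1 + amplitude) after forskolin at 180 s,
exponential decay (τ = 30 s) toward baseline × (1 + amplitude × residual)
after inhibitor at 400 s, Gaussian noise of SD 0.01 × baseline, sampled
every 5 s — plate-reader-like kinetics. Not modelled: dye loading drift,
well-to-well baseline heterogeneity, additive artifacts at injection.

All generators are deterministic given their seed. Because the generators
realize exactly the assumptions the estimators invert (Poisson counts,
uniform background, first-order kinetics), passing recovery tests
demonstrates internal consistency and calibration — not robustness to the
real-data violations listed above.

# Numerical choices and test problem sizes

* Gamma smoothing `pseudoRate` 0.1; enrichment fold φ = 20; mixture
  weight bounded to [0.02, 0.5].
* Pseudocount 0.5 for all log2 fold changes; thresholds ±1.0
  (classification) and ±0.4 (volcano flags), boundaries inclusive; BFDR
  tier boundaries 0.01/0.05 assigned to the stricter tier.
* Histogram bin width 1 for 16-bit backgrounds; ties to the lowest bin.
* Welch degrees of freedom by Satterthwaite; p floored at
  `.Machine$double.xmin` only in the doubly-degenerate unequal-mean case.
* The test suite uses 20 simulation seeds for scoring/differential
  calibration, 3 × 20 × 25 fields for imaging recovery, 500 preys for the
  volcano null, 100 random cases for each exact oracle, and 30 traces for
  FLIPR recovery — sizes chosen to give stable statistics in seconds.

# Known limitations

* The scorer is a calibrated stand-in, not a reimplementation of
  SAINTexpress; absolute probabilities differ even where rankings agree.
* BFDR-based re-scoring after normalization treats scaled counts as
  Poisson rates, an approximation (fractional counts are not re-integered).
* The imaging module is field-level: it does not segment cells, so
  condition effects that change cell number rather than intensity are
  diluted rather than detected.
* Set-based Jaccard ignores prey abundance; two baits sharing weak preys
  look as similar as two sharing strong ones.
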