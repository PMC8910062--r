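# proxitome

Comparative BioID interactome analysis with functional-assay
quantification, in R.

## What this is for

Proximity-dependent biotin identification (BioID) tags a bait protein with
a promiscuous biotin ligase and reads out, by mass spectrometry, spectral
counts for every protein biotinylated in the bait's ~10 nm neighbourhood.
Comparing such interactomes across conditions — a wild-type membrane
protein vs. a trafficking-defective mutant, with and without a corrector
drug, the motivating case being CFTR and ΔF508-CFTR under Orkambi — asks a
chain of statistical questions this package answers end to end:

* **Which preys are real interactors?** `scoreInteractions` scores each
  prey against tag-alone control runs with a Gamma–Poisson two-component
  model: the control counts define a posterior for the background rate
  λ₀ ~ Gamma(Σc + α, m + α); the alternative says a true interactor is
  labelled at a fixed fold-enrichment φ over background; the posterior
  probability is w·BF/(w·BF + 1 − w) with the mixture weight w fitted by
  maximum likelihood. `computeBFDR` converts ranked probabilities into a
  Bayesian FDR (cumulative mean of 1 − p), and `filterHighConfidence`
  applies the BFDR ≤ 1% gate. `replicateQC` enforces the mean R² > 0.9
  replicate-correlation convention.
* **What changed between conditions?** `normalizeByBait` removes
  bait-abundance differences using the bait's own spectral counts;
  `classifyPairwise` calls gained/lost at |log2FC| ≥ 1 (pseudocount 0.5);
  `classifyRestored` identifies drug-*restored* interactions (present in
  WT, lost from the mutant, regained under drug) and separates
  *attenuated* from *non-responsive* mutant gains; `volcanoStats` gives
  per-prey Welch t-tests on log2 counts with ±0.4 flags;
  `enrichmentTest` is an offline hypergeometric over-representation test.
* **Where does the bait live?** `rankCompartments` ranks a
  compartment-marker compendium by Jaccard distance to the bait's
  high-confidence prey profile.
* **Did trafficking/function actually change?** `quantifyField` and
  `aggregateExperiment` implement ratiometric surface:total quantification
  of 16-bit microscopy fields (histogram-mode background, 7×/20×
  fold-over-background thresholds, per-field ratio of channel means,
  experiment-level statistics). `computeDFF0` and `quantifyResponse`
  quantify FLIPR membrane-potential traces (ΔF/F0, agonist peak,
  inhibitor-sensitive fraction).
* **Can I test all of it?** `simulateBioidCounts`, `simulateFieldImage`
  and `simulateFliprTrace` generate every input kind with known ground
  truth.

See `vignettes/proxitome-methods.Rmd` for the models, parameter meanings
and design rationale.

## Worked example

```r
library(proxitome)

sim <- simulateBioidCounts(countSimConfig(seed = 42))
sim$table
#> SpectralCountTable: 9051 count records, 14 runs ( 2 control ), 661 preys
#>   conditions: control(2), dF508(4), dF508_Orkambi(4), WT(4)

qc <- replicateQC(sim$table, "WT")
sprintf("WT replicate QC: mean R^2 = %.3f (pass: %s)", qc$mean_r_squared, qc$pass)
#> "WT replicate QC: mean R^2 = 0.929 (pass: TRUE)"

scored <- lapply(setNames(nm = c("WT", "dF508", "dF508_Orkambi")),
                 function(cc) computeBFDR(scoreInteractions(sim$table, cc)))
scored$WT
#> ScoredInteractions: 661 preys for CFTR:WT
#>   prob range: [2.14e-24, 1]; 64 at BFDR <= 0.01

norm <- normalizeByBait(scored, baitSelfCounts(sim$table), "WT")
table(classifyPairwise(norm$WT, norm$dF508)$class)
#>    gained      lost unchanged
#>        30        22        15

trio <- classifyRestored(norm$WT, norm$dF508, norm$dF508_Orkambi)
table(trio$class)
#>     attenuated non_responsive          other       restored
#>             13             17             17             20
```

The simulation plants 60 true interactors (among them ten gained, ten
lost, and ten-prey restored/attenuated/non-responsive trios at
|log2FC| = 3) on top of 600 background contaminants. The WT
high-confidence set (64 preys at BFDR ≤ 1%) recovers the true interactors
plus the bait itself with few contaminant leaks; the pairwise and
three-condition calls recover the planted groups — the restored set also
picks up high-abundance "lost" preys that remain detectable under drug,
which is what its presence/absence definition implies. `sim$truth` holds
the planted classes if you want to score the calls yourself.

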