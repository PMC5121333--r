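# mTORaa

Dynamic modelling of amino-acid inputs to the mTOR–AMPK signalling
network, for systems biologists who want to ask *where* amino acids enter
a signalling network rather than assume the canonical entry point.

Amino acids activate mTORC1 via the Rag GTPases; whether they also
activate other kinases of the network (AMPK, PI3K, mTORC2) independently
of mTORC1 is a model-selection question. mTORaa implements the full
workflow:

* **Network model** — a mass-action phospho-state ODE model of the
  IR/IRS/PI3K/Akt/TSC1–TSC2/mTORC1/mTORC2/AMPK/PRAS40/p70-S6K network.
  Each reaction converts one state of a protein pool into another at rate
  `v = k · gate(t) · (Σ catalysts) · [substrate]`, with unitless step
  stimuli (amino acids, insulin) switched on at t = 0. The final model
  (extended p70-S6K module, amino-acid inputs on mTORC1 + IRS + AMPK +
  mTORC2) has 31 species, 48 reactions and 12 observables, and
  round-trips through SBML Level 2 Version 4.
* **Simulation** — LSODA integration (rtol 1e-6, atol 1e-12) and graded
  in-silico knockdowns: pool totals scaled to 10–100% residual levels,
  emulating wortmannin (PI3K), shRaptor (mTORC1), shSin1/shRictor
  (mTORC2) and compound-C/shAMPK (AMPK) experiments.
* **Estimation** — multi-start bounded trust-region least squares in
  log10 parameter space with a 10% observation error model
  (σ = max(0.1·y, 1% of the observable's maximum)), scored by
  AIC = χ² + 2k.
* **Selection** — stagewise amino-acid-input search: 12 double-input
  variants, pairs of accepted components as triples, three-component
  unions of accepted triples as quadruples, accepting a model when its
  AIC improves on the previous stage's best by at least 1%
  (`AIC_new ≤ 0.99 · AIC_prev`). With the reported survivors the
  procedure enumerates 1 + 12 + 36 + 21 = 70 models.
* **Identifiability** — ensemble-correlation flags (tuple r² > 0.9 and
  CV > 15% over the best 50% of fits) and profile likelihoods
  (Δχ² = 3.84) with re-optimized nuisance parameters.
* **Phosphoproteomics** — the triple-SILAC post-processing: bridged
  cross-experiment ratios through the 30-min channel (9 combinations at
  5 min, 6 at 10/15 min for the five-experiment design), per-column
  median centering, localization filtering (> 0.75), and volcano
  filtering (fold change ≥ 1.5 or 2, one-sample t-test p < 0.05,
  uncorrected).
* **Synthetic data** — a calibrated ground-truth parameterization plus
  generators for noisy immunoblot-style time courses and MaxQuant-style
  phosphosite tables, so every stage is testable offline.

## Worked example

```r
library(mTORaa)

## the final quadruple-input model
final <- buildVariant(buildBaseModel("extended"),
                      c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
final
#> ModelSpec: 31 species, 48 mass-action reactions, 36 parameters, 12 observables
#>   p70-S6K module: extended
#>   aa inputs: mTORC1 + AMPK_pT172, IRS_p, mTORC2_pS2481

## simulate amino-acid readdition with the shipped ground truth
tr <- simulateModel(truthModel(), Protocol(aa = 1, insulin = 0))
round(observableValues(tr)[match(c(1, 5, 15), tr@time),
                           c("AMPK-pT172", "p70S6K-pT389")], 3)
#>      AMPK-pT172 p70S6K-pT389
#> [1,]      0.400        0.013
#> [2,]      0.505        0.033
#> [3,]      0.507        0.096
```

AMPK-pT172 is already at ~80% of its plateau 1 min after amino-acid
readdition (the acute, mTORC1-independent response), while p70-S6K-pT389
(the mTORC1 output) rises an order of magnitude more slowly — the
qualitative separation that motivates looking for extra amino-acid
inputs.

```r
## the behaviour checklist behind the shipped truth
all(behaviourChecklist(truthModel()))
#> [1] TRUE

## SILAC ratio combinatorics of the five-experiment bridged design
tab <- generatePhosphoTable(nSites = 200, nRegulated = 10, log2FC = 1.5, seed = 1)
ncol(computeRatios(tab, silacDesign(), 5))
#> [1] 9
res <- runPhosphoPipeline(tab)
lengths(res$regulated)
#> 1.5 2.0
#>  29  13
all(attr(tab, "regulated") %in% res$regulated[["2.0"]])
#> [1] TRUE
```

All ten planted sites (log2 fold change 1.5 at the stimulated time
points) are recovered even at the stricter 2-fold cutoff. The extra
calls are a real feature of the bridged all-versus-all design: the 9
(or 6) ratios of a site share channel-noise terms, so the nominal
one-sample t-test is anti-conservative — one reason the original
analysis continued with the stricter 2-fold list.

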