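---
title: "Modelling amino-acid inputs to the mTOR-AMPK network with mTORaa"
author: "mTORaa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amino-acid inputs to the mTOR-AMPK network with mTORaa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mTORaa)
```

## The scientific question

Amino acids are classically thought to signal into the mTOR network through
a single entry point, the Rag-GTPase-mediated activation of mTORC1. mTORaa
implements a dynamic-modelling workflow for asking whether time-course
readouts across the network (quantified immunoblots of IR, IRS, Akt, TSC2,
PRAS40, AMPK, mTORC1/2 and p70-S6K phosphosites) are better explained by
additional, mTORC1-independent amino-acid inputs — and for locating them by
stagewise model selection. The package also re-implements the companion
triple-SILAC phosphoproteomics processing (bridged ratio combinatorics,
median normalization, volcano filtering) used to survey amino-acid-responsive
phosphosites proteome-wide, plus generators for realistic synthetic data so
that the entire pipeline is testable end-to-end without any external
downloads.

## The network model

The core object is a mass-action phospho-state model
(`buildBaseModel()`): each protein pool (IR, IRS, PI3K~PDK1~, PI3K~variant~,
Akt, TSC1–TSC2, mTORC1, mTORC2, AMPK, PRAS40, p70-S6K) is a closed set of
states interconverted by first-order reactions, optionally catalysed by the
summed amount of a catalyst pool and gated by one of two unitless stimulus
step functions (amino acids, insulin) that switch on at $t = 0$:

$$v \;=\; k \cdot \mathrm{gate}(t) \cdot \Big(\sum_{c \in \mathrm{cat}} x_c\Big) \cdot x_\mathrm{substrate}.$$

All pool totals are 1 arbitrary unit and all modified states (and the
refractory IR state) start at 0, reflecting 16 h of starvation before
stimulation. Because every reaction stays within a pool, per-pool mass is
conserved exactly — a property the test suite verifies along trajectories to
integrator tolerance.

Akt, PRAS40 and (in the extended module) p70-S6K carry combinatorial
two-site phospho-states. The corresponding "first" and "second" reactions
(for example S473 phosphorylation of Akt and of Akt-pT308) share one rate
constant, which keeps the parameter count at 33 for the extended base model
and 36 for the final quadruple-input variant (3 insulin-receptor parameters
plus 33 network parameters). The final model — extended p70-S6K module with
amino-acid inputs on mTORC1, IRS, AMPK and mTORC2 — has 31 species, 48
reactions and 12 observables; observables are unweighted sums of species
amounts (for example Akt-pS473 is `Akt_pS473 + Akt_pT308_pS473`).

```{r counts}
final <- buildVariant(buildBaseModel("extended"),
                      c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
final
```

Design choices worth spelling out, made where the connectivity admitted more
than one faithful mass-action reading:

* **AMPK ⊣ mTORC1 as pool sequestration.** AMPK phosphorylates TSC2-S1387,
  which promotes the GAP activity of TSC1–TSC2 towards mTORC1. We implement
  this by letting the catalyst pool of mTORC1 inactivation be
  `{TSC, TSC_pS1387}`: AMPK moves TSC away from the Akt-inactivatable
  T1462 state, enlarging the GAP-active pool. This preserves the
  qualitative AMPK ⊣ mTORC1 arm without spending extra reactions, and the
  Raptor-directed arm of AMPK's mTORC1 inhibition is folded into the same
  mechanism (no separate Raptor species; no Raptor readout exists in the
  observable set).
* **The negative-feedback loop (NFL) and mTORC2.** p70-S6K feeds back on
  IRS by catalysing the inhibitory IRS-S636 state; IRS gene-expression
  suppression is absorbed into the same reaction. The PI3K variant that
  activates mTORC2 is catalysed by IRS-p, placing mTORC2 downstream of the
  NFL. With the alternative wiring (PI3K variant activated directly by the
  insulin receptor), the Akt-S473 readout is structurally decoupled from
  mTORC1 — the S473 phosphorylation/dephosphorylation rates are shared
  between both T308 states, so the S473 total depends only on
  mTORC2-pS2481 — and the hallmark NFL observation (mTORC1 knockdown
  *raising* Akt-pS473) becomes unreproducible. The IRS-side wiring is the
  only one consistent with that perturbation signature.
* **Candidate input sites.** Extra amino-acid inputs can be attached at 12
  activatable states (`candidateSites()`): every phospho/active state
  except the three IR states (IR is the insulin sensor; amino-acid-only
  protocols have insulin = 0), the inhibitory IRS-pS636 state (an "input"
  there would be a removal, not an activation), and mTORC1 itself (which
  already carries the canonical input). A combinatorial site gains one
  gated reaction per precursor state, all sharing a single new rate
  parameter, so each added input costs exactly one parameter.
* **AMPK's insulin-responsive arm** is routed through IRS-p (an
  IRS-dependent feedback); gating it through IR directly is the main
  alternative we considered, but the IRS route keeps the arm sensitive to
  the NFL, which the ablation checks exercise.

Models round-trip through SBML Level 2 Version 4 (`exportSBML()`,
`importSBML()`); the kinetic laws spell out the gate and catalyst-sum
factors, so a re-import simulates identically and a re-export is
byte-stable.

## Simulation and in-silico knockdowns

`simulateModel()` integrates the ODEs with LSODA (default relative/absolute
tolerances $10^{-6}$/$10^{-12}$, output every 0.1 min over 120 min).
Inhibitor and knockdown experiments are represented purely as $t = 0$
scalings of pool totals (`perturbationScan()`: 10 residual levels from 10%
to 100%); the PI3K scan scales both PI3K species together since both are
wortmannin-sensitive. Nonnegativity is enforced by solver tolerance, not
clipping — a trajectory dipping below $-10^{-6}$ is reported as an error
rather than silently repaired.

## The synthetic ground truth

`truthParameters()` is a hand-calibrated parameterization (units 1/min) of
the quadruple-input extended model. It was calibrated once, against the
qualitative behaviour checklist (`behaviourChecklist()`), not against any
fitted quantity:

1. AMPK-pT172 at least half-maximal by 5 min of amino-acid readdition
   (acute response);
2. p70-S6K-pT389 still rising between 5 and 15 min (delayed response);
3. no observable above 0.95 of its pool (no saturation);
4. PI3K at 10% residual suppresses the Akt-pT308 peak by ≥ 50% while
   AMPK-pT172 changes ≤ 20% (the wortmannin signature);
5. mTORC1 at 25% residual suppresses p70-S6K-pT389 by ≥ 50% and raises
   Akt-pS473 (NFL release);
6. AMPK at 50% residual leaves p70-S6K-pT389 within ± 20% (no mTORC1
   activation by AMPK loss under amino-acid sufficiency);
7. mTORC2 at 40% residual suppresses Akt-pS473 by ≥ 30% with p70-S6K-pT389
   and AMPK-pT172 within ± 20%.

The residual levels 10/25/50/40% are the knockdown depths of the
corresponding wet-lab comparisons the model was originally confronted with.

`generateTimecourses()` draws replicate values as
$y = \hat y\,(1+\varepsilon)$, $\varepsilon \sim N(0, CV)$ truncated at
$-0.99$ — multiplicative noise of the kind immunoblot densitometry
produces. The default CV of 10% matches the fitting-side error model; only
that fitting-side value is documented for the original data, so the
generator adopts it as the data-generating law too. The default grid
(0–120 min, 12 points, 3 replicates, amino-acid-only and
amino-acid-plus-insulin conditions) mirrors the calibration design. What
the generator does *not* emulate: blot-to-blot normalization artefacts,
saturation of film exposure, correlated replicate errors, and readout
cross-reactivity; passing tests on synthetic data therefore demonstrate
correctness of the machinery, not biological validity on real blots.

## Parameter estimation

`fitModel()` minimizes
$\chi^2 = \sum_i \big((y_i - \hat y_i)/\sigma_i\big)^2$ with
$\sigma_i = \max(0.10\, y_i,\ 0.01 \max_o y)$ — a 10% observation error
model with a floor at 1% of the observable's maximum, which keeps the
$t = 0$ points (observables start at 0) from acquiring zero variance.
Optimization runs in log10 parameter space inside the box
$[10^{-6}, 10^{4}]$ with a bounded Levenberg–Marquardt trust-region
least-squares; each start perturbs the best-known vector by
$10^{N(0,\,0.4)}$ per parameter (the first start is unperturbed), and the
whole ensemble is deterministic given its seed. Convergence uses $\chi^2$
and parameter tolerances of $10^{-5}$ with at most 250 iterations per
start. During estimation the integrator runs at absolute tolerance
$10^{-8}$; the forward-difference step of the Jacobian is set to $10^{-6}$
(in squared-residual units) to sit above the integration noise floor —
with machine-epsilon steps the finite differences are dominated by solver
error and the optimizer stalls.

Model fit quality is scored as $\mathrm{AIC} = \chi^2 + 2k$ with $k$ the
number of fitted (distinct) parameters: the Gaussian known-variance form,
dropping additive constants. This is the only AIC variant consistent with
the acceptance-threshold arithmetic of the selection procedure (a 1%
improvement rule applied directly to these values). The three
insulin-receptor parameters are treated as independently calibrated and
held fixed during variant fitting.

## Stagewise input selection

`runSelection()` reproduces the enumeration logic of the staged scan:

* stage 1: the canonical single-input model;
* stage 2: one extra input per candidate site (12 variants);
* stage 3: all unordered pairs of the components whose stage-2 variant was
  accepted;
* stage 4: all three-component unions of two accepted stage-3 sets,
  deduplicated (unions with four distinct components would be quintuple
  inputs and are discarded).

A variant is accepted when its AIC is at least 1% below the previous
stage's best ($\mathrm{AIC} \le 0.99\, \mathrm{AIC}_{prev}$); the margin
exists to keep numerical-approximation wobble in parameter estimation from
spawning spurious structure. With the study's reported survivors (9 of 12
doubles, 7 of 36 triples, all sharing the IRS component) the procedure
enumerates $1 + 12 + 36 + 21 = 70$ models, which `scripts/acceptance.R`
recomputes from scratch.

Selection runs on the simple two-state p70-S6K module (the scan predates
the T229 extension; 11 observables), and the winning input set is then
re-fitted on the extended module. Every candidate is fitted twice: cold
(multi-start from the base model's values — the log-midpoint of the bounds
for an uncalibrated base) and warm (one start carried from its
best-fitting accepted parent, where first only the new input rate is
optimized, then everything). The warm path guarantees a nested candidate
cannot end worse than its parent; the cold path keeps candidates from
inheriting the parent's compensation regime. Ties for the final model
break toward fewer inputs, then lexicographically — the substantive
tie-break criteria used in the original analysis (data availability and
upstream position of the PI3K variant) reduce to minimum AIC on all data
we generate.

Because no PI3K readout exists, the four PI3K rate constants are not
identifiable from the observables and act as a free gain/timing dial on
the IRS → PI3K~variant~ → mTORC2 arm; left free, every candidate can
re-tune that arm to mimic a direct mTORC2 amino-acid input and selection
degrades into near-ties. The original calibration handled this by
*assuming* the PI3K parameters rather than estimating them, and the
selection experiments here do the same: the `fixed` set of
`selectionConfig()` can hold the PI3K module (and the separately
calibrated insulin-receptor module) at the base values during variant
fitting.

## Identifiability

`motaFlags()` works on the best 50% of a multi-start ensemble: each
parameter's log10 values are regressed on greedily chosen tuples (up to 5)
of other parameters; a parameter is flagged when the tuple $r^2$ exceeds
0.9 *and* its coefficient of variation exceeds 15%. The CV gate keeps
numerically pinned parameters from being flagged on meaningless
correlations. The published description of these two thresholds transposes
them ("correlation coefficient ... and coefficient of variance were >15%
and 0.9%"); the reading implemented here ($r^2 > 0.9$, CV > 15%) is the
only one consistent with how ensemble-correlation identifiability analysis
is defined. The regression family is linear in log-parameters; rational
transformations are a known extension we do not implement.

`profileLikelihood()` steps one parameter over a log10 grid (default ± 2
decades, 21 steps) re-optimizing all others at each step, marching outward
from the optimum with warm starts. Classification uses
$\Delta\chi^2 = 3.84$ (95%, 1 df — no threshold is documented for the
original analysis, so the standard likelihood-ratio bound is used): both
arms crossing means identifiable, one flat arm practically
non-identifiable, both flat structurally non-identifiable.

## The SILAC phosphosite pipeline

`generatePhosphoTable()` emulates the five-experiment triple-SILAC design:
experiments 1–3 measure 0/5/30 min, experiments 4–5 measure 10/15/30 min,
with channel-to-time assignment rotated across experiments (label
switches) and the 30-min point in every experiment as the normalization
bridge. `computeRatios()` forms every cross-experiment combination
$(I_{t,i}/I_{30,i})/(I_{0,j}/I_{30,j})$ — 9 ratios at 5 min
($3 \times 3$), 6 at 10 and 15 min ($2 \times 3$); these printed counts
force the all-versus-all cross-experiment enumeration, which is applied
uniformly even when $t$ and 0 share an experiment (the bridge then cancels
algebraically). Zero intensities count as missing, and any combination
with a missing term is dropped.

Log2 ratios are median-centered per combination column across sites (the
documented normalization names "the log2 ratios median" without
specifying; per-column centering is the standard reading and the one
implemented). `volcanoFilter()` then requires at least two ratios,
$|\overline{\log_2 R}| \ge \log_2(\mathrm{cutoff})$ for cutoff 1.5 or 2,
and a two-sided one-sample t-test $p < 0.05$, uncorrected; a site is
regulated overall if it passes at any stimulated time point. A
zero-variance ratio vector leaves the t-test undefined; it passes the
p-gate iff its mean is nonzero. Localization filtering retains sites with
probability strictly above 0.75.

## Problem sizes and numerical choices

The test suite and acceptance checks run deliberately scaled-down versions
of the estimation experiments so the whole suite completes on one CPU in
minutes: structure-recovery uses a 6-site candidate set — the three truth
inputs plus the three decoy components that the full-scale scan reported
as non-improving (TSC-pT1462, TSC-pS1387, PRAS40-pS183). The PI3K-variant
site is deliberately not among the decoys: an amino-acid input there
propagates to mTORC2 and is near-degenerate with a true mTORC2 input by
AIC alone (the full-scale analysis had to resolve that pair with
substantive, non-AIC criteria), so it cannot serve in an AIC-only
recovery check. The experiments use the full 12-point study grid with 3
replicates at CV 10%,
a small number of multi-starts per variant over a short list of data
seeds; parameter-recovery refits use noise-free data; profile likelihoods
use short grids with a restricted nuisance set. The full time grid
matters more than ensemble size here: on truncated grids the late-time
feedback dynamics that separate a genuine mTORC2 input from
TSC-side decoys are not sampled, and selection degrades.

At these scaled ensemble sizes the stagewise search recovers the planted
input set in most but not all data realizations: whenever every
intermediate variant is fitted near its optimum the true set wins by wide
AIC margins, but the single-input variants have rugged objective
landscapes in which a small multi-start occasionally misses the relevant
basin, and one under-fitted intermediate can block the path to the true
set (the acceptance rule only extends accepted models). Reliable recovery
is an ensemble-size question — the full-scale protocol runs thousands of
starts per variant — and the self-check reports its per-realization
outcomes rather than hiding this sensitivity. These sizes are the package's own defaults for
its self-checks; the functions scale to the full 12-site, thousands-of-
starts design by changing the corresponding configuration values. The
known cost is that a single under-converged fit can occasionally hide a
true improvement at these ensemble sizes, which is why the selection
procedure carries the warm-start safety net described above.

Degenerate inputs are handled explicitly: integration failures during
fitting return infinite objectives (the remaining starts continue), an
all-starts failure is an error carrying per-start diagnostics, empty ratio
columns and missing bridges warn and drop, and identity perturbations are
bitwise no-ops.

## Known limitations

* The reaction table is a normative reconstruction constrained by the
  published species/reaction/observable counts and every named connection;
  the original supplementary ODE listing was not used, so individual rate
  constants are not comparable, and per-variant parameter counts are
  structural facts of this reconstruction only.
* Fitted AIC values on synthetic data are not comparable to the published
  AIC magnitudes (those depend on the original immunoblot data, which are
  not reproduced numerically anywhere in the text).
* The phosphoproteomics generator emulates intensity structure, label
  rotation, missingness and localization confidence, but not peptide-level
  aggregation, charge states or MS1 interference.
* Lysosomal Rag-GTPase mechanics, ULK1/c-Jun downstream events, CaMKKβ and
  LKB1 are outside the model boundary; the amino-acid gate on AMPK stands
  in for the CaMKKβ-mediated activation.
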