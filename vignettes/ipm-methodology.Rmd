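---
title: "Deriving intermediate acceptance criteria with integrated process models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving intermediate acceptance criteria with integrated process models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmiac)
```

## The problem

A biopharmaceutical drug substance (DS) must meet specification limits for
its critical quality attributes (CQAs) — host-cell protein, aggregate
content, monomer purity — before release. Those limits apply only at the
end of a purification chain of many unit operations (UOs). Quality teams
also need *intermediate acceptance criteria* (iACs): which CQA level is
still acceptable in the pool of each intermediate step? Conventional
practice sets them at the mean ± 3 standard deviations of historical data,
which carries no link to the DS specification at all: it rewards noisy
processes with wide limits, punishes well-controlled ones with tight
limits, and can raise alerts at pool values the downstream process clears
comfortably.

`ipmiac` instead defines the iAC *probabilistically*: the pool value at a
unit operation for which the probability of an out-of-specification (OOS)
result at drug substance equals a pre-defined threshold (5% by default). A
run exactly at the iAC therefore still has a 95% probability of releasing
in-spec material.

## The model

### Performance indicators

Each unit operation is summarized per CQA by a performance indicator
computed from paired specific concentrations (amount per mg product) in
its load and pool:

* specific clearance for impurities, `SC = load / pool` (`SC > 1` means
  removal), and
* yield for purities, `Y = pool / load`,

with `SC * Y ≡ 1`. Specific (product-normalized) concentrations make the
indicator independent of scale and volume.

### Three model variants per unit operation

Performance is strictly positive and multiplicative, so all models work on
the natural log of the indicator (the log base is a free choice; natural
logs are used throughout):

1. **DoE model** — ordinary least squares of `log(performance)` on process
   parameters (PPs) coded to [-1, 1] against their design ranges, fitted to
   small-scale experiments. Candidate terms follow the design's resolution:
   one-factor-at-a-time studies support main effects only; the 11-run
   5×3-level design supports mains + quadratics; the 17-run face-centered
   central composite supports mains + two-factor interactions + quadratics.
   A best-subset search over all term sets respecting *strong heredity*
   (an interaction's two main effects, a quadratic's main effect, are always
   carried along) keeps subsets whose non-forced terms all have partial-t
   p < 0.1 — deliberately looser than 0.05 so potentially critical
   parameters are not screened out — and selects the largest such subset,
   breaking ties by residual standard deviation. Scale enters as a fixed
   effect when both scales are present; predictions are made at the
   manufacturing level.
2. **SC model** — `log(performance) = a + b·log(SLC)`, the dependence on
   the specific load concentration, fitted to manufacturing runs. The
   log-log form is the minimal one consistent with positivity and the log
   transform; a slope with p ≥ 0.1 flags the model as not significant, in
   which case the plain distribution model below is preferred. Predictions
   never extrapolate: loads outside the observed training range are clamped
   to the boundary (clearance assumed constant beyond it), on both sides,
   and clamped draws are counted and surfaced.
3. **Manufacturing distribution** — when neither relationship is
   supported, a normal distribution fitted to the log performance values of
   the manufacturing runs.

When a DoE and an SC model coexist at one unit operation, the DoE
prediction (valid at the DoE starting material's concentration `SLC_DoE`)
is corrected by the ratio of SC-model mean predictions at the simulation
load versus at `SLC_DoE`. The correction factor is deterministic given the
load; the DoE draw carries all stochasticity, so at `slc = SLC_DoE` the
combined model reproduces the DoE-only draws exactly. (A literal reading
of the combination rule could let the numerator be a random SC draw; that
would break the exact-identity property at the reference concentration,
so the deterministic-ratio reading was chosen.)

### Uncertainty sampling

A simulated run draws one performance value per step from the model's
*predictive distribution*: mean log-prediction plus a t-distributed error
(the model's error degrees of freedom) scaled by the prediction standard
error, which includes both parameter uncertainty — via the stored
`(X'X)^-1` of the training design — and residual variance. The 95%
prediction interval is the central region of this distribution. Sampling
*uniformly over* or *truncated at* the interval would distort propagated
variance; the truncated variant remains available as
`sampling = "truncated_95"` for sensitivity analysis. Distribution models
draw plainly from their fitted lognormal.

### Concatenation and the NOR

The integrated process model concatenates the steps: each simulated run
draws an initial load from the chain-entry lognormal, then per UO samples
every process parameter from its normal operating range (NOR), draws a
performance value, and computes `pool = load / SC` (impurity) or
`pool = load · Y` (purity); the pool becomes the next step's load. The NOR
is modelled as Normal(set-point, cv·|set-point|) with cv defaulting to 3% —
the conventional assumption when only set-points are recorded — with
variance-matched uniform and ±3 sd truncated-normal variants for
parameters that only need to stay within a range. PP draws are independent
across steps and runs (the NOR represents uncontrollable noise, so
independence is the minimal assumption).

Percent-type CQAs are capped at 100% after each step (a physical
constraint the data model would otherwise violate); capped draws are
counted. Runs producing non-finite values are aborted and counted rather
than resampled — resampling would bias the tails — and more than 10%
aborts is a hard error. Everything is driven by sub-seeds derived
deterministically from one master seed, so results are reproducible
bit-for-bit.

800 Monte-Carlo runs are the default: a convergence scan
(`convergence_scan()`) of the across-repeat variance of the DS median and
MAD over 50–1200 cycles shows 1/n decay with no severe change beyond
~800, which the acceptance suite checks.

## OOS probability

The DS distribution is summarized by a normal fit whose mean is the
arithmetic mean and whose standard deviation is the *one-sided upper 80%
chi-square confidence bound* of the sample sd,
`s·sqrt((n−1)/χ²(0.20, n−1))`. The inflation makes OOS estimates from 10
manufacturing runs comparable with those from 800 simulated runs (the
bound shrinks toward `s` as n grows). One-sided was chosen over the upper
end of a two-sided 80% interval as the simpler conservative reading;
`sided = "two"` is available. OOS is the tail area beyond the DS limit:
upper tail for impurities, lower for purities, the sum for two-sided
specifications. The fit is on the raw scale by default; attributes
spanning decades (HCP-like) use `fit_scale = "log"` — raw-scale normal
fits of a wide lognormal would be meaningless.

A plausibility check (`plausibility_check()`) compares simulation against
manufacturing runs at target conditions: density-normalized histograms
(each integrating to 1), a standardized mean difference (SMD), a
two-sample Kolmogorov–Smirnov statistic, and both OOS probabilities. The
verdict passes when the OOS values are within a factor of 10 of each other
(or both below 10⁻⁴) *and* |SMD| ≤ 1 — the location criterion is needed
because two well-separated distributions can both have negligible OOS.

## Deriving the acceptance criteria

For each (UO, CQA) the parameter sensitivity analysis:

1. builds a screening grid of mean ± 10 sd of the manufacturing pool
   values at that UO, 15 equidistant points including both endpoints,
   clipped to positive values (and to 100 for percent CQAs) with
   re-spacing, ordered toward the risky side;
2. imposes each grid value as the UO's pool — the step's own model is
   bypassed and upstream steps are skipped (they cannot influence anything
   downstream of a fixed pool);
3. simulates 800 downstream runs per grid point with common random numbers
   across points (one sub-stream per UO×CQA), which smooths the curve;
4. computes the OOS probability per point, fits an isotonic
   (non-decreasing toward the risky side) curve, and
5. reads the pool value where the curve crosses the threshold.

The crossing is interpolated between the two bracketing grid points
*on the probit scale* of the OOS estimates: OOS-vs-pool curves are
normal-tail shaped, so `qnorm(OOS)` is nearly linear in the pool value
while OOS itself is strongly convex. Raw-scale linear interpolation at the
grid's resolution biases the criterion by about −2.6% on the analytic test
chain (measured; the bias persists at 10⁴ runs per point), whereas probit
interpolation reduces it to ~0.2%. When either bracketing estimate is
exactly 0 or 1 the raw-scale fallback is used. If the curve never reaches
the threshold inside the grid the result is `not_derivable` — widening the
grid is the remedy; extrapolation is never performed.

The last modelled UO's criterion is the DS specification limit itself.
Steps with no usable data — e.g. every measurement at the assay's limit of
quantification, where no standard deviation exists — are flagged
`iac_equals_ds_spec` and also receive the DS limit, relying on the
assumption that the impurity does not increase there. Partially quantified
groups substitute LOQ/2 (the conventional conservative value) with a
warning.

## The synthetic world

The manufacturing and characterization data behind processes of this kind
are proprietary, so the package ships a fully specified synthetic process
(`make_default_process()`) that is its own generating truth: 9 unit
operations; an HCP-like impurity (ng/mg, ~4 decades of clearance, modelled
UO 1–6, all-LoQ at the viral filtration step), an aggregate-like percent
impurity and a monomer-like percent purity (both UO 2–9, the monomer
against a 98% lower DS limit); 10 manufacturing batches; OFAT (5 runs),
5×3-level (11 runs) and face-centered central composite (17 runs) designs.
Default choices, made once:

* DoE effect sizes are such that PP variation at 3% CV moves the log
  performance by ~0.5–1 residual sd — large enough to matter, small enough
  that set-point OOS stays in (0.001, 0.2), the regime in which a 5% OOS
  threshold is reachable by the sensitivity sweep.
* Impurity log-performance residual sds lie in [0.05, 0.3]. Monomer
  log-*yield* sds are ~8×10⁻⁴: a 0.05 log-sd on a yield would move a 97%
  pool by ~5 percentage points per step, which no purification step
  exhibits; the band above is an impurity-scale statement.
* SC-model training ranges span ~1.5× the propagated load log-sd — the
  range 10 manufacturing runs typically cover — so clamping is a tail
  event rather than the norm.
* The 11-run 5×3-level design is a 3×3 factorial plus (±0.5, 0): five
  levels in the first factor, three in the second, a single center point,
  resolving mains and quadratics. (A full 5×3 grid would need 15 runs,
  inconsistent with the documented 11.)

A deliberately minimal **oracle chain** (`make_oracle_chain()`) uses only
lognormal distribution models, so the DS log-value is exactly
`N(m₀ − Σmₖ, sqrt(s₀² + Σsₖ²))` and OOS probability and the iAC inversion
have closed forms (`analytic_chain_oracle()`). The acceptance suite checks
simulation, OOS estimation and criterion inversion against these closed
forms, the re-simulated OOS at the derived iAC (0.05 ± 0.01), coefficient
recovery and heredity on 200 replicated designs, the exact combined-model
identity and clamp behaviour, chi-square bound coverage, convergence
scaling, the 3SD comparison and CLI determinism.

## What a green test does and does not establish

The generator emulates the *structure* of a real downstream process, not
any particular product: no batch-to-batch PP correlation, no drift or
campaign effects, no assay-specific error structure, no interactions
between quality attributes (each CQA is propagated independently — a known
limitation of the approach), and clean lognormal noise. Green tests
establish that the machinery is mathematically correct on a world where
truth is known; they say nothing about how well three model variants can
describe any specific real process. On real data the residual diagnostics
(`residual_diagnostics()`) and the plausibility check are the gates that
must be passed before the derived criteria mean anything.

Two further honest caveats. First, the DS distribution of the full
synthetic process is *not* exactly lognormal: predictive-t draws with few
error degrees of freedom have heavy tails and the no-extrapolation clamp
truncates, both detectable by a normality test at large n. This is a
property of the method's own uncertainty model, not a bug; exact
lognormality is asserted only on the oracle chain, where it holds by
construction. Second, iACs derived this way are valid only for the
set-point conditions they were computed at: changing set-points, or a
process whose variability grows, requires re-derivation.

## Numerical choices

* Chi-square bound: one-sided, level 0.80 (`upper_sd_ci(1, 10) ≈ 1.293`).
* Degenerate (zero-variance) samples: OOS is exactly 0 or 1 by the
  position of the mean, with a degeneracy flag.
* Screening-grid lower clip: mean/1000 (concentrations are positive).
* Threshold-crossing tie-break on flat isotonic segments: the first (least
  extreme, i.e. conservative) crossing point.
* Aborted-run policy: abort and count, never resample; hard failure above
  10%.
* Seeds: one master seed; sub-streams per (CQA), per (UO × CQA) for
  sensitivity grids (common random numbers across grid points), derived by
  integer mixing kept below 2³¹.

## A worked example

```{r example, eval = FALSE}
library(ipmiac)
chain <- make_oracle_chain(4)
oracle <- analytic_chain_oracle(chain)
sim <- ipm_simulate(chain, sim_config(n_runs = 10000, seed = 1))
oos_probability(sim$ds$imp, chain$cqas$imp, fit_scale = "log")
mfg <- generate_manufacturing_runs(chain, n = 10, seed = 7)
grid <- screening_grid(mfg$pool_value[mfg$uo_id == 2 & mfg$cqa == "imp"],
                       chain$cqas$imp)
derive_iac(psa_curve(chain, 2, "imp", grid,
                     sim_config(n_runs = 800, seed = 1)), threshold = 0.05)
oracle$iac_closed_form(0.05, at_uo = 2)
```

See the README for the full 9-UO pipeline through the command-line
interface and the numbers it prints.
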