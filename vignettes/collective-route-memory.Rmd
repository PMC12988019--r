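---
title: "Quantifying collective route memory in homing pigeons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective route memory in homing pigeons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routemem)
```

## The scientific question

Homing pigeons trained in stable pairs learn idiosyncratic routes home.
If the two members of a pair later forget *different* parts of the route,
the pair as a collective may retain a more faithful route memory than
either bird alone — a distributed memory. `routemem` implements the full
analysis chain needed to test this: GPS track preprocessing, route-fidelity
metrics against baseline routes, and multimember mixed-effects inference
over a two-site, two-treatment, paired-vs-solo factorial design, together
with a synthetic flight generator that reproduces the design's statistical
structure so every stage can be validated without field data.

## Design encoded by the generator

Each of 14 pairs trains at two release sites (the Oxfordshire coordinates
of the original protocol are the defaults: 8.1 km and 7.3 km beelines to
the loft). At the end of training, three tracked paired releases —
the *baseline routes* — are interspersed with tracked solo releases. One
site per pair is assigned to a *forgetting* treatment (a release-free gap
before memory testing), the other to an *extra-training* treatment (extra
paired releases, two of them tracked, then a shorter gap). At memory
testing each pair, at each site, is released either paired or with both
members solo (balanced within treatment × site).

The generator models a pair's route as a corridor of waypoints with
perpendicular Gaussian offsets about the beeline (sd
`corridor_sd_m = 400` m), flown at `step_speed_kmh = 65` km/h, sampled at
1 Hz with iid GPS jitter (`gps_noise_m = 15` m). Two further components
make the synthetic data behave like repeated real flights:

* **Release-to-release route drift.** A flight does not retrace the
  corridor to GPS precision: a perpendicular jitter (marginal sd
  `flight_jitter_sd_m = 150` m) is drawn once per release and shared by
  both birds of a paired release, so within-pair coherence is preserved
  while successive releases differ at route scale. The jitter follows a
  stationary AR(1) chain across a pair's releases at a site
  (`flight_jitter_ar = 0.7`): consecutive flights resemble each other
  more than distant ones, as repeated homing tracks do. Without this
  component, baseline flights would sit within ~15 m of each other and
  the route-memory metrics would measure nothing but GPS noise.
* **Differential forgetting.** At memory testing each bird independently
  retains each interior waypoint with probability
  `retention_forgetting = 0.6` (forgetting treatment) or
  `retention_extra = 0.9` (extra training); a Gaussian copula
  (`retention_correlation`, default 0) allows correlated forgetting. A
  forgotten waypoint collapses toward the beeline with fresh perpendicular
  noise (`lost_segment_sd_m = 800` m). A pair tested together flies the
  *pooled* memory: under the default `distributed` rule each waypoint
  retained by either member is kept (expected pooled retention
  $1-(1-p)^2$), which is the mechanism that produces collective memory;
  the alternative `leader` rule flies the waypoints of the member with
  the larger retained count, and produces no such gain.

Retention probabilities are free parameters of the generator — the field
study estimates no forgetting rate — chosen so the differential-forgetting
effect is detectable at 14 pairs. At these defaults the *pooled* pair
memory in the extra-training treatment is essentially at ceiling
(expected retention 0.99) but solo birds still forget about one waypoint,
which remains detectable on the log scale against the 150 m route-drift
floor; a fully null extra-training treatment needs `retention_extra`
near 1. Slow pre-departure dawdling and a loft approach are
injected into every track so the preprocessing rules always have work to
do.

## Preprocessing

The cleaning rules follow the field protocol, in protocol order:

1. **Speed filter**: fixes slower than 30 km/h are stationary and removed.
   Speeds are computed *once* on the raw track and thresholded; the filter
   is therefore deterministic and idempotent by construction (re-running
   with recomputed speeds is deliberately not done).
2. **Homing-segment trim**: from the final departure out of 2 km of the
   release point to the first entry within 500 m of the loft, boundary
   fixes included.
3. **Joined-flight detection**: every 30 s, a fix is checked against
   tracks of separately released birds for proximity within 50 m; the
   time-matching tolerance is ±15 s (half the check interval). Any flag
   excludes both tracks — the protocol's manual map inspection is replaced
   by this deterministic rule, with all flags logged for audit.
4. **Split truncation**: a paired release is truncated at the earliest
   moment the birds exceed 150 m separation and never re-establish
   proximity within that same radius; distances are evaluated on a common
   1 s grid with gaps forward-filled up to 5 s.

Every removal or truncation is recorded in an exclusion ledger
(release, bird, rule, detail).

## Metrics

For a test track $T$ and baseline routes $B_1,\dots,B_k$ (pooled fixes of
the pair's tracked paired baseline releases at that site):

* **mean NND** $= \frac{1}{|T|}\sum_{x \in T}\min_{y \in \cup_j B_j} d(x,y)$
* **2nd-order mean NND** $= \frac{1}{k}\sum_j \frac{1}{|T|}\sum_{x \in T}\min_{y\in B_j} d(x,y)$,
  robust to a variable number of baseline routes (it never decreases when
  routes are added, whereas the pooled minimum does)
* **homing efficiency index (HEI)**: beeline distance between first and
  last fix over path length, in (0, 1].

Distances are point-to-point (1 Hz sampling makes point-to-segment
differences negligible) and spherical great-circle (mean radius
6371.0088 km); the exported `geo_distance()` defaults to the WGS84
ellipsoidal geodesic, which is what reproduces the protocol's printed
site distances (8.1 km / 7.3 km) at their printed rounding — the two
conventions differ by under 0.3 % at these scales.

Baseline-testing tracks are compared only against *previously recorded*
baseline routes (so the first tracked baseline release contributes
efficiency only); memory-testing tracks are compared against all of the
pair's baselines. A paired release contributes one observation: the raw
metrics of the two birds are averaged and transforms applied afterwards
(`log` for the NND metrics, $\log((1-\mathrm{HEI})/\mathrm{HEI})$ for
efficiency). Degenerate values possible only in noise-free synthetic
fixtures are clamped and reported (NND 0 → 1 m; HEI 1 → $1-10^{-6}$).

## The multimember mixed model

Each response is analysed with
`response ~ condition * treatment * testing_time + site` plus random
intercepts for individuals and pairs. A paired observation loads on
*both* member birds with weight 0.5 (a solo observation with weight 1),
giving the multimember covariance

$$V = \sigma^2 I + \sigma^2_{ind} Z_1 Z_1^\top + \sigma^2_{pair} Z_2 Z_2^\top.$$

The REML criterion is maximised over the log variance ratios with
$\sigma^2$ profiled out; all linear algebra runs in the random-effect
space through the Woodbury identity, so a criterion evaluation is
$O(q^3)$ in the number of random-effect levels, not observations.
Nelder-Mead from three dispersed starts is combined with explicit
optimisation of every boundary sub-model (each subset of components
pinned at zero), so singular fits are reported as boundary fits rather
than failures; convergence is declared at a relative criterion change
below 1e-10. Fixed effects are the GLS solution at the optimum, with
covariance $(X^\top V^{-1} X)^{-1}$.

Wald tests use the standard-normal reference (no denominator-df
correction), matching the convention of reporting $t$ and a Wald $p$
without degrees of freedom; this is an approximation at these sample
sizes. Planned contrasts are obtained by refitting the identical model
with releveled factors — a pure reparameterisation that leaves the REML
log-likelihood unchanged (asserted in the tests to 1e-8) and equals the
corresponding contrast-vector computation on the original fit. Residual
diagnostics whiten the marginal residuals with the Cholesky factor of
the fitted covariance and apply a one-sample Kolmogorov–Smirnov test
against N(0,1); the test ignores parameter estimation, as is common
practice, so borderline p-values deserve a look at the returned QQ data.

The pair-vs-better-solo comparison reduces the table, per metric, to the
member with the smaller metric among pairs whose two members were both
tested solo at a round; the selection is made independently per metric,
so the "better" bird may differ between mean NND and 2nd-order mean NND.

## Validation studies and problem sizes

The package validates its inference machinery by simulation, at sizes
chosen to keep the full suite fast while leaving the physical scales and
the 14-pair design untouched:

* **Oracle equivalence**: metrics agree with brute-force double loops to
  1e-9 relative on 100 random fixtures; the REML fit dominates a dense
  $51^3$ grid over the variance components on a 40-observation
  multimember toy and collapses to OLS when the truth has no random
  variance.
* **Type-I calibration**: 1000 replicate experiments under the
  no-forgetting null (retention 1 in both treatments), recording the
  memory-testing pair-vs-solo Wald contrast on log mean NND.
* **Effect recovery**: 200 replicate experiments at the default effect
  size, checking the sign of the contrast, its 2-SE coverage of the
  long-run generating value, and the power of the condition ×
  testing-time interaction. One distinction matters when reading the
  coverage number: with 12 interior waypoints the *realized* forgetting
  effect differs between replicate experiments (binomial retention), so
  the within-experiment SE covers the long-run mean at less than the
  nominal rate even though the estimator itself is well calibrated — a
  toy study with a known fixed effect recovers it within 2 SE at ≥ 90 %.

The replicate studies use `replication_config()`: an 8 s GPS sampling
interval (≈145 m fix spacing, still dense against the 400–800 m corridor
scales) and shortened dawdle/approach phases; the joined-flight scan is
skipped there because the generator's release spacing keeps flight
windows disjoint.

A caveat the calibration study makes explicit: expected log NND depends
on the number of previously recorded baseline routes a track is compared
against (fewer routes, larger nearest-neighbour distances). The factorial
model — by design, the protocol's — does not adjust for that count, so
part of the baseline rows' variation around their cell means is
structural, inflating the pooled residual variance relative to the
variability of the memory-testing cells. The memory-testing contrast is
therefore slightly *conservative* under the null: across 1000 null
replicates its t-statistics have standard deviation ≈0.87 rather than 1,
an empirical rejection rate near 2.5–3 % at nominal 5 %. The AR route
drift keeps this mild (with independent release-to-release jitter it
would be far more severe); users comparing cells with very different
baseline counts should prefer the 2nd-order metric and treat marginal
p-values cautiously.

## What the generator does and does not emulate

It reproduces the design's factor structure, route-scale corridor
idiosyncrasy, within-pair coherence, release-to-release drift,
differential forgetting and its pooling — the features the analysis
consumes. It does not model flocking dynamics, wind, landmarks,
time-of-day effects, or bird-specific flight styles; GPS noise is iid
rather than autocorrelated; and retention probabilities are free
parameters, not field estimates. Passing the validation studies
demonstrates that the *pipeline* measures what it claims on data with
the assumed structure — it cannot certify the biological model itself.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), out_dir = "pigeon-run")
subset(res$contrasts, comparison == "pair_vs_solo_memory" &
         response == "log_mean_nnd")
```

The contrast table contains every comparison the analysis reports: pair
vs solo at memory testing and at baseline per treatment, the condition ×
testing-time interaction per treatment, pair vs better solo (route-memory
metrics), and the baseline-to-memory efficiency change per condition and
treatment.

## Known limitations

* Point-to-point (not point-to-segment) nearest neighbours; negligible at
  1 Hz but a genuine approximation at sparse sampling.
* Wald inference with a normal reference; no Satterthwaite or
  Kenward–Roger correction.
* The multimember weight convention (0.5/0.5 per paired observation,
  mirroring the response averaging) is a modelling choice, exposed as
  `model_spec(paired_weight = )`.
* Real logger quirks (drop-outs, multipath spikes) are not simulated;
  the preprocessing rules are exercised by constructed slow phases
  instead.
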