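---
title: "Gross N transformation rates by 15N isotope pool dilution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gross N transformation rates by 15N isotope pool dilution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdrates)
library(dplyr)
```

## The problem

Net changes in ammonium or nitrate concentration hide the turnover behind
them: a pool that looks static may be produced and consumed at high equal
rates. Isotope pool dilution (IPD) separates the two. A small amount of the
pool is replaced by highly $^{15}$N-enriched tracer; gross production then
feeds the pool with N at natural abundance and *dilutes* the label, while
gross consumption removes N at whatever enrichment currently prevails.
Tracking pool size and enrichment at two incubation times therefore yields
both gross rates.

`ipdrates` implements this calculation for assays on solid matrices
(soils, waste, sediments) — ammonium for gross N mineralization, nitrate
for gross nitrification — together with the bookkeeping around it (blank
correction, atom-percent-excess, tracer planning, unit conversions),
headspace N$_2$O screening, group statistics, and a forward simulator used
as ground truth for validation.

## Model and assumptions

Between tracer addition and termination the pool is assumed to follow the
two-pool model with constant (zero-order) gross production $GP$ and gross
consumption $GC$:

$$\frac{dC}{dt} = GP - GC, \qquad
  \frac{d(C\cdot APE)}{dt} = -\,GC \cdot APE,$$

where $C$ is the pool in mg N (kg DM)$^{-1}$ and $APE$ the atom percent
$^{15}$N excess above the unlabeled background. Production enters at
natural abundance (zero excess), consumption leaves at the current
enrichment, and remineralization of freshly assimilated tracer is assumed
negligible over the assay window. Solving between two sampling times
$t_1 < t_2$ and inverting gives the estimators implemented in
`gross_production()` and `gross_consumption()`:

$$GP = \frac{c_{2} - c_{1}}{t_2 - t_1}
       \cdot \frac{\ln(APE_{1}/APE_{2})}{\ln(c_{2}/c_{1})},
\qquad
GC = \frac{c_{1} - c_{2}}{t_2 - t_1}
     \cdot \left[1 + \frac{\ln(APE_{2}/APE_{1})}{\ln(c_{2}/c_{1})}\right].$$

Two consequences are used as internal checks throughout the test suite:
$GP - GC = (c_2 - c_1)/(t_2 - t_1)$ holds identically, and applying the
estimators to any two points of the model's own trajectory returns the
generating rates to machine precision.

Before the rate equations, each labeled measurement is corrected for
reagent-N carried through extraction and microdiffusion
(`blank_correct()`), using the total N mass of the measured aliquot and of
a procedural blank; unlabeled background samples are left uncorrected
because their enrichment is indistinguishable from the blank's. The
corrected enrichment minus the background enrichment of the unlabeled
reference gives the APE.

### Validity screening

The model requires enrichment to *fall* between $t_1$ and $t_2$. Pairs in
which it rises — or declines by less than `ape_tol` (default $10^{-6}$
at%, i.e. less than numerical noise) — violate the assumptions and are
excluded with an explicit reason rather than producing a number. Negative
computed rates from accepted pairs are reported, not clamped: deciding
whether they are physical is an interpretation question, not an arithmetic
one. This mirrors how such assays fail in practice: when a large pool
(~1000 mg N kg DM$^{-1}$) turns over slowly (~50 mg N (kg DM day)$^{-1}$,
a mean residence time near 20 days), the enrichment decline over 24 h is
comparable to IRMS measurement error and most pairs fail the screen — the
method becomes insensitive, which the simulator reproduces (see below).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `times_h` | 4, 24 | h | termination times; $\Delta t = 5/6$ day |
| `target_fraction` | 0.1 | – | tracer share of the (native or spiked) pool |
| `label_enrichment` | 98 | at% | tracer enrichment |
| `spike_floor` | 15 | mg N kg DM$^{-1}$ | added pool size in spike mode |
| `background_atpct` | 0.3663 | at% | natural abundance vs AIR ($\delta = 0$) |
| `ape_tol` | $10^{-6}$ | at% | minimum accepted APE decline |
| `conc_tol` | $10^{-6}$ | – | relative $c_1 \approx c_2$ switch to the analytic limit |
| `alpha` | 0.05 | – | family-wise level of Tukey comparisons |

Internal time is days, so rates are mg N (kg DM day)$^{-1}$ as commonly
reported; the 4 h / 24 h design gives $\Delta t = 5/6$ day. The isotope
scale is atom percent everywhere internally; $\delta^{15}$N conversions
(vs the AIR ratio 0.0036765) are explicit via `delta_to_atom_percent()`
and never implicit, and only APE *ratios* enter the estimators, so a
consistent scale is all that matters. Tracer additions target ~10% of the
pool at 98 at%, which lands the initial enrichment near 10 at%; pools too
small to measure are instead raised by a fixed spike (10% label : 90%
carrier) to the measurability floor.

## The synthetic campaign

`simulate_pool()` draws one assay from the closed-form trajectory, mixes
blank N into each aliquot (so the pipeline's blank correction is exercised
as an inverse problem), then applies measurement noise: lognormal and
mean-preserving on concentrations (default CV 5%), Gaussian truncated to
physical bounds on enrichments (default SD 0.1 at%). `simulate_study()`
expands a design table over groups, sampling days and replicate reactors
(n = 3), plans pool- or spike-mode tracer additions by pool size, adds
lognormal between-reactor variability on the true rates (CV 30%), and
emits the CSV-ready schema the pipeline consumes, plus a ground-truth
table. The default design (`default_study_cells()`) spans the magnitudes
reported for landfill-style reactors — ammonium pools near 1000 mg N
kg DM$^{-1}$ early and under anaeroby with fluxes of tens to hundreds,
small aerated pools with $GP \approx 3.7$ and $GC \approx 35.7$ around day
110, nitrate pools of 5–55 with nitrification fluxes up to ~30 — with
pools adjusted where needed so the zero-order window never exhausts them
(the truth table always records the rates actually simulated).

What the generator deliberately does *not* emulate: first-order or
time-varying kinetics, remineralization, spatial heterogeneity of the
solid matrix beyond a lognormal reactor effect, and correlated errors
between the two termination times. Passing recovery tests therefore show
that the estimator chain is self-consistent and robust to measurement
noise of the stated magnitude — not that field data obey the zero-order
model.

Noise magnitudes deserve one caveat. With CV 5% on concentrations, the
$\Delta c/\Delta t$ term that separates $GC$ from $GP$ carries an absolute
error of roughly $\sqrt{2}\,\mathrm{CV}\,c_0/\Delta t$ regardless of the
rate's size, so *per-replicate* relative errors of recovered $GC$ are
large (median $\approx$ 20% at $c_0 \approx 110$, $GC = 30$). The
recovery criterion is therefore stated on the *median recovered rate*
across replicates, which is nearly unbiased (within ~2% here); per-pair
dispersion is a property of the assay, not of the implementation.

```{r recovery-example}
sim <- simulate_pool(sim_config(gp_true = 12, gc_true = 30,
                                c0 = 110, at0 = 9.24, seed = 1))
ipd_rates(sim$incubations, sim$blanks) %>%
  select(reactor_id, day, assay, gp, gc, net, valid)
```

## Statistics

Group summaries follow the convention of reporting the mean per
operational group with 1 SE ($sd/\sqrt{n}$), with the reactor as the
aggregation unit: technical replicates are averaged within reactor first.
A cell with a single valid reactor reports its mean with the SE flagged
undefined — no statistical evaluation is possible there, and the pipeline
says so instead of inventing a zero. Differences among cells are tested by
one-way ANOVA followed by Tukey's HSD at 95% family-wise confidence
(`anova_tukey()`, with `tidy()`/`glance()` accessors); no additional
multiplicity layer is applied. Designs too sparse to test return a
structured skip so batch pipelines keep running.

## Numerical choices

* At $c_1 = c_2$ the rate equations are $0/0$; within `conc_tol` relative
  difference the analytic limit $(c_1/\Delta t)\ln(APE_1/APE_2)$ is used
  (both estimators coincide there, net zero).
* The exclusion comparison uses an absolute tolerance (`ape_tol`) so that
  floating-point noise cannot make a flat enrichment pass as dilution.
* A zero-mass blank is treated as the exact identity rather than
  evaluating the correction formula, avoiding one-ulp perturbations.
* Records are paired by replicate index within reactor × day × assay,
  not on time-point means; unpairable records surface as structured
  exclusions.
* With a constant response the ANOVA F statistic is defined as 0 (ratio of
  two zero mean squares) rather than the indeterminate value `aov()`
  returns.
* All randomness flows from one master seed through deterministic
  sub-seeds recorded in the truth table; pipeline outputs are
  byte-reproducible.

## Problem sizes used in validation

The shipped validation uses $10^4$ random inputs for the algebraic
identity, a $20 \times 20$ log-spaced rate grid (0.5–500 mg N
(kg DM day)$^{-1}$, including the $GP = GC$ diagonal) for oracle
equivalence cross-checked against stiff ODE integration, 1000 noisy
replicates for parameter recovery, and 1500 replicates per regime for the
large-pool insensitivity contrast; these sizes give stable medians and
fractions while keeping the default check fast.

## Known limitations

The estimators assume constant gross rates over the window; strongly
depleting pools (consumption approaching the pool size per day) violate
this before 24 h, and the simulator refuses such scenarios rather than
silently extrapolating. Remineralization corrections, non-constant-rate
numerical IPD estimators, isotopomer-based N$_2$O source partitioning and
tracer mass balance in the solid phase are out of scope. N$_2$O handling
is screening only — concentration and enrichment plausibility against the
tracer-derived ceiling — not flux estimation.
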