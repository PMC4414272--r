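---
title: "Modelling UBL-tag cleavage: product-inhibited kinetics, rate estimation and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UBL-tag cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ublcleave)
```

## The kinetic model and its assumptions

Tag removal by a UBL-specific protease is a single-cut reaction
S → P + P′ in which the released UBL module P keeps binding the protease:
it presents almost the same interaction surface as the intact substrate.
The package therefore models cleavage velocity with a competitive
product-inhibition extension of Michaelis–Menten kinetics,

$$v = -\frac{dS}{dt} =
  \frac{k_{cat} E_0 S}{K_M\left(1 + P/K_P + S/K_M\right)},$$

implemented in `rate_full()`. Three modelling commitments are built in:

* **Total enzyme is used throughout.** Free enzyme is never tracked, so
  depletion of enzyme by tight binding to product is not modelled. This
  is the standard quasi-steady-state treatment and is consistent with the
  micromolar enzyme / hundred-micromolar substrate regime the assays use.
* **Only one product inhibits.** The second product P′ (the untagged
  target) leaves the protease's recognition surface with the UBL module,
  so it is produced 1:1 with P but not represented as state. Mass
  conservation reads S + P = S0.
* **Units are fixed package-wide**: concentrations in µM, time in
  minutes, rates in min⁻¹. These match the assay scales (µM substrate,
  minutes-to-hours incubations); any conversion belongs at the I/O
  boundary, not inside the model.

Because substrate and product share the interface, it is natural to
assume they bind with similar affinity, $K_P = K_M$ (`rate_equal_affinity()`).
With the stoichiometric substitution $P = S_0 - S$ the rate law then
collapses to exact first-order decay with the apparent rate

$$k_{app} = \frac{k_{cat} E_0}{K_M + S_0},$$

(`kapp_from_params()`), so the cleaved fraction follows the single
exponential $f(t) = 1 - e^{-k_{app} t}$ (`fraction_cleaved()`). No
experiment in this setting identifies $k_{cat}$, $K_M$ and $K_P$
separately from fraction-only progress data at one substrate
concentration, and the package deliberately does not try: $k_{app}$ is
the comparable quantity, and the three constants are free simulation
parameters.

A note on orientation: with first-order substrate decay the *remaining*
fraction is $e^{-k_{app}t}$ and the *cleaved* fraction its complement.
The public API reports the cleaved fraction, because that is what gels
are quantified for (completeness of cleavage).

## When the single exponential is trustworthy

The equal-affinity assumption is exactly that — an assumption. The
simulator exists to quantify its cost. `simulate_ode()` integrates the
full rate law (deSolve's `lsoda`, relative tolerance 1e−8, absolute
1e−10 µM; the system is one-dimensional and cheap, and tolerances this
tight make equivalence testing against the closed form meaningful), and
`sweep_kp_ratio()` scans $K_P/K_M$:

```{r sweep}
base <- kinetic_params(kcat = 1, K_M = 10, K_P = 10, E0 = 0.5, S0 = 100)
horizon <- 3 / kapp_from_params(base)$k_app
sweep_kp_ratio(base, c(0.1, 0.5, 1, 2, 10), horizon)
```

At $K_P = K_M$ the deviation is at solver tolerance. The deviation is
*signed*: weaker product inhibition ($K_P > K_M$) can only accelerate
cleavage relative to the exponential, stronger inhibition only retard it
— a property the test suite checks at every interior time point. A
2-fold affinity mismatch already distorts the progress curve by ~0.1 in
fraction, so single-point rate comparisons implicitly lean on the shared
interface argument; they should be read as comparisons, not absolute
rate measurements.

The default output grid (`time_grid()`) places 60 log-spaced points plus
t = 0 over the horizon: progress-curve curvature is concentrated at early
times.

## Estimating apparent rates

`kapp_single_point()` inverts the exponential for a single lane:
$k_{app} = -\ln(1-f)/t$. A saturated lane ($f = 1$ at gel resolution)
carries no rate information and returns a censored lower-bound object
rather than a number. `kapp_fit()` generalises to multi-point courses by
nonlinear least squares of $f(t) = 1 - e^{-kt}$ with **no intercept and
no free amplitude** — the model structurally forces completion at 1, so a
fitted amplitude would only launder systematic deviations into the rate.
Saturated points are dropped when at least two unsaturated points remain;
when only one unsaturated point exists they are retained as right-censored
at $1 - \epsilon$ with $\epsilon = 0.01$ (one gel-resolution step below
complete); a course that is saturated everywhere is an error, not a fit.

Summary statistics built on rates:

* `fold_excess(S0, E0)` — molar substrate excess; with near-complete
  cleavage it equals the average turnover per enzyme molecule.
* `min_complete_conc()` — lowest titration concentration reaching a
  near-complete threshold. "Near complete" is not a number the gels
  define; the default is 0.95, since mixed cleavage standards resolve
  roughly 5% increments, and it is configurable. Noisy, non-monotone
  titrations still return the smallest passing concentration but carry a
  quality flag when a higher concentration fails — the lowest-lane-fully-
  cut reading of a gel, with the inconsistency surfaced instead of hidden.
* `compare_activity()` — fold difference with direction, refusing to
  compare measurements whose substrate, temperature, substrate
  concentration or NaCl differ (these are the axes assays actually vary);
  min-concentration inputs are inverted (less enzyme = more active), and
  censored inputs propagate as bounds.
* `overdigestion_fold()` — applied over minimal sufficient enzyme; a
  minimal concentration known only as "< x" makes the fold a lower bound.

## Densitometry calibration

Gels report band intensities, not fractions. For a lane with full-length
band intensity $I_{fl}$ and C-terminal cleavage-product band $I_{ccp}$,
the package uses the one-parameter response model

$$f = \frac{I_{ccp}}{I_{ccp} + r\,I_{fl}},$$

where $r$ is the per-mole staining ratio of the two bands. One scalar
suffices because Coomassie response is approximately mass-proportional;
fitting anything richer against a handful of standard lanes would be
over-parameterised. `build_standard_curve()` estimates $r$ by least
squares against lanes mixed to known fractions, on a log scale (a ratio
should be fitted multiplicatively), requiring at least one interior lane
— pure 0% and 100% lanes are reproduced exactly under *any* $r$ and so
cannot identify it. Without standards, `mass_ratio_curve()` supplies the
mass-proportional default $r = m_{ccp}/m_{fl}$. The default mixing ladder
{0, 0.10, 0.25, 0.50, 0.75, 0.90, 1} brackets the calls a titration gel
must make ("near complete", "about half").

## Cross-reactivity and orthogonality

`classify_cell()` maps a digestion outcome onto the four-level key
`++` (highly efficient cleavage), `+` (cleavage), `-` (traces),
`--` (none). The default cutoffs 0.90 / 0.10 / 0.01 are a package choice,
not an assay constant: 0.90 for "essentially complete", 0.10 as the
clear-band boundary, 0.01 as the typical Coomassie detection limit for a
trace band. All are configurable.

`orthogonality_calls()` works on cognate protease/substrate pairs: two
pairs are mutually orthogonal iff neither protease cleaves the other's
substrate above the trace cutoff at the *maximum tested concentration* —
orthogonality is only meaningful when heavy over-digestion still shows
nothing. The default strictness demands the `--` category; tolerating
traces is an explicit option. Verdicts are symmetric by construction,
self-pairs are excluded by definition, and raising the trace cutoff can
only add orthogonal pairs. Maximal mutually-orthogonal sets are the
maximal cliques of the orthogonality graph (via igraph).

## Synthetic data: what it emulates, what it does not

Every assay the pipeline consumes has a seeded generator:
`gen_timecourse()` (progress curves, optionally with forward-modelled
band intensities), `gen_titration()` (dilution series), `gen_crossreact()`
(all-against-all panels from a planted specificity matrix),
`gen_standards()` (mixed cleavage-standard lanes). All are pure functions
of their parameters and a seed; one global seed feeds per-generator
streams through a label hash, so adding a generator never reshuffles
existing streams.

The noise model is multiplicative log-normal intensity noise per band
(default CV 0.10, a typical Coomassie densitometry repeatability figure —
the source assays report no error bars, so this is a stated default, not
a fitted one), an optional additive baseline, and optional additive
Gaussian noise directly on fractions for assays recorded as fractions.

Generator defaults mirror the wet-lab conditions the assays describe:
100 µM substrate; sub-µM protease for time courses; 20-h titrations at
37 °C; 20 µM protease, 3 h, 25 °C for specificity panels. The validation
studies use: a 5×5×5 lattice of (kcat, K_M, S0) for ODE/closed-form
equivalence; 200 seeded 8-point courses at fraction noise σ = 0.02
(about half a ladder increment) for rate recovery; 500 standard-ladder
replicate lanes at CV 0.10 for densitometry recovery. The ladder-replicate
design for lanes reflects what a mixed-standards gel actually contains;
recovery is hardest at mid-range fractions (error in the band *ratio* is
maximal there) and trivially easy at the endpoints.

What passing these tests shows: the estimators invert the generators —
rates, response factors, minimal concentrations and planted specificity
patterns are recovered under the stated noise. What it does not show:
real gels have correlated lane artefacts, background subtraction errors,
partial proteolysis side products and staining nonlinearity at high load,
none of which the noise model represents. Synthetic recovery is a
necessary check of the arithmetic, not a validation of densitometry as a
measurement technique.

## File formats and configuration

All tables share one CSV dialect (comma-separated, `.` decimal, UTF-8,
`#` comments); writers stamp a header comment with package version, seed
and a configuration hash so every file traces to its run. Readers
validate required columns and cell ranges with file/line/column in the
error, and pass unknown columns through untouched. Grid *completeness*
is deliberately not a parser concern: a partial grid parses fine, and
`orthogonality_calls()` raises the incomplete-grid error naming the
absent pairs — separating transport from analysis contracts.
`read_run_config()` reads a YAML key/value file (seed, thresholds,
integrator tolerances, paths) over package defaults and rejects unknown
keys and out-of-range thresholds.

## Known limitations

* $k_{cat}$, $K_M$, $K_P$ are not separately identifiable from the data
  the pipeline consumes; only $k_{app}$ is estimated.
* No temperature or salt dependence is modelled; conditions are metadata
  used to guard comparisons, not model inputs.
* Enzyme depletion by tight product binding and multi-substrate
  competition are outside the rate law.
* Band extraction from gel images is out of scope; intensities are
  assumed already quantified.
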