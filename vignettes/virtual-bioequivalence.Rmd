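---
title: "Virtual bioequivalence for modified-release formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual bioequivalence for modified-release formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vbesim)
```

## The problem

When an oral modified-release product is reformulated — a new strength, a new
piece of manufacturing equipment, or an individually manufactured (e.g. 3D
printed) batch — regulators normally ask for a bioequivalence (BE) study with
pharmacokinetic endpoints: the 90% confidence interval of the test/reference
geometric mean ratio (GMR) for Cmax and AUC must fall within 80–125%. For
drug products whose composition changes per patient, running a clinical BE
study per variant is infeasible. A *virtual* bioequivalence (VBE) study
replaces dosed volunteers with simulated ones: in vitro dissolution profiles
characterise each formulation, a pharmacokinetic model turns release into
plasma exposure for a virtual population, and the usual BE statistics are
applied to the simulated endpoints.

`vbesim` implements that workflow end to end for the simplest well-posed
case: a highly soluble, highly permeable (BCS class 1) compound for which
neither dissolution in vivo nor permeability limits absorption, so that
*formulation release alone* controls the input of drug into the body.

## Dissolution: the f2 similarity factor

Candidate formulations are screened against the reference with the
model-independent similarity factor

$$ f_2 = 50\,\log_{10}\!\left(100\left[1 + \tfrac{1}{n}\textstyle\sum_{t=1}^n (R_t - T_t)^2\right]^{-1/2}\right), $$

where $R_t$ and $T_t$ are mean percent dissolved at the $n$ shared sampling
times. Identical curves give $f_2 = 100$; a uniform offset of
$\sqrt{99} \approx 9.95$ percentage points gives exactly 50; profiles are
declared similar in the band 50–100.

```{r}
ref <- c(10, 30, 50, 70, 85)
test <- c(15, 35, 55, 75, 90)
compute_f2(ref, test)
```

Two conventions exist for which points enter the sum. By default
`compute_f2()` uses *all* shared time points of the replicate-mean profiles.
The regulatory convention of retaining at most one point after both products
exceed 85% dissolved is available as `truncate_85 = TRUE`, and a
replicate-level mode (`level = "replicate"`) returns the f2 of every
reference-vessel × test-vessel pairing for sensitivity checks.

## The Weibull release model

Each formulation's cumulative release is summarised by the four-parameter
Weibull curve

$$ F_\mathrm{diss}(t) = F_\mathrm{max}\left(1 - e^{-((t-\mathrm{lag})/\alpha)^\beta}\right), $$

with plateau $F_\mathrm{max}$ (percent), lag time (h), time scale $\alpha$
(h) and dimensionless shape $\beta$. Note that the Weibull appears in the
dissolution literature in two parameterisations; the alternative
$\exp(-(t-\mathrm{lag})^\beta / a)$ maps onto this one via $a = \alpha^\beta$.
We use the scale/shape form because $\alpha$ then has units of time (it is
the time past the lag at which 63.2% of the plateau is released, for any
$\beta$), which makes population variability on it interpretable.

`fit_weibull()` estimates the four parameters by bounded least squares
against the replicate-mean profile (Levenberg–Marquardt with box bounds).
The objective is multimodal in ($\mathrm{lag}, \alpha, \beta$), so the
optimiser is restarted from three deterministic starts built from
data-driven heuristics — plateau height for $F_\mathrm{max}$, time to 63.2%
of the plateau for $\alpha$, $\mathrm{lag} = 0$, and $\beta \in \{0.6, 1,
1.6\}$ — and the best residual sum of squares wins. Deterministic starts
(rather than randomly jittered ones) keep fits bit-reproducible.

### What is and is not identifiable

A practical caveat found while validating the fitter: on the standard 9-point
sampling grid (1, 2, 4, 6, 8, 12, 16, 20, 24 h) with replicate noise of ~2
percentage points, $F_\mathrm{max}$, $\alpha$ and $\beta$ are recovered with
median relative errors of a few percent (with 7 replicate vessels: roughly
1%, 2% and 3.5%), but a *short lag* is not. For a true lag of 0.5 h the
Fisher information carried by a grid whose first sample is at 1 h bounds the
achievable standard deviation at roughly 0.14 h (7 replicates), i.e. a
best-case median relative error near 19% — no estimator can do better from
these data. Downstream results are insensitive to this: release-limited
absorption integrates over the release curve, and a ±0.1 h shift in lag is
invisible in Cmax and AUC. But fitted lag values should not be
over-interpreted, and sampling before 1 h is required if the lag itself is of
interest.

## The reduced oral PK model

The simulator deliberately uses the smallest mechanistic structure that
preserves what matters for a BCS-1 VBE question — *how fast drug appears* —
rather than a full physiologically based (multi-segment gut, tissue
partitioning) model:

* each dose is an undissolved depot releasing into a dissolved gut
  compartment at the time-derivative of the Weibull curve (superposed over
  dose events);
* dissolved drug is absorbed with first-order rate `ka` (default 2 h⁻¹) and
  fraction absorbed `Fa` (default 1), both fast/complete so that release is
  rate-limiting;
* disposition is one-compartment with well-stirred hepatic clearance
  $CL_h = Q f_u CL_\mathrm{int,eff}/(Q + f_u CL_\mathrm{int,eff})$ plus renal
  clearance.

All kinetics are linear, so dose proportionality and superposition hold
exactly and single-dose $AUC_{0-\infty} = F_a (F_\mathrm{max}/100) D / CL$
provides a mass-balance oracle. The system is integrated with a
stiff-capable solver (`deSolve::lsoda`, relative tolerance 1e-8, absolute
1e-10) on a grid of 4 points/h anchored at dose events. The instantaneous
release limit $\alpha \to 0$ is handled exactly as a bolus into the gut
compartment (`release = NULL`, or $\alpha$ below $10^{-8}$ h), in which case
the profile is the classical Bateman double exponential — one of the solver's
validation oracles.

Competitive inhibition of the two metabolising enzymes (CYP1A2, CYP3A4) is
modelled statically: at constant unbound inhibitor concentration $I_u$,

$$ CL_\mathrm{int,eff} = CL_\mathrm{int}\left[\frac{fm_{1A2}}{1 + I_u/(K_{i,1A2} f_{u,inc,1A2})} + \frac{fm_{3A4}}{1 + I_u/(K_{i,3A4} f_{u,inc,3A4})} + fm_\mathrm{other}\right], $$

with each $K_i$ corrected to an unbound basis by the incubation unbound
fraction. In the linear, flow-non-limited limit the steady-state AUC ratio
with/without inhibitor equals $CL_\mathrm{int}/CL_\mathrm{int,eff}$, which is
the cross-check `steady_state_auc_ratio()` is tested against (agreement
within 2%). When hepatic extraction is appreciable the well-stirred model
damps the interaction below the static prediction, which the simulated route
captures and the algebraic one does not.

## Virtual populations

Inter-individual variability is placed on parameters independently, each
drawn log-normally with median equal to the base value and
$\mathrm{sdlog} = \sqrt{\ln(1 + CV^2)}$ — the standard pharmacometric choice
that preserves positivity and the interpretation of the base value as the
population median. Release parameters default to CV 10% each, the
conventional allowance for in vivo dissolution variability on top of low in
vitro variability; clearance and volume CVs are configurable (the shipped
scenarios use 25% and 20%). Correlated sampling is not implemented — the two
trial arms are sampled *independently* from the same specification with
decorrelated sub-seeds, which operationalises the worst-case assumption that
inter-occasion variability equals inter-individual variability and is
exactly why the parallel design is the conservative choice here.

## NCA conventions

`compute_endpoints()` uses the linear trapezoid to the last positive sample
(simulated profiles are dense, so the linear/log-down difference is
negligible; a `log-down` flag exists), and picks the terminal window for
$\lambda_z$ by best adjusted $R^2$ over candidate windows of the last
$k \ge 3$ positive points excluding tmax, ties broken toward more points.
$AUC_{0-\infty} = AUC_{0-t} + C_\mathrm{last}/\lambda_z$; profiles with no
identifiable negative terminal slope return `NA` and are counted as missing
by the trial engine (a study is invalidated when more than 10% of an arm is
missing an endpoint).

## BE statistics and decision

For each endpoint the engine computes the mean difference of log endpoints
(test − reference) and its two-sample CI — Welch by default, since nothing
forces the two arms' variances to be equal in a parallel design; a
pooled-variance option exists. Exponentiating gives the GMR and its 90% CI
in percent. The decision is boundary-*inclusive*: a CI of exactly
[80.00, 125.00]% passes, matching the regulatory phrasing "falls within
80.00–125.00%". The CI decision is exactly dual to two one-sided tests
(TOST) at $\alpha = 0.05$ with the same standard error and degrees of
freedom, and the engine reports the TOST p-value alongside the CI so the
duality is checkable on every run. Degenerate zero-variance arms (useful for
deterministic sign checks) yield a point CI at the GMR.

## Study power

Trial sizing uses a central-limit-theorem calculation on the *raw* endpoint
scale: endpoint values in the two populations are taken as
$N(\mu_1, \sigma_1^2)$ and $N(\mu_2, \sigma_2^2)$, the two-sided critical
region is built from Population 1's sampling distribution at
$\alpha = 0.05$, and the power is the probability that Population 2's sample
mean lands in it. When the populations coincide the power is $\alpha$
exactly. This is a *difference-detection* power, not a TOST equivalence
power — it answers "how many subjects until a real formulation difference is
visible", which is the planning question for choosing a safe-space sample
size. PK endpoints are usually closer to log-normal, so a `log_scale`
option applies the same machinery to log summaries; the raw scale is the
default because the normality assumption is stated in those terms. One-sided
critical regions are available via `sided = 1`. `power_curve()` sweeps n
from 8 to 200 per population and reports the smallest n reaching a target
power (default 0.8).

## The synthetic-data generator

Real dissolution data for this kind of study live in figures, not tables, so
the package generates its own: Weibull curves evaluated on the 9-point USP
grid plus additive Gaussian replicate noise (default SD 1.5 percentage
points, truncated at 0 and capped at 105%), 7 replicate vessels for the
reference and 3 per test formulation. The shipped formulation triple —
reference (Fmax 95%, lag 0.5 h, α 9 h, β 1.10), a "similar" test (94%,
0.5 h, 9.8 h, 1.05) and a "faster" test (95%, 0.25 h, 3 h, 1.30) — is
labelled synthetic throughout and was chosen once so that the similar pair
is f2-similar and bioequivalent while the faster pair fails Cmax with
matching AUC, the canonical pattern for a release-rate change at constant
extent.

What the generator does *not* emulate: inter-batch/equipment variability,
non-Gaussian assay error, pH-dependent release, or any correlation between
release and disposition parameters. Passing tests on synthetic data
therefore demonstrate the *machinery* (estimators, solver, statistics), not
the fidelity of any particular compound file.

## Scenario bundles and the pipeline

`generate_scenario_bundle()` writes self-contained directories (dissolution
CSV + compound JSON + trial JSON + manifest) for four presets: `be-pass`,
`be-fail-cmax`, `ddi-demo` and `power-sweep`. `run_pipeline()` executes a
bundle end to end — fit, f2 gate (a failing f2 for an expected-similar pair
warns but does not stop the run, since f2 is a screening aid, not a decision
rule), population sampling, per-subject simulation, NCA, BE statistics,
optional power sweep and DDI ratio — and writes `summary.json`,
`endpoints.csv` and a `run_manifest.json` recording the master seed and
every derived stage seed, so any run can be reproduced exactly.

```{r, eval = FALSE}
dir <- tempfile("vbe-")
cfg <- generate_scenario_bundle("be-pass", dir, seed = 42)
res <- run_pipeline(cfg)
res
```

## Problem sizes and numerical choices

The shipped trial scenarios use 125 subjects per arm on a 0–96 h grid at 4
points/h for a single 2 mg dose — the size at which a parallel design
reaches ~80% power for AUC endpoints under the shipped variability, and
small enough that a full study simulates in seconds and the 10-study
replicate diagnostic in about a minute on one core. Solver tolerances
(1e-8/1e-10), the bolus threshold ($\alpha < 10^{-8}$ h), fit bounds
($F_\mathrm{max} \le 110$%, $\beta \in [0.05, 10]$, lag within the sampling
window) and the terminal-window rule are all stated above and fixed; none
are exposed as tuning knobs in the scenarios.

## Known limitations

* The PK core is a reduced surrogate: no mechanistic gut segments, no
  tissue partitioning, no enzyme ontogeny or transporters, no nonlinear
  elimination, no demographic covariates. The module boundary
  (`compound_params` → `simulate_subject`) is the seam where a richer model
  would plug in.
* Parameter correlations in the population are not modelled; each parameter
  varies independently.
* The inhibitor is a constant unbound concentration (steady-state
  approximation), not a simulated time course.
* Crossover and replicate BE designs are out of scope; the engine is
  parallel-only by design.
* Short lag times are weakly identifiable from standard sampling grids (see
  above).
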