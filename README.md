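# vbesim

Virtual bioequivalence (VBE) trial simulation for modified-release oral
formulations, in R.

When an oral product is reformulated — a new strength, new equipment, or an
individually manufactured (e.g. 3D printed) batch — demonstrating
bioequivalence normally requires a clinical study: the 90% confidence
interval of the test/reference geometric mean ratio (GMR) for Cmax,
AUC<sub>0–t</sub> and AUC<sub>0–∞</sub> must fall within 80–125%. `vbesim`
runs that study *in silico* for the cleanest tractable case, a BCS class 1
compound whose absorption is controlled purely by formulation release:

* **Dissolution** — the f2 similarity factor,
  `f2 = 50·log10(100·[1 + (1/n)·Σ(Rt−Tt)²]^(−1/2))`, with the 50–100
  similarity band, and Weibull release-model fitting
  (`Fdiss = Fmax·(1 − exp(−((t−lag)/α)^β))`) by bounded multi-start least
  squares — `compute_f2()`, `fit_weibull()`.
* **PK simulation** — a reduced mechanistic oral model: Weibull release per
  dose → dissolved gut compartment → first-order absorption → one-compartment
  disposition with well-stirred hepatic clearance
  `CLh = Q·fu·CLint/(Q + fu·CLint)` plus renal clearance; multi-dose
  regimens, weekly titration schedules, and static competitive CYP1A2/3A4
  inhibition — `simulate_subject()`, `effective_clint()`,
  `steady_state_auc_ratio()`.
* **Virtual populations** — seeded, median-preserving log-normal
  inter-individual variability per parameter — `sample_population()`.
* **NCA** — Cmax, tmax, trapezoidal AUC, adjusted-R²-selected terminal
  slope λz — `compute_endpoints()`.
* **BE trials** — parallel design with independent arms, Welch CI on log
  endpoints, boundary-inclusive 80–125% decision, TOST duality, replicate
  study diagnostics — `run_vbe()`, `be_decision()`.
* **Study power** — a central-limit-theorem calculation: the critical region
  from Population 1's sampling distribution at α = 0.05, power as the
  probability Population 2's sample mean lands in it; swept over n = 8–200 —
  `study_power()`, `power_curve()`.
* **Synthetic data** — seeded replicate dissolution sets on the 9-point USP
  grid (1–24 h) and runnable end-to-end scenario bundles — 
  `generate_dissolution()`, `generate_scenario_bundle()`, `run_pipeline()`.

## Worked example

Generate a synthetic replicate dissolution data set (7 reference vessels, 3
test vessels, additive noise), fit the release model, and screen similarity:

```r
library(vbesim)
gen <- generate_dissolution(scenario_spec(seed = 7))
fit_weibull(gen$profiles$REF)
#> Weibull release fit for 'REF' (9 points, RSS = 2.069)
#>        estimate std.error
#> fmax  94.761900   1.52400
#> lag    0.365094   0.13050
#> alpha  9.050680   0.24130
#> beta   1.116740   0.04792
compute_f2(gen$profiles$REF, gen$profiles$SIM)
#> f2 = 73.97 over 9 time points: SIMILAR (similarity band 50-100)
```

The fitted plateau (≈94.8% released), time scale (≈9.1 h to 63.2% of the
plateau) and shape near 1 describe a smooth 24-h release; f2 ≈ 74 declares
the test candidate similar to the reference, so it proceeds to the virtual
trial. Run a whole scenario end to end — 125 virtual subjects per arm,
single 2 mg dose, release CV 10%, clearance/volume CVs 25%/20%:

```r
dir <- tempfile("vbe-")
res <- run_pipeline(generate_scenario_bundle("be-pass", dir, seed = 42))
res
#> Virtual bioequivalence pipeline run
#>   f2 = 74.15 (similar)
#> Parallel virtual BE study: 125 subjects/arm, 90% CI vs [80, 125]%
#>   endpoint   gmr ci_lower ci_upper passes   tost_p
#>       cmax 93.23    89.99    96.59   TRUE 5.03e-12
#>    auc_0_t 97.00    94.14    99.95   TRUE 3.21e-22
#>  auc_0_inf 97.04    94.17   100.00   TRUE 3.25e-22
#> Overall bioequivalence: PASS
```

Each row is one endpoint's GMR with its 90% CI in percent; the study passes
because every CI sits inside 80–125%. The `be-fail-cmax` preset shows the
opposite canonical pattern — a faster-releasing test formulation whose AUC
matches (extent unchanged) but whose Cmax CI lands far above 125%, failing
bioequivalence on rate. `run_manifest.json` in the output directory records
the master seed and every derived stage seed, so any run reproduces exactly.

## Scope

The PK core is intentionally a reduced surrogate (no multi-segment gut, no
tissue partitioning, no IVIVE, no demographic covariate models), the
population is uncorrelated log-normal, and only the parallel BE design is
implemented. See the methods vignette
(`vignettes/virtual-bioequivalence.Rmd`) for the model assumptions,
numerical choices, identifiability caveats and limitations.
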