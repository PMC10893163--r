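#' Default synthetic formulations and compound
#'
#' The package ships a fully synthetic stand-in study: three 24-h
#' modified-release formulations described by Weibull parameters (a
#' reference-like product, a "similar" test expected to pass both the f2
#' gate and bioequivalence, and a "faster" test releasing on a much shorter
#' time scale, expected to fail bioequivalence on Cmax while matching on
#' AUC), plus a synthetic BCS-class-1, CYP1A2/3A4-cleared compound. None of
#' the values claim to reproduce any marketed product; they are chosen to be
#' realistic for a prolonged-release dopamine-agonist-like drug (volume of
#' distribution ~7 L/kg, half-life ~6 h, predominantly hepatic clearance).
#'
#' @return `synthetic_formulations()`: named list of [weibull_params()]
#'   (`REF`, `SIM`, `FAST`); `synthetic_compound()`: a [compound_params()];
#'   `synthetic_inhibitor()`: a ciprofloxacin-like [inhibitor_spec()] with
#'   Ki 2 uM (CYP1A2) and 1.5 uM (CYP3A4), incubation unbound fractions
#'   0.92 and 1.
#' @export
synthetic_formulations <- function() {
  list(REF = weibull_params(fmax = 95, lag = 0.5, alpha = 9, beta = 1.10),
       SIM = weibull_params(fmax = 94, lag = 0.5, alpha = 9.8, beta = 1.05),
       FAST = weibull_params(fmax = 95, lag = 0.25, alpha = 3.0, beta = 1.30))
}

#' @rdname synthetic_formulations
#' @export
synthetic_compound <- function() {
  compound_params(volume_of_distribution = 500, ka = 2, fraction_absorbed = 1,
                  fu_plasma = 0.9, hepatic_blood_flow = 90, clint_total = 100,
                  fm_cyp1a2 = 0.6, fm_cyp3a4 = 0.3, renal_cl = 5,
                  molecular_weight = 260.38)
}

#' @rdname synthetic_formulations
#' @param unbound_concentration Constant unbound inhibitor concentration,
#'   uM.
#' @export
synthetic_inhibitor <- function(unbound_concentration = 6) {
  inhibitor_spec(ki_cyp1a2 = 2, ki_cyp3a4 = 1.5,
                 fu_inc_cyp1a2 = 0.92, fu_inc_cyp3a4 = 1,
                 unbound_concentration = unbound_concentration)
}

#' Synthetic dissolution scenario specification
#'
#' Defines how replicate in vitro dissolution data are emulated: Weibull
#' curves per formulation evaluated on the 9-point USP sampling grid for
#' 24-h modified-release tablets (1, 2, 4, 6, 8, 12, 16, 20, 24 h) with
#' additive Gaussian replicate noise, truncated at 0 and capped at 105%.
#' Replicate counts default to 7 for the reference and 3 for test
#' formulations, the usual asymmetric vessel allocation when a reference
#' product is characterised more thoroughly. The default noise SD of 1.5%
#' reflects the low in vitro variability typical of small same-printer
#' batches.
#'
#' @param formulations Named list of [weibull_params()] (default
#'   [synthetic_formulations()]); the first entry is treated as the
#'   reference.
#' @param replicate_count Named vector: replicates for the `reference` and
#'   each `test` formulation.
#' @param noise_sd Additive noise SD in percentage points, >= 0.
#' @param time_grid Sampling times, h.
#' @param seed Integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(formulations = synthetic_formulations(),
                          replicate_count = c(reference = 7L, test = 3L),
                          noise_sd = 1.5,
                          time_grid = c(1, 2, 4, 6, 8, 12, 16, 20, 24),
                          seed = 1L) {
  stopifnot(length(formulations) >= 1L, !is.null(names(formulations)),
            noise_sd >= 0, all(time_grid > 0))
  lapply(formulations, function(f) stopifnot(inherits(f, "weibull_params")))
  structure(list(formulations = formulations,
                 replicate_count = replicate_count, noise_sd = noise_sd,
                 time_grid = as.numeric(time_grid), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate synthetic replicate dissolution profiles
#'
#' Evaluates each formulation's Weibull curve on the scenario time grid and
#' adds independent Gaussian noise per replicate measurement (truncated at 0
#' and capped at 105%). Fully deterministic given the scenario seed; the
#' generating parameters are returned as ground truth for recovery tests.
#'
#' @param spec A [scenario_spec()].
#' @return List with `profiles` (named list of [dissolution_profile()]) and
#'   `ground_truth` (the named list of generating [weibull_params()]).
#' @export
generate_dissolution <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  ref_name <- names(spec$formulations)[1L]
  profiles <- list()
  for (nm in names(spec$formulations)) {
    n_rep <- if (nm == ref_name) spec$replicate_count[["reference"]]
             else spec$replicate_count[["test"]]
    curve <- weibull_fraction(spec$formulations[[nm]], spec$time_grid)
    mat <- vapply(seq_len(n_rep), function(i) {
      y <- curve + stats::rnorm(length(curve), 0, spec$noise_sd)
      pmin(pmax(y, 0), 105)
    }, numeric(length(curve)))
    profiles[[nm]] <- dissolution_profile(nm, spec$time_grid, mat)
  }
  list(profiles = profiles, ground_truth = spec$formulations)
}

#' Write a self-contained runnable scenario bundle
#'
#' Emits a directory holding everything [run_pipeline()] needs: the
#' replicate dissolution CSV, the compound JSON, the trial configuration
#' JSON, and a manifest documenting the expected qualitative outcome.
#' Presets:
#' \describe{
#'   \item{be-pass}{similar test vs reference; expected to pass BE on all
#'     endpoints.}
#'   \item{be-fail-cmax}{fast-releasing test vs reference; expected to fail
#'     on Cmax and pass on both AUC endpoints.}
#'   \item{ddi-demo}{reference formulation co-administered with the
#'     ciprofloxacin-like competitive CYP inhibitor; reports the
#'     steady-state AUC ratio.}
#'   \item{power-sweep}{similar test vs reference plus a power-versus-n
#'     sweep from 8 to 200 subjects at target power 0.8.}
#' }
#'
#' @param name Preset name.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the bundle.
#' @return The path to the trial configuration JSON, invisibly.
#' @export
generate_scenario_bundle <- function(name = c("be-pass", "be-fail-cmax",
                                              "ddi-demo", "power-sweep"),
                                     out_dir, seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop(sprintf("unknown preset '%s'", name[1]),
                          call. = FALSE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  forms <- synthetic_formulations()
  test_name <- switch(name, "be-fail-cmax" = "FAST", "SIM")
  spec <- scenario_spec(formulations = forms[c("REF", test_name)],
                        seed = sub_seed(seed, 1))
  gen <- generate_dissolution(spec)
  diss_path <- file.path(out_dir, "dissolution.csv")
  write_dissolution_csv(gen$profiles, diss_path)

  comp <- synthetic_compound()
  comp_path <- file.path(out_dir, "compound.json")
  writeLines(jsonlite::toJSON(unclass(comp), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), comp_path)

  config <- list(
    scenario = name,
    seed = seed,
    dissolution_csv = "dissolution.csv",
    compound_json = "compound.json",
    reference_formulation = "REF",
    test_formulation = test_name,
    expected_similar = !identical(name, "be-fail-cmax"),
    population = list(parameter_cvs = list(clint_total = 0.25,
                                           volume_of_distribution = 0.20),
                      release_cv = 0.10),
    design = list(n_per_arm = 125, ci_level = 90, be_limits = c(80, 125),
                  n_replicate_studies = 1),
    regimen = list(type = "single", dose = 2),
    inhibitor = if (name == "ddi-demo")
      unclass(synthetic_inhibitor()) else NULL,
    power = if (name == "power-sweep")
      list(n_min = 8, n_max = 200, target = 0.8) else NULL,
    expected = switch(name,
      "be-pass" = list(overall_be = TRUE),
      "be-fail-cmax" = list(overall_be = FALSE, cmax_passes = FALSE,
                            auc_passes = TRUE),
      "ddi-demo" = list(auc_ratio_above_1 = TRUE),
      "power-sweep" = list(overall_be = TRUE))
  )
  cfg_path <- file.path(out_dir, "trial.json")
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), cfg_path)

  manifest <- list(preset = name, seed = seed,
                   files = c("dissolution.csv", "compound.json", "trial.json"),
                   ground_truth = lapply(gen$ground_truth, unclass),
                   expected = config$expected)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), file.path(out_dir, "manifest.json"))
  invisible(cfg_path)
}
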