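#' Parallel virtual bioequivalence trial design
#'
#' @param n_per_arm Subjects per arm (>= 3).
#' @param endpoints Endpoints tested, a subset of `cmax`, `auc_0_t`,
#'   `auc_0_inf`.
#' @param ci_level Confidence level in percent (default 90).
#' @param be_limits Bioequivalence limits in percent (default 80-125,
#'   boundary inclusive).
#' @param n_replicate_studies Number of replicate virtual studies (1 for a
#'   decision run; 10 is the conventional diagnostic set).
#' @param seed Master seed; each replicate study and arm receives a derived
#'   [sub_seed()].
#' @param ci_method `"welch"` (default, unequal variances) or `"pooled"`.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 125,
                         endpoints = c("cmax", "auc_0_t", "auc_0_inf"),
                         ci_level = 90, be_limits = c(80, 125),
                         n_replicate_studies = 1L, seed = 1L,
                         ci_method = c("welch", "pooled")) {
  stopifnot(n_per_arm >= 3, ci_level > 0, ci_level < 100,
            length(be_limits) == 2, be_limits[1] > 0,
            be_limits[1] < 100, be_limits[2] > 100,
            n_replicate_studies >= 1)
  endpoints <- match.arg(endpoints, c("cmax", "auc_0_t", "auc_0_inf"),
                         several.ok = TRUE)
  structure(list(design = "parallel", n_per_arm = as.integer(n_per_arm),
                 endpoints = endpoints, ci_level = ci_level,
                 be_limits = be_limits,
                 n_replicate_studies = as.integer(n_replicate_studies),
                 seed = as.integer(seed), ci_method = match.arg(ci_method)),
            class = "trial_design")
}

#' Bioequivalence decision for a confidence interval
#'
#' @param ci_lower,ci_upper 90% CI bounds of the geometric mean ratio, in
#'   percent.
#' @param limits BE limits in percent; the decision is boundary-inclusive
#'   (a CI of exactly \[80, 125\] passes).
#' @return TRUE when the interval lies within the limits.
#' @export
be_decision <- function(ci_lower, ci_upper, limits = c(80, 125)) {
  stopifnot(is.finite(ci_lower), is.finite(ci_upper), ci_lower <= ci_upper)
  ci_lower >= limits[1] && ci_upper <= limits[2]
}

# Two-sample CI for the log GMR (test - reference on the log scale).
# Welch by default; returns the point estimate, CI, se, df and the two
# one-sided test p-values for the TOST duality check.
log_gmr_ci <- function(log_test, log_ref, level = 0.90,
                       method = c("welch", "pooled"),
                       log_limits = log(c(0.80, 1.25))) {
  method <- match.arg(method)
  n1 <- length(log_test); n2 <- length(log_ref)
  m <- mean(log_test) - mean(log_ref)
  v1 <- stats::var(log_test); v2 <- stats::var(log_ref)
  if (method == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else Inf
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    ci <- c(m, m)
    p_lower <- as.numeric(m <= log_limits[1])  # degenerate arms
    p_upper <- as.numeric(m >= log_limits[2])
  } else {
    tq <- stats::qt(1 - (1 - level) / 2, df)
    ci <- m + c(-1, 1) * tq * se
    p_lower <- stats::pt((m - log_limits[1]) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((m - log_limits[2]) / se, df)
  }
  list(estimate = m, ci = ci, se = se, df = df,
       tost_p = max(p_lower, p_upper))
}

#' Run a parallel-design virtual bioequivalence trial
#'
#' Samples two independent virtual populations (one per arm), simulates each
#' subject under a single-dose (or supplied) regimen with the arm's
#' formulation, computes NCA endpoints, and decides bioequivalence per
#' endpoint: the two-sample confidence interval of the mean log endpoint
#' difference (test - reference) is exponentiated into a geometric mean
#' ratio with its CI in percent, and the study passes an endpoint when the
#' CI falls inside the BE limits (inclusive). Independent arms operationalise
#' the worst case in which inter-occasion variability equals
#' inter-individual variability. A study is flagged invalid when an endpoint
#' is missing for more than 10% of an arm.
#'
#' @param test_release,ref_release [weibull_params()] for the test and
#'   reference formulations.
#' @param compound A [compound_params()] shared by both arms.
#' @param pop_spec A [population_spec()]; `n` is overridden by the design's
#'   `n_per_arm`.
#' @param design A [trial_design()].
#' @param regimen A [dosing_regimen()] (default a single 2 mg dose).
#' @param grid Simulation grid passed to [simulate_subject()] (default 0-96
#'   h at 4 points/h).
#' @return For `n_replicate_studies = 1` an object of class `vbe_trial`;
#'   otherwise a `vbe_trial_set` (list of `vbe_trial`). Each trial carries a
#'   per-endpoint table (`$results`: endpoint, gmr, ci_lower, ci_upper,
#'   passes), `$overall_be`, the subject-level endpoint table
#'   (`$endpoints`), seeds, and validity flags.
#' @export
run_vbe <- function(test_release, ref_release, compound, pop_spec, design,
                    regimen = regimen_single(2), grid = seq(0, 96, by = 0.25)) {
  stopifnot(inherits(design, "trial_design"),
            inherits(pop_spec, "population_spec"))
  studies <- lapply(seq_len(design$n_replicate_studies), function(rep_i) {
    seed_test <- sub_seed(design$seed, rep_i, 1)
    seed_ref <- sub_seed(design$seed, rep_i, 2)
    spec <- pop_spec; spec$n <- design$n_per_arm
    arm <- function(release, seed, label) {
      subjects <- sample_population(spec, compound, release, seed = seed)
      profiles <- lapply(subjects, function(s)
        simulate_subject(s$compound, s$release, regimen, grid = grid))
      endpoint_table(profiles, subject_ids = vapply(subjects, `[[`,
                                                    integer(1), "subject_id"),
                     formulation = label)
    }
    et <- arm(test_release, seed_test, "test")
    er <- arm(ref_release, seed_ref, "reference")
    res <- summarise_be(et, er, design)
    res$seeds <- c(test = seed_test, reference = seed_ref)
    res$replicate <- rep_i
    res
  })
  if (design$n_replicate_studies == 1L) return(studies[[1L]])
  structure(studies, class = "vbe_trial_set", design = design)
}

# BE statistics for one study given the two endpoint tables.
summarise_be <- function(endpoints_test, endpoints_ref, design) {
  rows <- list(); valid <- TRUE
  for (ep in design$endpoints) {
    xt <- endpoints_test[[ep]]; xr <- endpoints_ref[[ep]]
    miss_t <- mean(!is.finite(xt) | xt <= 0)
    miss_r <- mean(!is.finite(xr) | xr <= 0)
    if (miss_t > 0.10 || miss_r > 0.10) valid <- FALSE
    xt <- xt[is.finite(xt) & xt > 0]; xr <- xr[is.finite(xr) & xr > 0]
    st <- log_gmr_ci(log(xt), log(xr), level = design$ci_level / 100,
                     method = design$ci_method,
                     log_limits = log(design$be_limits / 100))
    gmr <- 100 * exp(st$estimate)
    lo <- 100 * exp(st$ci[1]); hi <- 100 * exp(st$ci[2])
    rows[[ep]] <- data.frame(endpoint = ep, gmr = gmr, ci_lower = lo,
                             ci_upper = hi,
                             passes = be_decision(lo, hi, design$be_limits),
                             tost_p = st$tost_p)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 overall_be = valid && all(results$passes),
                 valid = valid,
                 endpoints = rbind(endpoints_test, endpoints_ref),
                 design = design),
            class = "vbe_trial")
}

#' @export
print.vbe_trial <- function(x, ...) {
  d <- x$design
  cat(sprintf("Parallel virtual BE study: %d subjects/arm, %g%% CI vs [%g, %g]%%\n",
              d$n_per_arm, d$ci_level, d$be_limits[1], d$be_limits[2]))
  r <- x$results
  r$gmr <- round(r$gmr, 2); r$ci_lower <- round(r$ci_lower, 2)
  r$ci_upper <- round(r$ci_upper, 2); r$tost_p <- signif(r$tost_p, 3)
  print(r, row.names = FALSE)
  if (!x$valid) cat("STUDY INVALID: >10% of an arm missing an endpoint\n")
  cat(sprintf("Overall bioequivalence: %s\n",
              if (x$overall_be) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.vbe_trial_set <- function(x, ...) {
  cat(sprintf("Replicate virtual BE studies: %d studies\n", length(x)))
  pass <- vapply(x, `[[`, logical(1), "overall_be")
  cat(sprintf("  concluding BE on all endpoints: %d / %d\n",
              sum(pass), length(x)))
  for (i in seq_along(x)) {
    r <- x[[i]]$results
    cat(sprintf("  study %2d: %s | %s\n", i,
                if (x[[i]]$overall_be) "PASS" else "FAIL",
                paste(sprintf("%s %.1f [%.1f, %.1f]", r$endpoint, r$gmr,
                              r$ci_lower, r$ci_upper), collapse = " | ")))
  }
  invisible(x)
}

#' Forest-plot-ready summary table
#'
#' @param trial A `vbe_trial` or `vbe_trial_set`.
#' @return data.frame (study, endpoint, gmr, ci_lower, ci_upper, passes).
#' @export
be_summary_table <- function(trial) {
  if (inherits(trial, "vbe_trial")) trial <- list(trial)
  do.call(rbind, lapply(seq_along(trial), function(i)
    cbind(study = i, trial[[i]]$results[
      c("endpoint", "gmr", "ci_lower", "ci_upper", "passes")])))
}

#' @export
plot.vbe_trial_set <- function(x, ...) {
  tab <- be_summary_table(x)
  eps <- unique(tab$endpoint)
  graphics::par(mfrow = c(1, length(eps)))
  for (ep in eps) {
    d <- tab[tab$endpoint == ep, ]
    graphics::plot(d$gmr, seq_len(nrow(d)), xlim = c(60, 150), pch = 16,
                   xlab = "GMR (%)", ylab = "Study", main = ep)
    graphics::segments(d$ci_lower, seq_len(nrow(d)), d$ci_upper,
                       seq_len(nrow(d)))
    graphics::abline(v = c(80, 100, 125), lty = c(2, 3, 2),
                     col = c("red", "grey50", "red"))
  }
  invisible(x)
}
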