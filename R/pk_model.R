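#' Compound disposition parameters for the reduced oral PK model
#'
#' The simulator uses a deliberately reduced structure for a BCS class 1
#' compound: formulation release (Weibull) feeding a dissolved gut
#' compartment, first-order absorption, and one-compartment central
#' disposition cleared by a well-stirred liver,
#' \deqn{CL_h = \frac{Q\, f_u\, CL_{int,eff}}{Q + f_u\, CL_{int,eff}},}
#' plus renal clearance. Hepatic intrinsic clearance is split across CYP1A2,
#' CYP3A4 and a residual pathway via `fm_cyp1a2`/`fm_cyp3a4`, which is what a
#' competitive inhibitor acts on (see [effective_clint()]).
#'
#' @param volume_of_distribution Central volume, L.
#' @param ka First-order absorption rate constant, 1/h. The default of 2/h is
#'   fast relative to a 24-h release so that release remains rate-limiting.
#' @param fraction_absorbed Fraction of dissolved drug absorbed, in (0, 1].
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param hepatic_blood_flow Liver blood flow Q, L/h.
#' @param clint_total Total unbound intrinsic clearance, L/h.
#' @param fm_cyp1a2,fm_cyp3a4 Fractions of intrinsic clearance carried by
#'   CYP1A2 and CYP3A4; their sum must not exceed 1.
#' @param renal_cl Renal clearance, L/h, >= 0.
#' @param molecular_weight g/mol; used only to convert mass concentrations to
#'   molar units for inhibitor arithmetic.
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(volume_of_distribution, ka = 2,
                            fraction_absorbed = 1, fu_plasma,
                            hepatic_blood_flow = 90, clint_total,
                            fm_cyp1a2 = 0, fm_cyp3a4 = 0, renal_cl = 0,
                            molecular_weight = NA_real_) {
  v <- c(volume_of_distribution, ka, fraction_absorbed, fu_plasma,
         hepatic_blood_flow, clint_total)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("compound_params: volumes, rates, flows and clearances must be finite and > 0",
         call. = FALSE)
  if (fraction_absorbed > 1 || fu_plasma > 1)
    stop("compound_params: fraction_absorbed and fu_plasma must lie in (0, 1]",
         call. = FALSE)
  if (fm_cyp1a2 < 0 || fm_cyp3a4 < 0 || fm_cyp1a2 + fm_cyp3a4 > 1 + 1e-12)
    stop("compound_params: fm_cyp1a2 + fm_cyp3a4 must lie in [0, 1]",
         call. = FALSE)
  if (renal_cl < 0) stop("compound_params: renal_cl must be >= 0", call. = FALSE)
  structure(list(volume_of_distribution = volume_of_distribution, ka = ka,
                 fraction_absorbed = fraction_absorbed, fu_plasma = fu_plasma,
                 hepatic_blood_flow = hepatic_blood_flow,
                 clint_total = clint_total, fm_cyp1a2 = fm_cyp1a2,
                 fm_cyp3a4 = fm_cyp3a4, renal_cl = renal_cl,
                 molecular_weight = molecular_weight),
            class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat("Reduced oral PK compound parameters:\n")
  cat(sprintf("  V = %.4g L, ka = %.4g /h, Fa = %.3g, fu = %.3g\n",
              x$volume_of_distribution, x$ka, x$fraction_absorbed, x$fu_plasma))
  cat(sprintf("  Q = %.4g L/h, CLint = %.4g L/h (fm 1A2 %.2g / 3A4 %.2g / other %.2g), CLr = %.4g L/h\n",
              x$hepatic_blood_flow, x$clint_total, x$fm_cyp1a2, x$fm_cyp3a4,
              max(0, 1 - x$fm_cyp1a2 - x$fm_cyp3a4), x$renal_cl))
  cat(sprintf("  CLh (uninhibited) = %.4g L/h, CL total = %.4g L/h\n",
              hepatic_clearance(x), total_clearance(x)))
  invisible(x)
}

#' Competitive CYP inhibitor specification
#'
#' Describes a static (steady-state) competitive inhibitor of CYP1A2 and/or
#' CYP3A4 by its inhibition constants, unbound fractions in the in vitro
#' incubation (used to correct Ki to an unbound basis), and constant unbound
#' plasma concentration.
#'
#' @param ki_cyp1a2,ki_cyp3a4 Inhibition constants, uM (> 0; use `Inf` for an
#'   enzyme the inhibitor does not touch).
#' @param fu_inc_cyp1a2,fu_inc_cyp3a4 Unbound fractions in incubation media,
#'   in (0, 1].
#' @param unbound_concentration Constant unbound inhibitor concentration, uM.
#' @return An object of class `inhibitor_spec`.
#' @export
inhibitor_spec <- function(ki_cyp1a2 = Inf, ki_cyp3a4 = Inf,
                           fu_inc_cyp1a2 = 1, fu_inc_cyp3a4 = 1,
                           unbound_concentration = 0) {
  if (ki_cyp1a2 <= 0 || ki_cyp3a4 <= 0)
    stop("inhibitor_spec: Ki values must be > 0", call. = FALSE)
  if (fu_inc_cyp1a2 <= 0 || fu_inc_cyp1a2 > 1 ||
      fu_inc_cyp3a4 <= 0 || fu_inc_cyp3a4 > 1)
    stop("inhibitor_spec: fu_inc values must lie in (0, 1]", call. = FALSE)
  if (!is.finite(unbound_concentration) || unbound_concentration < 0)
    stop("inhibitor_spec: unbound_concentration must be finite and >= 0",
         call. = FALSE)
  structure(list(ki_cyp1a2 = ki_cyp1a2, ki_cyp3a4 = ki_cyp3a4,
                 fu_inc_cyp1a2 = fu_inc_cyp1a2, fu_inc_cyp3a4 = fu_inc_cyp3a4,
                 unbound_concentration = unbound_concentration),
            class = "inhibitor_spec")
}

#' Dosing regimens
#'
#' A regimen is an ordered table of (time, dose) events. Helper constructors
#' cover single doses, repeated q-h dosing (e.g. BID/TID), and week-wise
#' up-titration of a TID schedule.
#'
#' @param times Event times, h, >= 0.
#' @param doses Doses, mg, one per event (recycled if scalar).
#' @return An object of class `dosing_regimen` (a data.frame with columns
#'   `time` and `dose`).
#' @export
dosing_regimen <- function(times, doses) {
  times <- as.numeric(times); doses <- rep_len(as.numeric(doses), length(times))
  if (any(!is.finite(times)) || any(times < 0))
    stop("dosing_regimen: event times must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("dosing_regimen: doses must be finite and >= 0", call. = FALSE)
  o <- order(times)
  structure(data.frame(time = times[o], dose = doses[o]),
            class = c("dosing_regimen", "data.frame"))
}

#' @rdname dosing_regimen
#' @param dose Dose per administration, mg.
#' @param time Administration time, h.
#' @export
regimen_single <- function(dose, time = 0) dosing_regimen(time, dose)

#' @rdname dosing_regimen
#' @param interval Dosing interval, h (12 for BID, 8 for TID).
#' @param n_doses Number of administrations.
#' @param start First administration time, h.
#' @export
regimen_repeated <- function(dose, interval, n_doses, start = 0)
  dosing_regimen(start + interval * (seq_len(n_doses) - 1L), dose)

#' @rdname dosing_regimen
#' @param step_doses Per-administration doses for successive titration steps,
#'   mg (default 0.5, 1, 1.5, 2 mg TID, the conventional ropinirole-style
#'   weekly up-titration).
#' @param days_per_step Days each titration step lasts.
#' @param times_per_day Administrations per day (TID = 3, evenly spaced).
#' @param extra_days Days to continue at the final dose after the last step.
#' @export
regimen_titration <- function(step_doses = c(0.5, 1, 1.5, 2),
                              days_per_step = 7, times_per_day = 3,
                              extra_days = 0) {
  interval <- 24 / times_per_day
  times <- numeric(0); doses <- numeric(0)
  t0 <- 0
  for (d in step_doses) {
    n <- days_per_step * times_per_day
    times <- c(times, t0 + interval * (seq_len(n) - 1L))
    doses <- c(doses, rep(d, n))
    t0 <- t0 + days_per_step * 24
  }
  if (extra_days > 0) {
    n <- extra_days * times_per_day
    times <- c(times, t0 + interval * (seq_len(n) - 1L))
    doses <- c(doses, rep(step_doses[length(step_doses)], n))
  }
  dosing_regimen(times, doses)
}

#' Well-stirred hepatic clearance and total clearance
#'
#' @param compound A [compound_params()].
#' @param inhibitor Optional [inhibitor_spec()]; when given, the intrinsic
#'   clearance is first reduced by [effective_clint()].
#' @return Clearance in L/h.
#' @export
hepatic_clearance <- function(compound, inhibitor = NULL) {
  clint <- if (is.null(inhibitor)) compound$clint_total
           else effective_clint(compound, inhibitor)
  q <- compound$hepatic_blood_flow; fu <- compound$fu_plasma
  q * fu * clint / (q + fu * clint)
}

#' @rdname hepatic_clearance
#' @export
total_clearance <- function(compound, inhibitor = NULL)
  hepatic_clearance(compound, inhibitor) + compound$renal_cl

#' Intrinsic clearance under static competitive CYP inhibition
#'
#' Applies the standard static drug-drug interaction model: each inhibited
#' pathway's intrinsic clearance is divided by \eqn{1 + I_u/(K_i f_{u,inc})}
#' while the residual pathway is untouched,
#' \deqn{CL_{int,eff} = CL_{int}\Bigl[\frac{fm_{1A2}}{1 + I_u/(K_{i,1A2} f_{u,inc,1A2})}
#'  + \frac{fm_{3A4}}{1 + I_u/(K_{i,3A4} f_{u,inc,3A4})} + (1 - fm_{1A2} - fm_{3A4})\Bigr].}
#'
#' @param compound A [compound_params()].
#' @param inhibitor An [inhibitor_spec()].
#' @return Effective intrinsic clearance, L/h.
#' @export
effective_clint <- function(compound, inhibitor) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(inhibitor, "inhibitor_spec"))
  iu <- inhibitor$unbound_concentration
  r1 <- iu / (inhibitor$ki_cyp1a2 * inhibitor$fu_inc_cyp1a2)
  r2 <- iu / (inhibitor$ki_cyp3a4 * inhibitor$fu_inc_cyp3a4)
  fm1 <- compound$fm_cyp1a2; fm2 <- compound$fm_cyp3a4
  compound$clint_total * (fm1 / (1 + r1) + fm2 / (1 + r2) + (1 - fm1 - fm2))
}

#' Convert a mass concentration to molar units
#'
#' @param conc_ng_ml Concentration in ng/mL.
#' @param molecular_weight g/mol.
#' @return Concentration in uM.
#' @export
ngml_to_uM <- function(conc_ng_ml, molecular_weight) {
  stopifnot(is.finite(molecular_weight), molecular_weight > 0)
  conc_ng_ml / molecular_weight  # ng/mL == ug/L; ug/L / (g/mol) = umol/L
}

#' Simulate one subject's plasma concentration-time profile
#'
#' Integrates the reduced oral PK system for an arbitrary dosing regimen.
#' Each dose contributes an undissolved depot releasing into the dissolved
#' gut compartment at the time-derivative of the Weibull cumulative-release
#' curve (superposed over dose events); dissolved drug is absorbed at rate
#' `ka`, a fraction `fraction_absorbed` reaching the central compartment,
#' which is cleared by the well-stirred liver plus renal clearance. With
#' `release = NULL` (or a Weibull scale below 1e-8 h) release is treated as
#' instantaneous and each dose enters the gut compartment as a bolus — the
#' limit in which the profile is the classical Bateman double exponential.
#'
#' @param compound A [compound_params()].
#' @param release A [weibull_params()] describing the formulation, or NULL
#'   for instantaneous release.
#' @param regimen A [dosing_regimen()].
#' @param grid Output time grid, h. Default: 4 points/h from 0 to 72 h past
#'   the last dose.
#' @param inhibitor Optional [inhibitor_spec()] (constant unbound
#'   concentration, steady-state approximation).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `concentration_profile`: a data.frame with
#'   columns `time` (h) and `conc` (ng/mL), with the dose events, clearances
#'   and amounts carried as attributes.
#' @export
simulate_subject <- function(compound, release, regimen,
                             grid = NULL, inhibitor = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(regimen, "dosing_regimen"))
  if (!is.null(release) && !inherits(release, "weibull_params"))
    stop("simulate_subject: release must be weibull_params or NULL", call. = FALSE)
  immediate <- is.null(release) || release$alpha < 1e-8
  if (is.null(grid)) {
    end <- max(regimen$time) + 72
    grid <- seq(0, end, by = 0.25)
  }
  grid <- sort(unique(c(0, grid)))
  if (max(regimen$time) > max(grid))
    stop("simulate_subject: grid must cover all dose events", call. = FALSE)

  cl <- total_clearance(compound, inhibitor)
  v <- compound$volume_of_distribution
  ka <- compound$ka
  fa <- compound$fraction_absorbed
  fmax_frac <- if (immediate) {
    if (is.null(release)) 1 else release$fmax / 100
  } else release$fmax / 100
  ke <- cl / v

  if (immediate) {
    events <- data.frame(var = "gut", time = regimen$time,
                         value = regimen$dose * fmax_frac * fa, method = "add")
    grid2 <- sort(unique(c(grid, regimen$time)))
    deriv <- function(t, y, parms) {
      list(c(gut = -ka * y[["gut"]],
             central = ka * y[["gut"]] - ke * y[["central"]]))
    }
    sol <- deSolve::lsoda(c(gut = 0, central = 0), grid2, deriv, parms = NULL,
                          rtol = rtol, atol = atol,
                          events = list(data = events))
  } else {
    rel_rate <- function(t) {
      td <- t - regimen$time
      pos <- td > 0
      if (!any(pos)) return(0)
      sum(regimen$dose[pos] * fmax_frac * weibull_release_rate(release, td[pos]))
    }
    deriv <- function(t, y, parms) {
      rin <- rel_rate(t)
      list(c(gut = rin * fa - ka * y[["gut"]],
             central = ka * y[["gut"]] - ke * y[["central"]]))
    }
    # anchor the solver at dose times (release-rate kinks)
    grid2 <- sort(unique(c(grid, regimen$time,
                           regimen$time + release$lag)))
    sol <- deSolve::lsoda(c(gut = 0, central = 0), grid2, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  sol <- as.data.frame(sol)
  keep <- sol$time %in% grid
  conc <- sol$central[keep] / v * 1000  # mg/L -> ng/mL
  neg <- conc < 0
  if (any(conc < -1e-6 * max(abs(conc), 1)))
    stop("simulate_subject: solver produced negative concentrations beyond tolerance",
         call. = FALSE)
  conc[neg] <- 0
  out <- data.frame(time = sol$time[keep], conc = conc)
  structure(out,
            class = c("concentration_profile", "data.frame"),
            regimen = regimen, clearance = cl, volume = v,
            amount_central_mg = sol$central[keep],
            amount_gut_mg = sol$gut[keep],
            release = release, inhibitor = inhibitor)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration-time profile: %d points over %g-%g h, Cmax = %.4g ng/mL\n",
              nrow(x), min(x$time), max(x$time), max(x$conc)))
  cat(sprintf("  CL = %.4g L/h, V = %.4g L, %d dose event(s)\n",
              attr(x, "clearance"), attr(x, "volume"),
              nrow(attr(x, "regimen"))))
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, log = "", ...) {
  graphics::plot(x$time, x$conc, type = "l", lwd = 2, log = log,
                 xlab = "Time (h)", ylab = "Concentration (ng/mL)", ...)
  graphics::abline(v = attr(x, "regimen")$time, col = "grey80", lty = 3)
  invisible(x)
}

#' Steady-state AUC ratio with versus without an inhibitor
#'
#' Simulates the same multiple-dose regimen to steady state with and without
#' the inhibitor and returns the ratio of dosing-interval AUCs over the last
#' interval. In the linear, flow-non-limited limit this equals
#' `clint_total / effective_clint()`.
#'
#' @param compound A [compound_params()].
#' @param inhibitor An [inhibitor_spec()].
#' @param release A [weibull_params()] or NULL (instantaneous release).
#' @param dose Dose per administration, mg.
#' @param interval Dosing interval, h.
#' @param n_doses Number of doses simulated; the default targets ~10
#'   terminal half-lives of run-in.
#' @param ss_tol Relative difference between the last two interval AUCs above
#'   which a non-steady-state warning is raised.
#' @return The AUC ratio (inhibited / uninhibited), with the two interval
#'   AUCs as attributes.
#' @export
steady_state_auc_ratio <- function(compound, inhibitor, release = NULL,
                                   dose = 1, interval = 8, n_doses = NULL,
                                   ss_tol = 0.02) {
  stopifnot(inherits(inhibitor, "inhibitor_spec"))
  if (is.null(n_doses)) {
    # slowest half-life is under inhibition
    thalf <- log(2) * compound$volume_of_distribution /
      total_clearance(compound, inhibitor)
    n_doses <- max(6L, ceiling(10 * thalf / interval) + 1L)
  }
  regimen <- regimen_repeated(dose, interval, n_doses)
  grid <- seq(0, max(regimen$time) + interval, by = min(0.25, interval / 16))
  auc_last <- function(inh) {
    prof <- simulate_subject(compound, release, regimen, grid = grid,
                             inhibitor = inh)
    t1 <- max(regimen$time); t0 <- t1 - interval
    a_last <- interval_auc(prof, t0, t1)
    a_prev <- interval_auc(prof, t0 - interval, t0)
    if (abs(a_last - a_prev) > ss_tol * a_last)
      warning("steady_state_auc_ratio: regimen not at steady state; using last-interval AUC",
              call. = FALSE)
    a_last
  }
  a_inh <- auc_last(inhibitor)
  a_base <- auc_last(NULL)
  structure(a_inh / a_base, auc_inhibited = a_inh, auc_baseline = a_base)
}

# trapezoidal AUC of a concentration profile between t0 and t1 (ng*h/mL)
interval_auc <- function(profile, t0, t1) {
  sel <- profile$time >= t0 - 1e-9 & profile$time <= t1 + 1e-9
  t <- profile$time[sel]; c <- profile$conc[sel]
  sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
}
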