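#' Noncompartmental PK endpoints
#'
#' Computes the standard noncompartmental endpoints from a concentration-time
#' profile: Cmax and tmax from the observed maximum, AUC0-t by the linear
#' trapezoidal rule up to the last positive concentration, the terminal
#' elimination rate constant lambda_z by log-linear least squares, and
#' AUC0-inf = AUC0-t + Clast / lambda_z.
#'
#' The terminal window for lambda_z is chosen automatically: among candidate
#' windows of the last k points (k >= 3, tmax excluded, positive
#' concentrations only), the one with the best adjusted R-squared wins, ties
#' broken toward more points; windows with non-negative slope are rejected.
#' When no valid window exists, `lambda_z` and `auc_0_inf` are returned as
#' `NA` and flagged. A `method = "log-down"` option applies the log
#' trapezoid on descending segments; simulated profiles are dense enough
#' that the default linear rule is standard.
#'
#' @param profile A [simulate_subject()] result, or a data.frame with
#'   columns `time` and `conc`.
#' @param method `"linear"` (default) or `"log-down"` trapezoid for AUC.
#' @param max_terminal_points Largest terminal window screened (default 12).
#' @return An object of class `pk_endpoints`: list with `cmax`, `tmax`,
#'   `auc_0_t`, `auc_0_inf`, `lambda_z`, `lambda_z_r2`,
#'   `lambda_z_n_points`.
#' @export
compute_endpoints <- function(profile, method = c("linear", "log-down"),
                              max_terminal_points = 12L) {
  method <- match.arg(method)
  t <- profile$time; c <- profile$conc
  if (length(t) < 3L)
    stop("compute_endpoints: need at least 3 samples", call. = FALSE)
  if (any(c < 0)) stop("compute_endpoints: negative concentrations", call. = FALSE)

  if (all(c == 0)) {
    warning("compute_endpoints: all-zero profile; endpoints are zero",
            call. = FALSE)
    return(structure(list(cmax = 0, tmax = t[1L], auc_0_t = 0, auc_0_inf = 0,
                          lambda_z = NA_real_, lambda_z_r2 = NA_real_,
                          lambda_z_n_points = 0L),
                     class = "pk_endpoints"))
  }

  imax <- which.max(c)
  cmax <- c[imax]; tmax <- t[imax]
  ilast <- max(which(c > 0))
  tt <- t[seq_len(ilast)]; cc <- c[seq_len(ilast)]
  auc_0_t <- if (method == "linear") {
    sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  } else {
    seg_auc <- function(t1, t2, c1, c2) {
      if (c2 < c1 && c1 > 0 && c2 > 0) (c1 - c2) * (t2 - t1) / log(c1 / c2)
      else (t2 - t1) * (c1 + c2) / 2
    }
    sum(mapply(seg_auc, head(tt, -1), tail(tt, -1), head(cc, -1), tail(cc, -1)))
  }

  # terminal slope: windows of the last k positive points after (excluding) tmax
  cand_idx <- which(seq_along(c) > imax & c > 0 & t <= t[ilast])
  lambda_z <- NA_real_; r2 <- NA_real_; npts <- 0L
  if (length(cand_idx) >= 3L) {
    best <- NULL
    for (k in 3:min(max_terminal_points, length(cand_idx))) {
      idx <- tail(cand_idx, k)
      fit <- stats::lm.fit(cbind(1, t[idx]), log(c[idx]))
      slope <- unname(fit$coefficients[2L])
      if (!is.finite(slope) || slope >= 0) next
      res <- fit$residuals
      tss <- sum((log(c[idx]) - mean(log(c[idx])))^2)
      if (tss <= 0) next
      ar2 <- 1 - (sum(res^2) / (k - 2)) / (tss / (k - 1))
      if (is.null(best) || ar2 > best$ar2 + 1e-10 ||
          (abs(ar2 - best$ar2) <= 1e-10 && k > best$k))
        best <- list(slope = slope, ar2 = ar2, k = k)
    }
    if (!is.null(best)) {
      lambda_z <- -best$slope; r2 <- best$ar2; npts <- best$k
    }
  }
  auc_0_inf <- if (is.finite(lambda_z)) auc_0_t + c[ilast] / lambda_z
               else NA_real_

  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
                 auc_0_inf = auc_0_inf, lambda_z = unname(lambda_z),
                 lambda_z_r2 = unname(r2), lambda_z_n_points = npts),
            class = "pk_endpoints")
}

#' @export
print.pk_endpoints <- function(x, ...) {
  cat(sprintf("NCA endpoints: Cmax = %.4g ng/mL at tmax = %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-t = %.5g, AUC0-inf = %.5g ng*h/mL\n", x$auc_0_t, x$auc_0_inf))
  cat(sprintf("  lambda_z = %.4g /h (adj. R2 = %.4f, %d points)\n",
              x$lambda_z, x$lambda_z_r2, x$lambda_z_n_points))
  invisible(x)
}

#' Endpoint table for a set of subjects
#'
#' @param profiles List of concentration profiles (one per subject).
#' @param subject_ids Optional ids (default sequence).
#' @param formulation Label recycled into the table.
#' @return data.frame: subject_id, formulation, cmax, tmax, auc_0_t,
#'   auc_0_inf, lambda_z.
#' @export
endpoint_table <- function(profiles, subject_ids = NULL, formulation = "test") {
  if (is.null(subject_ids)) subject_ids <- seq_along(profiles)
  do.call(rbind, Map(function(p, id) {
    e <- compute_endpoints(p)
    data.frame(subject_id = id, formulation = formulation, cmax = e$cmax,
               tmax = e$tmax, auc_0_t = e$auc_0_t, auc_0_inf = e$auc_0_inf,
               lambda_z = e$lambda_z)
  }, profiles, subject_ids))
}
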