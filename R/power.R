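#' Study power for detecting a difference between two simulated populations
#'
#' Implements the central-limit-theorem based power procedure used in
#' trial-size planning for virtual studies. Endpoint values in Population 1
#' and Population 2 are taken as normal, \eqn{x \sim N(\mu_1, \sigma_1^2)}
#' and \eqn{y \sim N(\mu_2, \sigma_2^2)}, so the sample means are
#' \eqn{\bar x \sim N(\mu_1, \sigma_1^2/n_1)} and
#' \eqn{\bar y \sim N(\mu_2, \sigma_2^2/n_2)}. A critical value is computed
#' from Population 1's sampling distribution at significance level `alpha`
#' (two-sided by default: reject when
#' \eqn{|\bar x - \mu_1| > z_{1-\alpha/2}\,\sigma_1/\sqrt{n_1}}), and the
#' power is the probability that \eqn{\bar y} falls in that rejection
#' region. When the two populations are identical and \eqn{n_1 = n_2} the
#' power equals `alpha` exactly.
#'
#' PK endpoints are often closer to log-normal; `log_scale = TRUE` applies
#' the same machinery to log-transformed summaries (the caller supplies
#' means and variances of the logs).
#'
#' @param mu1,sigma1_sq Mean and variance of the endpoint in Population 1.
#' @param mu2,sigma2_sq Mean and variance in Population 2.
#' @param n1,n2 Sample sizes (>= 2).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param sided 2 (default) for the symmetric two-sided region, 1 for the
#'   one-sided region in the direction of `mu2 - mu1`.
#' @return The power, a probability in \[0, 1\].
#' @examples
#' study_power(0, 1, 1, 1, 16, 16)  # 0.9793
#' @export
study_power <- function(mu1, sigma1_sq, mu2, sigma2_sq, n1, n2,
                        alpha = 0.05, sided = 2) {
  stopifnot(sigma1_sq > 0, sigma2_sq > 0, n1 >= 2, n2 >= 2,
            alpha > 0, alpha < 1, sided %in% c(1, 2))
  se1 <- sqrt(sigma1_sq / n1)
  se2 <- sqrt(sigma2_sq / n2)
  if (sided == 2) {
    crit <- stats::qnorm(1 - alpha / 2) * se1
    # P(ybar outside [mu1 - crit, mu1 + crit])
    1 - (stats::pnorm((mu1 + crit - mu2) / se2) -
           stats::pnorm((mu1 - crit - mu2) / se2))
  } else {
    crit <- stats::qnorm(1 - alpha) * se1
    if (mu2 >= mu1) 1 - stats::pnorm((mu1 + crit - mu2) / se2)
    else stats::pnorm((mu1 - crit - mu2) / se2)
  }
}

#' Power versus number of subjects for simulated endpoint samples
#'
#' Sweeps [study_power()] over a grid of per-population sample sizes for one
#' or more PK endpoints whose population means and variances are estimated
#' from simulated endpoint samples (one value per virtual subject). Reports
#' the smallest n reaching a target power, or marks it not reached.
#'
#' @param pop1,pop2 data.frames of per-subject endpoint values (e.g. from
#'   [endpoint_table()]), or named lists of numeric vectors. Columns/entries
#'   named in `endpoints` are used.
#' @param endpoints Endpoint names (default the three standard BE
#'   endpoints).
#' @param n Vector of per-population sample sizes (default 8 to 200).
#' @param alpha Significance level.
#' @param target Target power used for the sample-size readout.
#' @param sided,log_scale Passed to / interpreted as in [study_power()];
#'   with `log_scale = TRUE` the summaries are computed on log endpoint
#'   values.
#' @return An object of class `power_curve`: data.frame (endpoint, n,
#'   power), with per-endpoint smallest-n attribute `n_target` (NA when the
#'   target is not reached inside the grid).
#' @export
power_curve <- function(pop1, pop2,
                        endpoints = c("cmax", "auc_0_t", "auc_0_inf"),
                        n = 8:200, alpha = 0.05, target = 0.8,
                        sided = 2, log_scale = FALSE) {
  get_col <- function(pop, nm) {
    v <- if (is.data.frame(pop)) pop[[nm]] else pop[[nm]]
    if (is.null(v)) stop(sprintf("power_curve: endpoint '%s' not found", nm),
                         call. = FALSE)
    v <- v[is.finite(v)]
    if (log_scale) log(v) else v
  }
  rows <- list(); n_target <- stats::setNames(rep(NA_real_, length(endpoints)),
                                              endpoints)
  for (ep in endpoints) {
    x <- get_col(pop1, ep); y <- get_col(pop2, ep)
    pw <- vapply(n, function(k)
      study_power(mean(x), stats::var(x), mean(y), stats::var(y),
                  k, k, alpha = alpha, sided = sided), numeric(1))
    rows[[ep]] <- data.frame(endpoint = ep, n = n, power = pw)
    hit <- which(pw >= target)
    if (length(hit) > 0L) n_target[ep] <- n[hit[1L]]
  }
  structure(do.call(rbind, rows), class = c("power_curve", "data.frame"),
            target = target, n_target = n_target, alpha = alpha)
}

#' @export
print.power_curve <- function(x, ...) {
  tgt <- attr(x, "target"); nt <- attr(x, "n_target")
  cat(sprintf("Study power sweep (alpha = %g), n in [%d, %d]:\n",
              attr(x, "alpha"), min(x$n), max(x$n)))
  for (ep in names(nt)) {
    cat(sprintf("  %-10s smallest n with power >= %.2g: %s\n", ep, tgt,
                if (is.na(nt[[ep]])) "not reached" else nt[[ep]]))
  }
  invisible(x)
}

#' @export
plot.power_curve <- function(x, ...) {
  eps <- unique(x$endpoint)
  graphics::plot(NA, xlim = range(x$n), ylim = c(0, 1),
                 xlab = "Subjects per population", ylab = "Power", ...)
  for (i in seq_along(eps)) {
    d <- x[x$endpoint == eps[i], ]
    graphics::lines(d$n, d$power, col = i, lwd = 2)
  }
  graphics::abline(h = attr(x, "target"), lty = 2, col = "grey50")
  graphics::legend("bottomright", legend = eps, col = seq_along(eps), lwd = 2)
  invisible(x)
}
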