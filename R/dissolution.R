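#' Replicate-resolved dissolution profile
#'
#' Holds percent-dissolved measurements for one formulation over a shared
#' time grid, one column per replicate vessel. The standard sampling scheme
#' for 24-h modified-release tablets draws at 1, 2, 4, 6, 8, 12, 16, 20 and
#' 24 h.
#'
#' @param formulation_id Character label for the formulation.
#' @param times Strictly increasing sampling times in hours, > 0.
#' @param dissolved Numeric matrix (length(times) x n_replicates) of percent
#'   dissolved, or a vector for a single replicate. Values must be finite and
#'   within \[0, 110\].
#' @param replicate_ids Optional replicate labels (default "R1", "R2", ...).
#' @return An object of class `dissolution_profile`.
#' @seealso [read_dissolution_csv()], [compute_f2()], [fit_weibull()]
#' @export
dissolution_profile <- function(formulation_id, times, dissolved,
                                replicate_ids = NULL) {
  stopifnot(is.character(formulation_id), length(formulation_id) == 1L)
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times <= 0))
    stop("dissolution_profile: times must be finite and > 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("dissolution_profile: times must be strictly increasing", call. = FALSE)
  if (is.vector(dissolved)) dissolved <- matrix(as.numeric(dissolved), ncol = 1L)
  dissolved <- as.matrix(dissolved)
  if (nrow(dissolved) != length(times))
    stop("dissolution_profile: dissolved must have one row per time point",
         call. = FALSE)
  if (any(!is.finite(dissolved)))
    stop("dissolution_profile: dissolved values must be finite", call. = FALSE)
  if (any(dissolved < 0) || any(dissolved > 110))
    stop("dissolution_profile: dissolved values must lie in [0, 110] percent",
         call. = FALSE)
  if (is.null(replicate_ids)) replicate_ids <- paste0("R", seq_len(ncol(dissolved)))
  stopifnot(length(replicate_ids) == ncol(dissolved))
  colnames(dissolved) <- replicate_ids
  structure(list(formulation_id = formulation_id, times = times,
                 dissolved = dissolved),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("Dissolution profile '%s': %d time points (%g-%g h), %d replicate(s)\n",
              x$formulation_id, length(x$times), min(x$times), max(x$times),
              ncol(x$dissolved)))
  df <- data.frame(time_h = x$times, round(x$dissolved, 2),
                   mean = round(rowMeans(x$dissolved), 2),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dissolution_profile <- function(x, ...) {
  graphics::matplot(x$times, x$dissolved, type = "p", pch = 1, col = "grey40",
                    xlab = "Time (h)", ylab = "Dissolved (%)",
                    main = x$formulation_id, ylim = c(0, 110), ...)
  graphics::lines(x$times, rowMeans(x$dissolved), lwd = 2)
  invisible(x)
}

#' Replicate-mean dissolution curve
#'
#' @param profile A [dissolution_profile()].
#' @return Numeric vector of mean percent dissolved, named by time.
#' @export
mean_profile <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  m <- rowMeans(profile$dissolved)
  names(m) <- profile$times
  m
}

#' Read/write dissolution profiles in long CSV format
#'
#' The interchange format is a long table with header
#' `formulation_id,replicate,time_h,dissolved_pct`. All replicates of a
#' formulation must share the same time grid.
#'
#' @param path Path to a CSV file.
#' @return `read_dissolution_csv()`: a named list of
#'   [dissolution_profile()] objects, one per formulation in the file.
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("dissolution CSV not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("formulation_id", "replicate", "time_h", "dissolved_pct")
  if (!all(need %in% names(df)))
    stop(sprintf("dissolution CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  out <- lapply(split(df, df$formulation_id), function(d) {
    reps <- split(d, d$replicate)
    times <- sort(unique(d$time_h))
    mat <- vapply(reps, function(r) {
      r <- r[order(r$time_h), ]
      if (!isTRUE(all.equal(r$time_h, times)))
        stop("all replicates must share the same time grid", call. = FALSE)
      r$dissolved_pct
    }, numeric(length(times)))
    dissolution_profile(d$formulation_id[1L], times, mat,
                        replicate_ids = names(reps))
  })
  out[order(names(out))]
}

#' @rdname read_dissolution_csv
#' @param profiles A `dissolution_profile` or list of them.
#' @export
write_dissolution_csv <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(formulation_id = p$formulation_id,
               replicate = rep(colnames(p$dissolved), each = length(p$times)),
               time_h = rep(p$times, ncol(p$dissolved)),
               dissolved_pct = as.vector(p$dissolved))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' f2 dissolution-profile similarity factor
#'
#' Computes the model-independent similarity factor
#' \deqn{f_2 = 50 \log_{10}\!\Bigl(100\,\bigl[1 + \tfrac{1}{n}\sum_t (R_t - T_t)^2\bigr]^{-1/2}\Bigr)}
#' between a reference and a test dissolution curve on a shared time grid.
#' Two profiles are declared similar when \eqn{50 \le f_2 \le 100}; identical
#' curves give exactly 100 and a constant offset of \eqn{\sqrt{99}} percentage
#' points gives exactly 50.
#'
#' By default all supplied time points enter the sum and profiles are compared
#' on their replicate means. `truncate_85 = TRUE` applies the regulatory
#' convention of keeping at most one time point after both mean profiles have
#' exceeded 85% dissolved. `level = "replicate"` instead returns the f2 of
#' every reference-replicate x test-replicate pairing.
#'
#' @param reference,test [dissolution_profile()] objects or bare numeric
#'   percent series on identical grids.
#' @param truncate_85 Apply the 85%-dissolved truncation rule (default FALSE).
#' @param level `"mean"` (default) or `"replicate"`.
#' @return An object of class `f2_result` with elements `f2`,
#'   `n_points_used` and `similar` (and, for `level = "replicate"`, the matrix
#'   `f2_replicate`).
#' @examples
#' r <- c(10, 30, 50, 70, 85); t <- c(15, 35, 55, 75, 90)
#' compute_f2(r, t)  # f2 = 64.63
#' @export
compute_f2 <- function(reference, test, truncate_85 = FALSE,
                       level = c("mean", "replicate")) {
  level <- match.arg(level)
  ref_prof <- test_prof <- NULL
  extract <- function(x) {
    if (inherits(x, "dissolution_profile"))
      list(times = x$times, mean = rowMeans(x$dissolved), mat = x$dissolved)
    else if (is.numeric(x))
      list(times = NULL, mean = as.numeric(x), mat = matrix(as.numeric(x), ncol = 1L))
    else stop("compute_f2: inputs must be dissolution profiles or numeric series",
              call. = FALSE)
  }
  R <- extract(reference); T_ <- extract(test)
  if (!is.null(R$times) && !is.null(T_$times) &&
      !isTRUE(all.equal(R$times, T_$times)))
    stop("compute_f2: reference and test time grids differ", call. = FALSE)
  if (length(R$mean) != length(T_$mean))
    stop("compute_f2: reference and test time grids differ", call. = FALSE)
  keep <- seq_along(R$mean)
  if (truncate_85) {
    over <- which(R$mean >= 85 & T_$mean >= 85)
    if (length(over) > 0L) keep <- seq_len(min(over[1L] , length(keep)))
  }
  if (length(keep) < 2L)
    stop("compute_f2: at least 2 shared time points are required", call. = FALSE)

  f2_of <- function(r, t) {
    msd <- mean((r - t)^2)
    50 * log10(100 / sqrt(1 + msd))
  }
  f2 <- f2_of(R$mean[keep], T_$mean[keep])
  res <- list(f2 = f2, n_points_used = length(keep),
              similar = f2 >= 50 && f2 <= 100)
  if (level == "replicate") {
    res$f2_replicate <- outer(seq_len(ncol(R$mat)), seq_len(ncol(T_$mat)),
                              Vectorize(function(i, j)
                                f2_of(R$mat[keep, i], T_$mat[keep, j])))
    dimnames(res$f2_replicate) <- list(colnames(R$mat), colnames(T_$mat))
  }
  structure(res, class = "f2_result")
}

#' @export
print.f2_result <- function(x, ...) {
  cat(sprintf("f2 = %.2f over %d time points: %s (similarity band 50-100)\n",
              x$f2, x$n_points_used,
              if (x$similar) "SIMILAR" else "NOT similar"))
  if (!is.null(x$f2_replicate)) {
    cat("Replicate-level f2:\n")
    print(round(x$f2_replicate, 2))
  }
  invisible(x)
}
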