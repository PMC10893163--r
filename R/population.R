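#' Virtual population specification
#'
#' Describes how inter-individual variability is placed on model parameters.
#' Each named parameter is drawn independently from a log-normal distribution
#' with median equal to the base value and log-SD
#' \eqn{\sqrt{\ln(1 + CV^2)}}, which preserves the base value as the
#' population median and guarantees positivity. Recognised parameter names
#' are the Weibull release parameters (`fmax`, `lag`, `alpha`, `beta`) and
#' the compound parameters (`volume_of_distribution`, `ka`,
#' `fraction_absorbed`, `fu_plasma`, `clint_total`, `renal_cl`).
#'
#' When `parameter_cvs` is NULL the release parameters inherit the CV stored
#' on the base [weibull_params()] (default 0.10 each), and no compound
#' parameter varies.
#'
#' @param n Number of subjects, >= 1.
#' @param parameter_cvs Named numeric vector of fractional CVs, or NULL.
#' @param seed Integer seed; sampling is fully deterministic given the seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n, parameter_cvs = NULL, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1)
  if (!is.null(parameter_cvs)) {
    if (is.null(names(parameter_cvs)) || any(names(parameter_cvs) == ""))
      stop("population_spec: parameter_cvs must be a named vector", call. = FALSE)
    if (any(parameter_cvs < 0))
      stop("population_spec: CVs must be >= 0", call. = FALSE)
  }
  structure(list(n = as.integer(n), parameter_cvs = parameter_cvs,
                 distribution = "log-normal", seed = as.integer(seed)),
            class = "population_spec")
}

.release_par_names <- c("fmax", "lag", "alpha", "beta")
.compound_par_names <- c("volume_of_distribution", "ka", "fraction_absorbed",
                         "fu_plasma", "clint_total", "renal_cl")

#' Sample a virtual population
#'
#' Draws `spec$n` virtual subjects, each a perturbed copy of the base
#' compound and release parameters. Fractions (`fraction_absorbed`,
#' `fu_plasma`) are clipped back to (0, 1] after sampling; `fmax` is capped
#' at 110%. Two populations drawn with different seeds are independent,
#' which is how the two arms of a parallel trial are built.
#'
#' @param spec A [population_spec()].
#' @param base_compound A [compound_params()].
#' @param base_release A [weibull_params()].
#' @param seed Optional seed overriding `spec$seed` (used by the trial
#'   engine to decorrelate arms and replicate studies).
#' @return A list of `virtual_subject` objects, each with `subject_id`,
#'   `compound` and `release`.
#' @export
sample_population <- function(spec, base_compound, base_release, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(base_compound, "compound_params"),
            inherits(base_release, "weibull_params"))
  cvs <- spec$parameter_cvs
  if (is.null(cvs)) {
    cvs <- stats::setNames(rep(base_release$cv, 4L), .release_par_names)
  }
  known <- c(.release_par_names, .compound_par_names)
  bad <- setdiff(names(cvs), known)
  if (length(bad) > 0L)
    stop(sprintf("sample_population: unknown parameter name(s) in CV map: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(seed)) seed <- spec$seed
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  draw <- function(base, cv) {
    if (cv <= 0 || base == 0) return(rep(base, spec$n))
    sdlog <- sqrt(log(1 + cv^2))
    base * exp(stats::rnorm(spec$n, mean = 0, sd = sdlog))
  }
  samples <- lapply(names(cvs), function(nm) {
    base <- if (nm %in% .release_par_names) base_release[[nm]]
            else base_compound[[nm]]
    draw(base, cvs[[nm]])
  })
  names(samples) <- names(cvs)

  lapply(seq_len(spec$n), function(i) {
    comp <- base_compound; rel <- base_release
    for (nm in names(samples)) {
      val <- samples[[nm]][i]
      if (nm %in% c("fraction_absorbed", "fu_plasma")) val <- min(val, 1)
      if (nm == "fmax") val <- min(val, 110)
      if (nm %in% .release_par_names) rel[[nm]] <- val else comp[[nm]] <- val
    }
    structure(list(subject_id = i, compound = comp, release = rel),
              class = "virtual_subject")
  })
}

#' Export a sampled population as a data.frame for audit
#'
#' @param subjects A list of `virtual_subject` objects from
#'   [sample_population()].
#' @return A data.frame with one row per subject and one column per
#'   parameter.
#' @export
population_table <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               fmax = s$release$fmax, lag = s$release$lag,
               alpha = s$release$alpha, beta = s$release$beta,
               volume_of_distribution = s$compound$volume_of_distribution,
               ka = s$compound$ka,
               fraction_absorbed = s$compound$fraction_absorbed,
               fu_plasma = s$compound$fu_plasma,
               clint_total = s$compound$clint_total,
               renal_cl = s$compound$renal_cl)
  }))
}
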