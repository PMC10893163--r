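test_that("be_decision is boundary-inclusive on the 80-125% limits", {
  expect_true(be_decision(85, 118))
  expect_false(be_decision(79.9, 110))
  expect_false(be_decision(90, 125.01))
  expect_true(be_decision(80, 125))
  expect_error(be_decision(110, 90), "ci_lower")
})

test_that("the Welch interval matches the t.test oracle on small arms", {
  set.seed(41)
  for (i in 1:10) {
    x <- rlnorm(5, 3, 0.3); y <- rlnorm(5, 3.1, 0.5)
    ours <- vbesim:::log_gmr_ci(log(x), log(y), level = 0.90)
    oracle <- t.test(log(x), log(y), conf.level = 0.90)
    expect_equal(ours$ci, as.numeric(oracle$conf.int), tolerance = 1e-12)
    expect_equal(ours$estimate, unname(diff(rev(oracle$estimate))),
                 tolerance = 1e-12)
    pooled <- vbesim:::log_gmr_ci(log(x), log(y), method = "pooled")
    oracle2 <- t.test(log(x), log(y), conf.level = 0.90, var.equal = TRUE)
    expect_equal(pooled$ci, as.numeric(oracle2$conf.int), tolerance = 1e-12)
  }
})

test_that("zero-variability identical arms give GMR exactly 100% and pass", {
  des <- trial_design(n_per_arm = 4, seed = 3)
  pop0 <- population_spec(4, parameter_cvs = c(alpha = 0))
  tr <- run_vbe(ref_weibull(), ref_weibull(), synthetic_compound(), pop0, des,
                grid = seq(0, 96, by = 0.5))
  expect_true(all(tr$results$gmr == 100))
  expect_true(all(tr$results$ci_lower == 100 & tr$results$ci_upper == 100))
  expect_true(tr$overall_be)
})

test_that("doubling the release scale spares AUC but depresses Cmax (deterministic arms)", {
  des <- trial_design(n_per_arm = 3, seed = 3)
  pop0 <- population_spec(3, parameter_cvs = c(alpha = 0))
  slow <- weibull_params(90, 0.5, 16, 1.2)
  tr <- run_vbe(slow, ref_weibull(), synthetic_compound(), pop0, des,
                grid = seq(0, 400, by = 0.25))
  res <- tr$results
  expect_equal(res$gmr[res$endpoint == "auc_0_inf"], 100, tolerance = 0.005)
  expect_lt(res$gmr[res$endpoint == "cmax"], 100)
})

test_that("the CI-within-limits decision is dual to TOST at alpha 0.05", {
  des <- trial_design(n_per_arm = 12, seed = 5, n_replicate_studies = 4L)
  pop <- population_spec(12, parameter_cvs = c(clint_total = 0.3,
                                               alpha = 0.1))
  # a marginal formulation difference so both decisions occur
  trs <- run_vbe(weibull_params(90, 0.5, 11, 1.2), ref_weibull(),
                 synthetic_compound(), pop, des, grid = seq(0, 96, by = 0.5))
  n_checked <- 0L
  for (tr in trs) {
    for (i in seq_len(nrow(tr$results))) {
      expect_identical(tr$results$passes[i], tr$results$tost_p[i] <= 0.05)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 12L)
})

test_that("swapping test and reference inverts the GMR and mirrors the CI", {
  set.seed(47)
  des <- trial_design(n_per_arm = 8)
  et <- data.frame(subject_id = 1:8, formulation = "test",
                   cmax = rlnorm(8, 1, 0.2), auc_0_t = rlnorm(8, 3, 0.2),
                   auc_0_inf = rlnorm(8, 3.1, 0.2))
  er <- data.frame(subject_id = 1:8, formulation = "reference",
                   cmax = rlnorm(8, 1.1, 0.2), auc_0_t = rlnorm(8, 3, 0.2),
                   auc_0_inf = rlnorm(8, 3.1, 0.2))
  fwd <- vbesim:::summarise_be(et, er, des)$results
  rev_ <- vbesim:::summarise_be(er, et, des)$results
  expect_equal(fwd$gmr * rev_$gmr, rep(100^2, 3), tolerance = 1e-10)
  expect_equal(fwd$ci_lower * rev_$ci_upper, rep(100^2, 3), tolerance = 1e-10)
})

test_that("replicate studies are seeded, reproducible and distinct", {
  des <- trial_design(n_per_arm = 5, seed = 11, n_replicate_studies = 3L)
  pop <- population_spec(5, parameter_cvs = c(clint_total = 0.2))
  t1 <- run_vbe(ref_weibull(), ref_weibull(), synthetic_compound(), pop, des,
                grid = seq(0, 96, by = 1))
  t2 <- run_vbe(ref_weibull(), ref_weibull(), synthetic_compound(), pop, des,
                grid = seq(0, 96, by = 1))
  expect_s3_class(t1, "vbe_trial_set")
  expect_equal(be_summary_table(t1), be_summary_table(t2))
  gmrs <- vapply(t1, function(s) s$results$gmr[1], numeric(1))
  expect_gt(diff(range(gmrs)), 0)  # different sub-seeds per study
  # arms use distinct sub-seeds
  expect_false(t1[[1]]$seeds[["test"]] == t1[[1]]$seeds[["reference"]])
})

test_that("studies missing endpoints in >10% of an arm are flagged invalid", {
  des <- trial_design(n_per_arm = 10)
  mk <- function(bad) {
    d <- data.frame(subject_id = 1:10, formulation = "x",
                    cmax = rlnorm(10, 1, 0.1), auc_0_t = rlnorm(10, 3, 0.1),
                    auc_0_inf = rlnorm(10, 3, 0.1))
    d$auc_0_inf[seq_len(bad)] <- NA
    d
  }
  ok <- vbesim:::summarise_be(mk(1), mk(0), des)
  expect_true(ok$valid)
  bad <- vbesim:::summarise_be(mk(2), mk(0), des)
  expect_false(bad$valid)
  expect_false(bad$overall_be)
})

test_that("the CI narrows as arms grow at fixed variability", {
  set.seed(53)
  widths <- vapply(c(10, 40, 160), function(n) {
    x <- exp(rnorm(n, 0, 0.2)); y <- exp(rnorm(n, 0, 0.2))
    st <- vbesim:::log_gmr_ci(log(x), log(y))
    diff(st$ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
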