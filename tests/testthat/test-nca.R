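test_that("mono-exponential decay is recovered in closed form", {
  t <- seq(0, 120, by = 0.1)
  prof <- data.frame(time = t, conc = 10 * exp(-0.1 * t))
  e <- compute_endpoints(prof)
  expect_equal(e$auc_0_inf, 100, tolerance = 0.5 / 100)
  expect_equal(e$lambda_z, 0.1, tolerance = 0.001 / 0.1)
  expect_equal(e$cmax, 10)
  expect_equal(e$tmax, 0)
  expect_gte(e$auc_0_inf, e$auc_0_t)
})

test_that("tmax is the first point of a strictly decreasing profile", {
  t <- 0:24
  e <- compute_endpoints(data.frame(time = t, conc = 50 * exp(-0.2 * t)))
  expect_equal(e$tmax, 0)
})

test_that("endpoints are homogeneous of degree one in concentration", {
  t <- seq(0, 48, by = 0.25)
  c1 <- 5 * t * exp(-0.3 * t)
  e1 <- compute_endpoints(data.frame(time = t, conc = c1))
  e2 <- compute_endpoints(data.frame(time = t, conc = 2 * c1))
  expect_equal(e2$cmax, 2 * e1$cmax)
  expect_equal(e2$auc_0_t, 2 * e1$auc_0_t)
  expect_equal(e2$auc_0_inf, 2 * e1$auc_0_inf)
  expect_equal(e2$lambda_z, e1$lambda_z)
})

test_that("trailing zero samples do not change Cmax or AUC0-t", {
  t <- seq(0, 48, by = 0.5)
  c1 <- 5 * t * exp(-0.3 * t)
  c1[t > 40] <- 0
  e1 <- compute_endpoints(data.frame(time = t, conc = c1))
  t2 <- c(t, 50, 60); c2 <- c(c1, 0, 0)
  e2 <- compute_endpoints(data.frame(time = t2, conc = c2))
  expect_equal(e2$cmax, e1$cmax)
  expect_equal(e2$auc_0_t, e1$auc_0_t)
})

test_that("trapezoid AUC converges at second order on a smooth profile", {
  f <- function(t) 5 * t * exp(-0.3 * t)
  exact <- integrate(f, 0, 30, rel.tol = 1e-12)$value
  err <- vapply(c(0.5, 0.25, 0.125), function(h) {
    t <- seq(0, 30, by = h)
    abs(compute_endpoints(data.frame(time = t, conc = f(t)))$auc_0_t - exact)
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 3.3 & ratios < 4.7))
})

test_that("degenerate profiles are flagged rather than mis-reported", {
  expect_warning(e <- compute_endpoints(data.frame(time = 0:5,
                                                   conc = rep(0, 6))),
                 "all-zero")
  expect_equal(e$auc_0_inf, 0)
  # rising-only profile: no terminal slope identifiable
  e2 <- compute_endpoints(data.frame(time = 0:5, conc = c(1, 2, 3, 4, 5, 6)))
  expect_true(is.na(e2$lambda_z))
  expect_true(is.na(e2$auc_0_inf))
  expect_error(compute_endpoints(data.frame(time = 0:1, conc = c(1, 2))),
               "3 samples")
  expect_error(compute_endpoints(data.frame(time = 0:3, conc = c(1, -1, 2, 0))),
               "negative")
})

test_that("log-down trapezoid is close to linear on dense declining data", {
  t <- seq(0, 72, by = 0.25)
  prof <- data.frame(time = t, conc = 10 * exp(-0.15 * t))
  lin <- compute_endpoints(prof, method = "linear")
  logd <- compute_endpoints(prof, method = "log-down")
  expect_equal(logd$auc_0_t, lin$auc_0_t, tolerance = 1e-3)
  expect_lt(logd$auc_0_t, lin$auc_0_t)  # log rule is exact, linear overestimates
})
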