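test_that("dissolution_profile validates its invariants", {
  expect_s3_class(dissolution_profile("F", usp_times,
                                      matrix(1:18 * 5, nrow = 9)),
                  "dissolution_profile")
  expect_error(dissolution_profile("F", c(2, 1, 4), c(1, 2, 3)),
               "strictly increasing")
  expect_error(dissolution_profile("F", c(0, 1), c(1, 2)), "> 0")
  expect_error(dissolution_profile("F", c(1, 2), c(1, 120)), "\\[0, 110\\]")
  expect_error(dissolution_profile("F", c(1, 2), c(1, NA)), "finite")
})

test_that("dissolution CSV round-trips profiles exactly", {
  p1 <- dissolution_profile("A", usp_times,
                            cbind(seq(5, 85, 10), seq(6, 86, 10)))
  p2 <- dissolution_profile("B", usp_times, seq(4, 84, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dissolution_csv(list(p1, p2), path)
  back <- read_dissolution_csv(path)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$dissolved, p1$dissolved, ignore_attr = TRUE)
  expect_equal(back$B$times, usp_times)
  expect_error(read_dissolution_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("f2 matches its analytic identities", {
  r <- c(10, 30, 50, 70, 85)
  expect_equal(compute_f2(r, r)$f2, 100)
  expect_equal(compute_f2(r, r - sqrt(99))$f2, 50)
  res <- compute_f2(r, c(15, 35, 55, 75, 90))
  expect_equal(res$f2, 64.63, tolerance = 0.01 / 64.63)
  expect_true(res$similar)
  expect_equal(res$n_points_used, 5L)
})

test_that("f2 is symmetric and strictly decreasing in a constant offset", {
  r <- c(10, 30, 50, 70, 85)
  offsets <- c(0.5, 1, 2, 5, 8, 12)
  f2s <- vapply(offsets, function(d) compute_f2(r, r + d)$f2, numeric(1))
  expect_true(all(diff(f2s) < 0))
  for (d in offsets)
    expect_equal(compute_f2(r, r + d)$f2, compute_f2(r + d, r)$f2)
})

test_that("f2 rejects mismatched grids and too-few points", {
  pa <- dissolution_profile("A", usp_times, seq(5, 85, 10))
  pb <- dissolution_profile("B", usp_times + 1, seq(5, 85, 10))
  expect_error(compute_f2(pa, pb), "grids differ")
  expect_error(compute_f2(c(1, 2, 3), c(1, 2)), "grids differ")
  expect_error(compute_f2(50, 50), "at least 2")
})

test_that("the similarity flag follows the 50-100 band", {
  r <- c(10, 30, 50, 70, 85)
  expect_false(compute_f2(r, r + 15)$similar)     # f2 below 50
  expect_true(compute_f2(r, r + 5)$similar)       # f2 well inside the band
  expect_equal(compute_f2(r, r + sqrt(99))$f2, 50)
})

test_that("85% truncation keeps at most one point past 85% on both curves", {
  r <- c(20, 50, 80, 90, 95, 97)
  t <- r - 2
  res_all <- compute_f2(r, t)
  res_tr <- compute_f2(r, t, truncate_85 = TRUE)
  # both curves first exceed 85 at index 4; keep through that point only
  expect_equal(res_tr$n_points_used, 4L)
  expect_equal(res_all$n_points_used, 6L)
})

test_that("replicate-level f2 returns one value per replicate pairing", {
  set.seed(3)
  base <- weibull_fraction(ref_weibull(), usp_times)
  pa <- dissolution_profile("A", usp_times,
                            sapply(1:3, function(i) pmin(base + rnorm(9), 105)))
  pb <- dissolution_profile("B", usp_times,
                            sapply(1:2, function(i) pmin(base + rnorm(9), 105)))
  res <- compute_f2(pa, pb, level = "replicate")
  expect_equal(dim(res$f2_replicate), c(3L, 2L))
  expect_true(all(res$f2_replicate > 50))
})
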