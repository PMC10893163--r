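test_that("constructors enforce parameter invariants", {
  expect_error(compound_params(volume_of_distribution = -1, fu_plasma = 0.5,
                               clint_total = 10), "> 0")
  expect_error(compound_params(volume_of_distribution = 50, fu_plasma = 0.5,
                               clint_total = 10, fm_cyp1a2 = 0.7,
                               fm_cyp3a4 = 0.5), "fm_cyp1a2")
  expect_error(inhibitor_spec(ki_cyp1a2 = 0), "Ki")
  expect_error(inhibitor_spec(fu_inc_cyp1a2 = 1.5), "fu_inc")
  expect_error(dosing_regimen(c(-1, 2), 1), ">= 0")
  reg <- dosing_regimen(c(8, 0, 16), c(2, 1, 3))
  expect_equal(reg$time, c(0, 8, 16))
  expect_equal(reg$dose, c(1, 2, 3))
})

test_that("regimen helpers build the expected event tables", {
  bid <- regimen_repeated(500, 12, 14)
  expect_equal(nrow(bid), 14L)
  expect_equal(bid$time, seq(0, by = 12, length.out = 14))
  tit <- regimen_titration(step_doses = c(0.5, 1, 1.5, 2), days_per_step = 7,
                           times_per_day = 3)
  expect_equal(nrow(tit), 4 * 7 * 3)
  expect_equal(unique(tit$dose[tit$time < 7 * 24]), 0.5)
  expect_equal(unique(tit$dose[tit$time >= 21 * 24]), 2)
  expect_equal(diff(tit$time)[1], 8)
})

test_that("instantaneous release reproduces the Bateman double exponential", {
  comp <- oracle_compound()
  ke <- total_clearance(comp) / comp$volume_of_distribution
  grid <- seq(0, 72, by = 0.1)
  prof <- simulate_subject(comp, NULL, regimen_single(10), grid = grid)
  oracle <- bateman(grid, 10, comp$ka, ke, comp$volume_of_distribution)
  idx <- oracle > max(oracle) * 1e-3
  expect_lt(max(abs(prof$conc[idx] - oracle[idx]) / oracle[idx]), 1e-4)
  # a sub-threshold Weibull scale takes the same exact-bolus path
  tiny <- weibull_params(100, 0, 1e-9, 1)
  prof2 <- simulate_subject(comp, tiny, regimen_single(10), grid = grid)
  expect_equal(prof2$conc, prof$conc, tolerance = 1e-10)
})

test_that("single-dose AUC0-inf obeys mass balance: Fa Fmax D / CL", {
  comp <- oracle_compound(renal = 1)
  wp <- ref_weibull()
  grid <- seq(0, 240, by = 0.25)
  prof <- simulate_subject(comp, wp, regimen_single(10), grid = grid)
  e <- compute_endpoints(prof)
  expected <- 1 * (90 / 100) * 10 / total_clearance(comp) * 1000
  expect_lt(abs(e$auc_0_inf - expected) / expected, 0.005)
})

test_that("kinetics are linear in dose and superpose over events", {
  comp <- oracle_compound()
  wp <- ref_weibull()
  grid <- seq(0, 120, by = 0.25)
  p1 <- simulate_subject(comp, wp, regimen_single(10), grid = grid)
  p2 <- simulate_subject(comp, wp, regimen_single(20), grid = grid)
  expect_equal(p2$conc, 2 * p1$conc, tolerance = 1e-6)
  pm <- simulate_subject(comp, wp, dosing_regimen(c(0, 12), 10), grid = grid)
  shifted <- approx(grid + 12, p1$conc, xout = grid, yleft = 0)$y
  expect_lt(max(abs(pm$conc - (p1$conc + shifted))) / max(pm$conc), 1e-3)
})

test_that("no input mass means zero concentrations everywhere", {
  comp <- oracle_compound()
  prof <- simulate_subject(comp, ref_weibull(), regimen_single(0),
                           grid = seq(0, 48, 0.5))
  expect_true(all(prof$conc == 0))
  # fmax -> 0 limit: concentrations scale away with the released fraction
  small <- weibull_params(1e-3, 0.5, 8, 1.2)
  prof2 <- simulate_subject(comp, small, regimen_single(10),
                            grid = seq(0, 48, 0.5))
  expect_lt(max(prof2$conc), 1e-3)
})

test_that("slower release lowers Cmax but leaves AUC0-inf unchanged", {
  comp <- oracle_compound()
  grid <- seq(0, 400, by = 0.25)
  alphas <- c(4, 8, 16)
  eps <- lapply(alphas, function(a)
    compute_endpoints(simulate_subject(comp, weibull_params(90, 0.5, a, 1.2),
                                       regimen_single(10), grid = grid)))
  cmax <- vapply(eps, `[[`, numeric(1), "cmax")
  auc <- vapply(eps, `[[`, numeric(1), "auc_0_inf")
  expect_true(all(diff(cmax) < 0))
  expect_lt(diff(range(auc)) / mean(auc), 0.005)
})

test_that("effective_clint implements the static competitive-inhibition model", {
  comp <- compound_params(volume_of_distribution = 100, fu_plasma = 0.5,
                          clint_total = 2, fm_cyp1a2 = 0.5, fm_cyp3a4 = 0.4)
  expect_equal(effective_clint(comp, inhibitor_spec()), comp$clint_total)
  # fully CYP1A2-cleared compound at Iu/(Ki fu_inc) = 1: CLint halves
  c1 <- compound_params(volume_of_distribution = 100, fu_plasma = 0.5,
                        clint_total = 2, fm_cyp1a2 = 1)
  i1 <- inhibitor_spec(ki_cyp1a2 = 2, fu_inc_cyp1a2 = 0.5,
                       unbound_concentration = 1)
  expect_equal(effective_clint(c1, i1), 1)
  # hand-evaluated split: fm 0.5/0.4, both inhibition ratios 9
  i9 <- inhibitor_spec(ki_cyp1a2 = 1, ki_cyp3a4 = 1,
                       unbound_concentration = 9)
  expect_equal(effective_clint(comp, i9) / comp$clint_total, 0.19)
})

test_that("steady-state AUC ratio matches the static prediction in the linear limit", {
  comp <- compound_params(volume_of_distribution = 100, ka = 2,
                          fu_plasma = 0.5, hepatic_blood_flow = 90,
                          clint_total = 2, fm_cyp1a2 = 0.5, fm_cyp3a4 = 0.4)
  expect_equal(as.numeric(
    steady_state_auc_ratio(comp, inhibitor_spec(), dose = 1)), 1,
    tolerance = 1e-6)
  i9 <- inhibitor_spec(ki_cyp1a2 = 1, ki_cyp3a4 = 1, unbound_concentration = 9)
  r <- as.numeric(steady_state_auc_ratio(comp, i9, dose = 1))
  expect_equal(r, 1 / 0.19, tolerance = 0.02)
  # single fully inhibited pathway: ratio = 1 + Iu/Ki,u
  c1 <- compound_params(volume_of_distribution = 100, ka = 2, fu_plasma = 0.5,
                        hepatic_blood_flow = 90, clint_total = 2,
                        fm_cyp1a2 = 1)
  i3 <- inhibitor_spec(ki_cyp1a2 = 1, unbound_concentration = 3)
  expect_equal(as.numeric(steady_state_auc_ratio(c1, i3, dose = 1)), 4,
               tolerance = 0.02)
})

test_that("the solver grid must cover all dose events", {
  comp <- oracle_compound()
  expect_error(simulate_subject(comp, NULL, regimen_single(10, time = 100),
                                grid = seq(0, 48, 1)), "grid")
})
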