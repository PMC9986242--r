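tgrid <- seq(5, 120, by = 5)

test_that("noiseless PFO data are recovered exactly", {
  dat <- gen_kinetic_series("pfo", list(qe = 14.102, k1 = 0.02), tgrid)
  f <- fit_pfo(dat)
  expect_equal(f$parameters$qe_cal, 14.102, tolerance = 1e-6)
  expect_equal(f$parameters$k1, 0.02, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_length(f$excluded, 0)
})

test_that("PFO handles the flat and saturated edge cases", {
  flat <- kinetic_data(tgrid, rep(5, length(tgrid)), qe_exp = 6)
  f <- fit_pfo(flat)
  expect_false(f$admissible)
  expect_equal(f$parameters$k1, 0, tolerance = 1e-12)
  # points at or above qe_exp are excluded from the log transform
  sat <- kinetic_data(c(5, 10, 20, 40, 80, 120), c(2, 4, 6, 8, 10, 10),
                      qe_exp = 10)
  fs <- fit_pfo(sat)
  expect_equal(fs$excluded, c(80, 120))
  expect_error(fit_pfo(kinetic_data(c(1, 2, 3), c(9.9, 10, 10), qe_exp = 10)),
               "usable")
})

test_that("noiseless PSO data are recovered exactly, with the qe gap reported", {
  dat <- gen_kinetic_series("pso", list(qe = 16.215, k2 = 0.008), tgrid)
  f <- fit_pso(dat)
  expect_equal(f$parameters$qe_cal, 16.215, tolerance = 1e-6)
  expect_equal(f$parameters$k2, 0.008, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # against the study's experimental capacity the relative gap is ~15%
  f2 <- fit_pso(dat, qe_exp = 14.102)
  expect_equal(f2$qe_gap, abs(16.215 - 14.102) / 14.102, tolerance = 1e-6)
  expect_equal(f2$qe_gap, 0.1498, tolerance = 0.01)
})

test_that("Elovich literal fit matches the published parameter reading", {
  dat <- gen_kinetic_series("elovich", list(alpha = 1.392, beta = 3.29), tgrid)
  f <- fit_elovich(dat)
  expect_equal(f$parameters$alpha, 1.392, tolerance = 1e-6)
  expect_equal(f$parameters$beta, 3.29, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # literal and standard parameterizations describe the same regression line
  fs <- fit_elovich(dat, parameterization = "standard")
  a <- fs$parameters$a
  b <- fs$parameters$b
  expect_equal((1 / b) * log(a * b), f$parameters$alpha, tolerance = 1e-9)
  expect_equal(1 / b, f$parameters$beta, tolerance = 1e-9)
  # constant uptake degenerates
  fc <- fit_elovich(kinetic_data(tgrid, rep(2, length(tgrid)), qe_exp = 2))
  expect_false(fc$admissible)
})

test_that("single-segment intraparticle fit recovers slope, intercept, origin flag", {
  dat <- gen_kinetic_series("ipd", list(k_id = 1.53, c = 3.745), tgrid)
  f <- fit_ipd(dat)
  expect_equal(unname(f$parameters$k_id), 1.53, tolerance = 1e-6)
  expect_equal(unname(f$parameters$c), 3.745, tolerance = 1e-6)
  expect_equal(unname(f$parameters$r_squared), 1, tolerance = 1e-12)
  expect_false(f$parameters$through_origin)
  origin <- gen_kinetic_series("ipd", list(k_id = 0.9, c = 0), tgrid)
  fo <- fit_ipd(origin)
  expect_true(fo$parameters$through_origin)
  expect_equal(unname(fo$parameters$c), 0, tolerance = 1e-8)
})

test_that("auto segmentation recovers a three-phase uptake curve", {
  # piecewise sqrt-t curve: fast film diffusion, slower pore diffusion,
  # near-flat equilibrium, continuous at the joins
  t1 <- seq(4, 36, by = 4)    # 9 points, slope 2.0
  t2 <- seq(40, 80, by = 4)   # 11 points, slope 0.8
  t3 <- seq(85, 120, by = 5)  # 8 points, slope 0.1
  q1 <- 2.0 * sqrt(t1)
  off2 <- 2.0 * sqrt(36) - 0.8 * sqrt(36)
  q2 <- 0.8 * sqrt(t2) + off2
  off3 <- (0.8 * sqrt(80) + off2) - 0.1 * sqrt(80)
  q3 <- 0.1 * sqrt(t3) + off3
  dat <- kinetic_data(c(t1, t2, t3), c(q1, q2, q3))
  f <- fit_ipd(dat, breakpoints = "auto", n_segments = 3)
  expect_equal(nrow(f$parameters), 3)
  expect_equal(unname(f$parameters$k_id), c(2.0, 0.8, 0.1), tolerance = 1e-6)
  # exhaustive-search oracle: recovered cuts are within one grid point
  expect_true(abs(f$cuts[1] - length(t1)) <= 1)
  expect_true(abs(f$cuts[2] - (length(t1) + length(t2))) <= 1)
  # explicit breakpoints reproduce the same segmentation
  fe <- fit_ipd(dat, breakpoints = c(36, 80))
  expect_equal(unname(fe$parameters$k_id), c(2.0, 0.8, 0.1), tolerance = 1e-6)
  expect_error(fit_ipd(dat, breakpoints = "auto", n_segments = 20),
               "infeasible")
})

test_that("seeded noisy PFO rate constants are recovered within 10% (median)", {
  err <- vapply(1:100, function(s) {
    dat <- gen_kinetic_series("pfo", list(qe = 14.102, k1 = 0.02), tgrid,
                              noise = 0.02 * 14.102, seed = s)
    f <- fit_pfo(dat, qe_exp = 14.102)
    abs(f$parameters$k1 - 0.02) / 0.02
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("model comparison prefers the generating kinetic law", {
  wins <- vapply(1:100, function(s) {
    dat <- gen_kinetic_series("pso", list(qe = 16.215, k2 = 0.008), tgrid,
                              noise = 0.02 * 16.215, seed = s + 1000)
    ck <- compare_kinetics(dat)
    which(names(ck$fits) == "pso") < which(names(ck$fits) == "pfo")
  }, logical(1))
  expect_gte(sum(wins), 90)
  # noiseless Elovich data rank Elovich first with R^2 = 1
  datE <- gen_kinetic_series("elovich", list(alpha = 1.392, beta = 3.29), tgrid)
  ckE <- compare_kinetics(datE)
  expect_equal(ckE$fits[[1]]$model, "elovich")
  expect_equal(ckE$fits[[1]]$r_squared, 1, tolerance = 1e-12)
  expect_true(all(vapply(ckE$fits, function(f) all(f$r_squared <= 1 + 1e-12),
                         logical(1))))
})

test_that("fitted PSO curve rises monotonically to its asymptote", {
  dat <- gen_kinetic_series("pso", list(qe = 16.215, k2 = 0.008), tgrid,
                            noise = 0.1, seed = 4)
  f <- fit_pso(dat)
  grid <- seq(1, 5000, length.out = 300)
  curve <- kinetic_qt("pso", list(qe = f$parameters$qe_cal,
                                  k2 = f$parameters$k2), grid)
  expect_true(all(diff(curve) > 0))
  expect_true(all(curve < f$parameters$qe_cal))
  expect_equal(curve[300], f$parameters$qe_cal, tolerance = 0.01)
})

test_that("the study's equilibrium capacity ties kinetics to the mass balance", {
  qe <- capacity_qe(10, ce_from_removal(10, 70.509), V = 0.1, M = 0.05)
  expect_equal(qe, 14.102, tolerance = 1e-3)
})

test_that("the kinetic report labels calculated and experimental capacities", {
  dat <- gen_kinetic_series("pso", list(qe = 16.215, k2 = 0.008), tgrid)
  rep_ <- kinetic_report(compare_kinetics(dat, qe_exp = 14.102)$fits)
  expect_true(all(c("qe_cal", "qe_exp", "k2", "k1") %in% rep_$parameter))
  expect_true("k_id_seg1" %in% rep_$parameter)
})
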