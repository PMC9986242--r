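test_that("larger-is-better S/N matches its closed form", {
  expect_equal(snr_larger_better(87.14), 38.80, tolerance = 0.005)
  expect_equal(snr_larger_better(56.68), 35.07, tolerance = 0.005)
  expect_equal(snr_larger_better(10), 20)
  expect_equal(snr_larger_better(1), 0)
  # n = 1 reduces to 20 log10(Y); n > 1 averages 1/Y^2
  expect_equal(snr_larger_better(42), 20 * log10(42))
  expect_equal(snr_larger_better(c(10, 20)),
               -10 * log10((1 / 100 + 1 / 400) / 2))
  expect_error(snr_larger_better(c(5, -1)), "positive")
})

test_that("S/N is monotone in Y and shifts by 20 log10 under scaling", {
  Y <- sort(runif(50, 1, 100))
  sn <- snr_table(Y)
  expect_true(all(diff(sn) > 0))
  expect_equal(snr_table(2 * Y), sn + 20 * log10(2), tolerance = 1e-12)
  expect_equal(snr_table(rep(7, 5)), rep(20 * log10(7), 5))
})

test_that("the packaged run sheet's S/N column is reproduced", {
  tab <- mb_runs()
  expect_equal(round(snr_table(tab$removal_actual), 2), tab$snr,
               tolerance = 0.0051)
})

test_that("response table reproduces the published level means, deltas, ranks", {
  d <- mb_design()
  rt <- response_table(d, mb_runs()$removal_actual)
  expect_equal(unname(rt$means[, "pH"]),
               c(65.79, 69.72, 75.26, 82.64, 82.52), tolerance = 0.01 / 65)
  expect_lt(abs(rt$delta[["pH"]] - 16.84), 0.01)
  expect_lt(abs(rt$delta[["incubation_time_h"]] - 6.84), 0.01)
  expect_lt(abs(rt$delta[["peptone_pct"]] - 2.39), 0.01)
  expect_equal(unname(rt$rank),
               c(1, 2, 4, 3, 5)) # pH, time, MB, glucose, peptone
  df <- as_response_df(rt)
  expect_equal(nrow(df), 7) # 5 levels + Delta + Rank
})

test_that("constant responses give flat tables and tie-broken optima", {
  d <- mb_design()
  rt <- response_table(d, rep(50, 25))
  expect_true(all(rt$delta == 0))
  expect_equal(unname(rt$rank), 1:5)
  expect_equal(unname(select_optimum(rt)), rep(1L, 5))
  expect_equal(predict_additive(d, rep(50, 25), c(3, 1, 4, 1, 5)), 50)
})

test_that("optimum selection on the S/N scale recovers the published combo", {
  d <- mb_design()
  opt <- select_optimum(response_table(d, mb_runs()$removal_actual, "snr"))
  # pH 8.5, 60 h, 25 mg/L, glucose 2.5 %, peptone 2.5 %
  expect_equal(unname(opt), c(4L, 4L, 4L, 5L, 4L))
})

test_that("additive prediction reproduces the published Predicted column", {
  d <- mb_design()
  tab <- mb_runs()
  Y <- tab$removal_actual
  expect_equal(predict_additive(d, Y, d$runs[19, ]), 87.27, tolerance = 0.01)
  expect_equal(predict_additive(d, Y, d$runs[1, ]), 56.81, tolerance = 0.01)
  pred <- predict_additive(d, Y)
  expect_lt(max(abs(pred - tab$removal_predicted)), 0.01)
  # independent cell-means oracle
  sheet <- assign_levels(d)
  sheet$Y <- Y
  for (r in c(1, 7, 19, 25)) {
    expect_equal(pred[r],
                 oracle_additive(sheet, names(sheet)[2:6], "Y", r),
                 tolerance = 1e-12)
  }
  expect_error(predict_additive(d, Y, c(1, 2, 3, 4, 9)), "invalid")
})

test_that("main-effects ANOVA reproduces the published decomposition", {
  d <- mb_design()
  an <- main_effects_anova(d, mb_runs()$removal_actual)
  ss <- setNames(an$sum_sq, an$source)
  expect_equal(unname(ss["pH"]), 1136.8, tolerance = 0.005)
  expect_equal(unname(ss["Total"]), 1464.18, tolerance = 0.005)
  expect_equal(an$df, c(4, 4, 4, 4, 4, 4, 24))
  # decomposition is exact internally
  expect_equal(sum(ss[1:5]) + ss[["Residual"]], ss[["Total"]],
               tolerance = 1e-8)
  # cross-check the full table against stats::aov on factor() terms
  sheet <- assign_levels(d)
  sheet$Y <- mb_runs()$removal_actual
  av <- summary(stats::aov(Y ~ factor(pH) + factor(incubation_time_h) +
                             factor(initial_mb_mgL) + factor(glucose_pct) +
                             factor(peptone_pct), data = sheet))[[1]]
  expect_equal(unname(ss[1:5]), av[1:5, "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$statistic[1:5], av[1:5, "F value"], tolerance = 1e-8)
  expect_equal(an$p_value[1:5], av[1:5, "Pr(>F)"], tolerance = 1e-8)
  expect_true(all(an$p_value[1:5] <= 0.05))
})

test_that("prediction and ANOVA agree on the residual sum of squares", {
  d <- mb_design()
  Y <- mb_runs()$removal_actual
  an <- main_effects_anova(d, Y)
  pred <- predict_additive(d, Y)
  expect_equal(sum((Y - pred)^2),
               an$sum_sq[an$source == "Residual"], tolerance = 1e-8)
  rd <- residual_diagnostics(Y, pred)
  expect_equal(sum(rd$residuals), 0, tolerance = 1e-9)
  expect_equal(sum(rd$residuals^2),
               an$sum_sq[an$source == "Residual"], tolerance = 1e-8)
  expect_true(rd$sign_runs >= 1)
})

test_that("a saturated design reports SS but flags F/p unavailable", {
  d <- build_orthogonal_array(5, 6)
  set.seed(1)
  Y <- rnorm(25, 70, 3)
  an <- main_effects_anova(d, Y)
  expect_true(attr(an, "saturated"))
  expect_true(all(is.na(an$statistic[1:6])))
  expect_equal(sum(an$sum_sq[1:6]) + an$sum_sq[7], an$sum_sq[8],
               tolerance = 1e-8)
})

test_that("noiseless additive synthetic data are fitted exactly", {
  d <- mb_design()
  effects <- list(c(-8, -4, 0, 6, 6), c(-3, 0, 1, 2, 0),
                  c(-1, 0, 0, 1, 0), c(-2, -1, 0, 1, 2),
                  c(-0.5, 0, 0, 0.5, 0)) # pH analogue has the widest range
  sim <- gen_taguchi_responses(d, 75, effects, sd = 0)
  an <- main_effects_anova(d, sim$Y)
  expect_lt(abs(an$sum_sq[an$source == "Residual"]), 1e-8)
  expect_equal(predict_additive(d, sim$Y), sim$Y, tolerance = 1e-10)
  # injected effect ranges drive the delta ranking
  rt <- response_table(d, sim$Y)
  expect_equal(unname(rt$rank[1]), 1) # widest injected range first
  expect_equal(unname(rt$means[, 1]), 75 + effects[[1]] -
                 mean(effects[[1]]), tolerance = 1e-10)
})

test_that("Gaussian-noise residuals pass normality in most seeded replicates", {
  # residuals against the generator truth are iid Gaussian, so the
  # Shapiro-Wilk rejection rate should sit near its 5% size (fitted-model
  # residuals carry only 4 df here and are not an iid sample)
  d <- mb_design()
  effects <- mb_taguchi_effects()
  pass <- vapply(1:100, function(s) {
    sim <- gen_taguchi_responses(d, 75, effects, sd = 0.5, seed = s)
    rd <- residual_diagnostics(sim$Y, attr(sim, "truth"))
    rd$shapiro_p > 0.05
  }, logical(1))
  expect_gte(sum(pass), 90)
})

test_that("seeded noisy designs flag the injected factors at p < 0.05", {
  d <- mb_design()
  effects <- mb_taguchi_effects() # study-sized main effects
  sig <- vapply(1:100, function(s) {
    sim <- gen_taguchi_responses(d, 75.19, effects, sd = 0.5, seed = s)
    an <- main_effects_anova(d, sim$Y)
    an$p_value[1:5] < 0.05
  }, logical(5))
  # the four strong factors are detected in every replicate
  expect_true(all(sig[1:4, ]))
  # the weakest factor's detection rate agrees with its analytic
  # noncentral-F power (oracle), within a 3-sigma binomial band
  ss_weak <- 5 * sum(effects[[5]]^2)
  power <- 1 - stats::pf(stats::qf(0.95, 4, 4), 4, 4,
                         ncp = ss_weak / 0.5^2)
  rate <- mean(sig[5, ])
  expect_lt(abs(rate - power), 3 * sqrt(power * (1 - power) / 100))
})
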