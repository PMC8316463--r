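test_that("univariate fit: null recovery, separation and guards", {
  set.seed(81)
  x <- rnorm(10000)
  y <- rbinom(10000, 1, 0.5)
  f <- fit_choice_univariate(x, y)
  expect_lt(abs(f$coefficient), 3 * f$se)
  expect_false(f$separation)
  # perfectly separated toy data raises the flag
  fs <- fit_choice_univariate(1:10, as.integer(1:10 > 5))
  expect_true(fs$separation)
  expect_error(fit_choice_univariate(1:5, rep(1, 5)), "both choice classes")
  expect_error(fit_choice_univariate(rep(2, 6), rep(0:1, 3)), "constant")
})

test_that("univariate fit recovers a published-scale generating slope", {
  cells <- obstacle_cells()
  amr <- cells$amr[cells$target_offset_cm == 0]
  beta <- 4.67
  set.seed(82)
  x <- sample(amr, 6000, replace = TRUE)
  y <- rbinom(6000, 1, plogis(qlogis(0.9) + beta * (x - 1)))
  f <- fit_choice_univariate(x, y)
  expect_lt(abs(f$coefficient - beta), 3 * f$se)
  expect_lt(f$p_value, 0.01)
})

test_that("multivariate fit: sparsity of absent interactions, collinearity", {
  cells <- obstacle_cells()
  feats <- cells[sample.int(nrow(cells), 4000, replace = TRUE),
                 c("delta_theta", "delta_d", "amr")]
  z <- scale(as.matrix(feats))
  set.seed(83)
  y <- rbinom(4000, 1, plogis(1 + z %*% c(-1, -0.4, 0.8)))
  fit <- fit_choice_multivariate(feats, y)
  # generating model has no interactions: L1 + refit keeps them near zero
  expect_lt(abs(fit$effects[["delta_theta:delta_d"]]), 0.15)
  expect_lt(abs(fit$effects[["delta_theta:amr"]]), 0.15)
  expect_lt(abs(fit$effects[["delta_theta"]] - (-1)), 0.25)
  # duplicate feature column is reported
  dup <- feats; dup$amr <- dup$delta_d
  expect_warning(fit_choice_multivariate(dup, y, interactions = FALSE),
                 "collinear")
})

test_that("surrogate bootstrap: calibration, power, determinism, guards", {
  uni_fitter <- function(f, ch) c(slope = logit_slope(f$x, ch))
  # pure noise: surrogate p should not be extreme
  set.seed(84)
  ps <- vapply(1:11, function(i) {
    d <- data.frame(x = rnorm(80))
    ch <- rbinom(80, 1, 0.5)
    bootstrap_effects(d, ch, fitter = uni_fitter, n_surrogates = 150,
                      seed = i)$p_values[["slope"]]
  }, numeric(1))
  expect_gt(median(ps), 0.15)
  expect_lt(median(ps), 0.85)
  # strong standardized effect: no surrogate reaches it
  # (scaled down from n = 1e4 / 2000 surrogates to fit the test budget)
  set.seed(85)
  d <- data.frame(x = rnorm(2000))
  ch <- rbinom(2000, 1, plogis(5 * d$x))
  b <- bootstrap_effects(d, ch, fitter = uni_fitter, n_surrogates = 300,
                         seed = 9)
  expect_lt(b$p_values[["slope"]], 1 / 300)
  expect_true(b$ci[1, "slope"] <= b$observed[["slope"]] &
                b$observed[["slope"]] <= b$ci[2, "slope"])
  b2 <- bootstrap_effects(d, ch, fitter = uni_fitter, n_surrogates = 300,
                          seed = 9)
  expect_identical(b$ci, b2$ci)
  expect_error(bootstrap_effects(d, ch, fitter = uni_fitter,
                                 n_surrogates = 50), "at least 100")
})

test_that("effect partition: arithmetic, edge cases, scale invariance", {
  eq <- effect_partition(c(delta_theta = 0.2, delta_d = -0.2, amr = 0.2))
  expect_equal(unname(eq), rep(100 / 3, 3))
  sh <- effect_partition(c(delta_theta = 0.30, delta_d = 0.10, amr = -0.10))
  expect_equal(unname(sh), c(60, 20, 20))
  z <- effect_partition(c(delta_theta = 0.5, delta_d = 0, amr = 0.5))
  expect_equal(unname(z), c(50, 0, 50))
  expect_equal(sum(z), 100)
  expect_error(effect_partition(c(delta_theta = 0, delta_d = 0, amr = 0)),
               "zero")
  # rescaling a raw feature does not move the partition (standardization)
  cells <- obstacle_cells()
  feats <- cells[sample.int(nrow(cells), 3000, replace = TRUE),
                 c("delta_theta", "delta_d", "amr")]
  set.seed(86)
  y <- rbinom(3000, 1,
              plogis(1 - 0.4 * feats$delta_theta - 0.3 * feats$delta_d +
                       3 * (feats$amr - 1)))
  feats_mm <- transform(feats, delta_d = delta_d * 10)  # cm -> mm
  set.seed(87); f1 <- fit_choice_multivariate(feats, y)
  set.seed(87); f2 <- fit_choice_multivariate(feats_mm, y)
  expect_equal(effect_partition(f1), effect_partition(f2),
               tolerance = 1e-6)
})

test_that("LOOCV accuracy: separable, noise and determinism", {
  cells <- obstacle_cells()
  feats <- cells[rep(1:21, 4), c("delta_theta", "delta_d", "amr")]
  sep_choice <- as.integer(feats$delta_theta < 0)      # noise-free rule
  cv <- loocv_accuracy(feats, sep_choice)
  expect_equal(cv$accuracy_pct, 100)
  set.seed(88)
  noise <- rbinom(nrow(feats), 1, 0.5)
  cvn <- loocv_accuracy(feats, noise)
  expect_gt(cvn$accuracy_pct, 30); expect_lt(cvn$accuracy_pct, 70)
  cvn2 <- loocv_accuracy(feats, noise)
  expect_identical(cvn$accuracy_pct, cvn2$accuracy_pct)
  # participant-level folds
  unit <- rep(1:4, each = 21)
  cvp <- loocv_accuracy(feats, sep_choice, unit = unit)
  expect_equal(cvp$n_folds, 4)
  expect_equal(cvp$accuracy_pct, 100)
  expect_error(loocv_accuracy(feats[1:2, ], c(0, 1), unit = c(1, 1)),
               "at least 2 folds")
})

test_that("judgment threshold: symmetry, recovery and extrapolation flag", {
  # noiseless symmetric ratings around zero
  p0 <- sim_params(judgment_threshold = 0, judgment_noise_sd = 0)
  jd0 <- simulate_judgment(seq(-35, 35, 5), p0, n_raters = 1)
  jc0 <- judgment_threshold(jd0)
  expect_lt(abs(jc0$threshold_cm), 0.1)
  expect_false(jc0$extrapolated)
  expect_equal(jc0$monotone_increasing_violations, 0)
  # all-saturated ratings cannot bracket a crossing
  sat <- data.frame(offset_cm = seq(-35, 35, 5), rating = 10)
  js <- judgment_threshold(sat)
  expect_true(js$extrapolated)
  expect_error(judgment_threshold(data.frame(offset_cm = c(0, 5),
                                             rating = c(4, 6))),
               "4 distinct offsets")
})

test_that("AMGR models: recovery, guards and positive joint effects", {
  set.seed(89)
  a <- runif(8000, -1, 1)
  y <- rbinom(8000, 1, plogis(qlogis(0.9) + 1.94 * a))
  amr_v <- sample(obstacle_cells()$amr, 8000, replace = TRUE)
  fits <- fit_amgr_models(a, amr_v, y)
  expect_lt(abs(fits$univariate$coefficient - 1.94),
            3 * fits$univariate$se)
  expect_error(fit_amgr_models(c(a[1:10], NA), amr_v[1:11], y[1:11]),
               "undefined AMGR")
  expect_error(fit_amgr_models(rep(0.2, 20), amr_v[1:20],
                               rep(0:1, 10)), "constant")
  # both gaze ratio and margin ratio positively predict going right
  set.seed(90)
  y2 <- rbinom(8000, 1, plogis(-2 + 1.4 * a + 2 * amr_v))
  f2 <- fit_amgr_models(a, amr_v, y2)
  expect_gt(f2$bivariate$coefficients[["amgr"]], 0)
  expect_gt(f2$bivariate$coefficients[["amr"]], 0)
})

test_that("choice probability table bins with binomial intervals", {
  set.seed(91)
  x <- runif(300, -5, 5)
  tab <- choice_probability_table(x, rep(1L, 300), breaks = 5)
  expect_true(all(tab$p_right == 1))
  # a one-trial bin has an uninformative interval
  one <- choice_probability_table(c(0, 10), c(1L, 0L), breaks = 2)
  expect_gt(one$ci_high[1] - one$ci_low[1], 0.9)
  expect_warning(
    choice_probability_table(c(rep(0, 5), 10), rep(0:1, 3),
                             breaks = c(0, 1, 5, 10)),
    "empty")
})
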