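test_that("auroc equals pairwise concordance, including tie handling", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.8, 0.6, 0.4, 0.2))$value, 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.3, 4))$value, 0.5)
  # frozen: 3 concordant of 4 case-control pairs
  expect_equal(auroc(c(1, 1, 0, 0), c(0.6, 0.3, 0.5, 0.2))$value, 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "degenerate")
})

test_that("auroc matches the brute-force oracle on random small datasets", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))      # both classes guaranteed
    p <- round(runif(n), sample(1:3, 1))      # coarse rounding forces ties
    expect_equal(auroc(y, p)$value, brute_auroc(y, p),
                 tolerance = 1e-12, label = sprintf("dataset %d", i))
  }
})

test_that("auroc is invariant to strictly monotone transforms of p", {
  set.seed(7)
  y <- rbinom(200, 1, 0.3)
  y[1:2] <- c(0, 1)
  p <- runif(200)
  a0 <- auroc(y, p)$value
  expect_equal(auroc(y, qlogis(p))$value, a0)
  expect_equal(auroc(y, p^3)$value, a0)
  expect_equal(auroc(y, 5 * p - 2)$value, a0)
})

test_that("auroc point estimate and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- rbinom(300, 1, 0.25)
  y[1:2] <- c(0, 1)
  p <- plogis(rnorm(300, -1 + y))
  ours <- auroc(y, p)
  ref <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(ours$value, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci_low, ci[1], tolerance = 1e-9)
  expect_equal(ours$ci_high, ci[3], tolerance = 1e-9)
})

test_that("citl solves the offset-model score equation", {
  expect_equal(citl(c(1, 0), c(0, 0))$value, 0, tolerance = 1e-8)
  # frozen closed form: expit(a) = 3/4 -> a = ln 3
  expect_equal(citl(c(1, 1, 1, 0), rep(0, 4))$value, log(3),
               tolerance = 1e-7)
})

test_that("citl and calibration slope recover injected drift", {
  co <- make_cohort(50000, nonhdl_model(), drift_a = -0.5, drift_b = 1,
                    seed = 55)
  lp <- linear_predictor(nonhdl_model(), co)
  expect_lt(abs(citl(co$y_nonhdl, lp)$value - (-0.5)), 0.05)

  co1 <- make_cohort(50000, nonhdl_model(), seed = 56)
  lp1 <- linear_predictor(nonhdl_model(), co1)
  expect_lt(abs(calibration_slope(co1$y_nonhdl, lp1)$value - 1), 0.05)

  # the miscalibration regime observed in the temporal validation
  co2 <- make_cohort(20000, nonhdl_model(), drift_a = 0, drift_b = 0.71,
                     seed = 57)
  lp2 <- linear_predictor(nonhdl_model(), co2)
  est <- calibration_slope(co2$y_nonhdl, lp2)
  expect_true(est$ci_low <= 0.71 && 0.71 <= est$ci_high)
})

test_that("calibration slope equals the grid-search likelihood maximizer", {
  # overlapping classes, so the Bernoulli MLE is finite
  lp <- c(-2, -1, 0, 0, 1, 2)
  y <- c(0, 1, 0, 1, 0, 1)
  oracle <- grid_slope_mle(y, lp)
  fit <- calibration_slope(y, lp)
  expect_equal(fit$value, unname(oracle["b"]), tolerance = 1e-3)

  set.seed(70)
  lp2 <- rnorm(40, -1, 1)
  y2 <- rbinom(40, 1, plogis(0.5 * lp2)); y2[1:2] <- c(0, 1)
  expect_equal(calibration_slope(y2, lp2)$value,
               unname(grid_slope_mle(y2, lp2)["b"]), tolerance = 1e-3)
})

test_that("degenerate calibration inputs raise estimation errors", {
  y <- c(0, 1, 0, 1)
  expect_error(calibration_slope(y, rep(0.3, 4)), "constant")
  expect_error(calibration_slope(c(0, 0, 1, 1), c(-2, -1, 1, 2)),
               "separat")
  expect_error(citl(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("eo ratio and its log-normal CI behave as defined", {
  expect_equal(eo_ratio(c(0, 0, 1, 1), c(0.1, 0.3, 0.6, 0.8))$value, 0.9)
  expect_equal(eo_ratio(c(0, 1, 1), c(0, 1, 1))$value, 1)
  expect_error(eo_ratio(c(0, 0), c(0.2, 0.3)), "no observed events")

  co <- make_cohort(20000, nonhdl_model(), seed = 77)
  p <- predicted_probability(nonhdl_model(), co)
  est <- eo_ratio(co$y_nonhdl, p)
  expect_lt(abs(est$value - 1), 0.05)
  phi <- mean(co$y_nonhdl)
  expect_equal(est$se, sqrt((1 - phi) / (length(p) * phi)),
               tolerance = 1e-12)
})

test_that("binned calibration curve covers the diagonal when calibrated", {
  co <- make_cohort(20000, nonhdl_model(), seed = 91)
  p <- predicted_probability(nonhdl_model(), co)
  curve <- calibration_curve(co$y_nonhdl, p, bins = 10)
  expect_equal(nrow(curve), 10L)
  expect_false(is.unsorted(curve$predicted))
  covered <- curve$ci_low <= curve$predicted &
    curve$predicted <= curve$ci_high
  expect_gte(sum(covered), 8)
  expect_equal(sum(curve$events), sum(co$y_nonhdl))
})

test_that("slope below one bends the calibration curve around the diagonal", {
  # slope drift with the pivot placed at the cohort's mean log-odds
  # (a* = -(1 - b*) * mean LP), the risk-overestimation regime: the
  # curve runs above the diagonal at low risk and below it at high risk
  co <- make_cohort(20000, nonhdl_model(), drift_a = -0.51,
                    drift_b = 0.64, seed = 92)
  p <- predicted_probability(nonhdl_model(), co)
  curve <- calibration_curve(co$y_nonhdl, p, bins = 10)
  # risk overestimation at the high end, underestimation at the low end
  expect_gt(curve$observed[1], curve$predicted[1])
  expect_lt(curve$observed[10], curve$predicted[10])
})

test_that("calibration curve handles constant predictions and scarce data", {
  y <- rbinom(200, 1, 0.3)
  curve <- calibration_curve(y, rep(0.3, 200), bins = 10)
  expect_equal(length(unique(round(curve$predicted, 12))), 1L)
  expect_error(calibration_curve(y[1:30], rep(0.3, 30), bins = 10),
               "binning")
  lo <- calibration_curve(y, pmin(pmax(rnorm(200, 0.3, 0.1), 0.01), 0.99),
                          smoother = "loess")
  expect_true(all(lo$observed >= 0 & lo$observed <= 1))
})

test_that("validate_model assembles a coherent report", {
  co <- make_cohort(3000, ldl_model(), drift_b = 0.8, seed = 14)
  rep <- validate_model(ldl_model(), co)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$events, sum(co$y_ldl))
  expect_equal(rep$prevalence, mean(co$y_ldl))
  expect_true(rep$discrimination_label %in%
                c("no discrimination", "poor", "acceptable", "excellent",
                  "outstanding"))
  expect_error(validate_model(nonhdl_model(), co), "y_nonhdl")
})

test_that("same-data recalibrated predictions satisfy the MLE identities", {
  co <- make_cohort(4000, nonhdl_model(), drift_a = -0.3, drift_b = 0.7,
                    seed = 15)
  y <- co$y_nonhdl
  lp <- linear_predictor(nonhdl_model(), co)
  fit <- glm(y ~ lp, family = binomial())
  lp_recal <- fitted(fit)
  lp_recal <- log(lp_recal / (1 - lp_recal))
  expect_equal(calibration_slope(y, lp_recal)$value, 1, tolerance = 1e-6)
  expect_equal(citl(y, lp_recal)$value, 0, tolerance = 1e-6)
})
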