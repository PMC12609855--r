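test_that("subgroup AuROC conditions on the covariate", {
  set.seed(71)
  y <- rbinom(400, 1, 0.3); y[1:2] <- c(0, 1)
  p <- plogis(rnorm(400, -1 + 0.8 * y))
  # two copies of the same data in two groups -> identical AuROCs
  g <- rep(c("A", "B"), each = 400)
  tab <- subgroup_auroc(c(y, y), c(p, p), g)
  expect_equal(tab$auroc[1], tab$auroc[2], tolerance = 1e-12)
  expect_equal(sum(tab$n), 800)
  # perfectly separated subgroup reports 1.0
  g2 <- rep(c("sep", "rest"), each = 4)
  tab2 <- subgroup_auroc(c(1, 1, 0, 0, y[1:4]),
                         c(0.9, 0.8, 0.1, 0.2, p[1:4]), g2)
  expect_equal(tab2$auroc[tab2$subgroup == "sep"], 1)
  # single-class subgroup flagged, not dropped
  g3 <- c(rep("only_controls", 5), rep("ok", 395))
  y3 <- c(rep(0, 5), y[6:400])
  tab3 <- subgroup_auroc(y3, p, g3)
  expect_equal(tab3$flag[tab3$subgroup == "only_controls"],
               "single_class")
  expect_true(is.na(tab3$auroc[tab3$subgroup == "only_controls"]))
})

test_that("slope modification degrades subgroup discrimination", {
  spec <- cohort_spec(n = 20000, seed = 72)
  co <- generate_cohort(spec)
  grp <- rep(c("A", "B"), length.out = nrow(co))
  lp <- linear_predictor(nonhdl_model(), co)
  b <- ifelse(grp == "A", 1, 0.5)
  set.seed(73)
  y <- rbinom(nrow(co), 1, plogis(b * lp))
  tab <- subgroup_auroc(y, plogis(lp), grp)
  expect_gt(tab$auroc[tab$subgroup == "A"],
            tab$auroc[tab$subgroup == "B"])
})

test_that("saturated interaction equals independent per-group fits", {
  co <- make_cohort(4000, nonhdl_model(), drift_b = 0.8, seed = 74)
  grp <- factor(rep(c("A", "B"), length.out = nrow(co)))
  lp <- linear_predictor(nonhdl_model(), co)
  tab <- subgroup_calibration(co$y_nonhdl, lp, grp)
  for (g in c("A", "B")) {
    i <- grp == g
    fit <- glm(co$y_nonhdl[i] ~ lp[i], family = binomial())
    expect_equal(tab$c_slope[tab$subgroup == g],
                 unname(coef(fit)[2]), tolerance = 1e-6)
  }
})

test_that("subgroup calibration localizes injected drift", {
  spec <- cohort_spec(n = 20000, seed = 75)
  co <- generate_cohort(spec)
  grp <- rep(c("A", "B"), length.out = nrow(co))
  lp <- linear_predictor(nonhdl_model(), co)
  a <- ifelse(grp == "A", 0, -0.3)
  set.seed(76)
  y <- rbinom(nrow(co), 1, plogis(a + lp))
  tab <- subgroup_calibration(y, lp, grp)
  expect_lt(abs(tab$citl[tab$subgroup == "B"] - (-0.3)), 0.1)
  expect_lt(abs(tab$citl[tab$subgroup == "A"]), 0.1)
  expect_true(tab$citl_high[tab$subgroup == "B"] < 0)
  expect_true(tab$citl_low[tab$subgroup == "A"] < 0 &&
                tab$citl_high[tab$subgroup == "A"] > 0)
})

test_that("a single all-inclusive subgroup reproduces the global metrics", {
  co <- make_cohort(3000, nonhdl_model(), drift_b = 0.8, seed = 77)
  lp <- linear_predictor(nonhdl_model(), co)
  y <- co$y_nonhdl
  one <- factor(rep("all", nrow(co)))
  a <- subgroup_auroc(y, plogis(lp), one)
  cal <- subgroup_calibration(y, lp, one)
  expect_equal(a$auroc, auroc(y, plogis(lp))$value, tolerance = 1e-9)
  expect_equal(cal$c_slope, calibration_slope(y, lp)$value,
               tolerance = 1e-9)
  expect_equal(cal$citl, citl(y, lp)$value, tolerance = 1e-9)
})

test_that("fairness report partitions the cohort and flags small cells", {
  co <- make_cohort(2000, nonhdl_model(), seed = 78,
                    isco_probs = rep(0.1, 10))
  expect_warning(ft <- fairness_report(co, nonhdl_model()), "omitted")
  for (cov in unique(ft$covariate)) {
    rows <- ft[ft$covariate == cov, ]
    expect_equal(sum(rows$n), nrow(co), label = cov)
    expect_equal(sum(rows$events), sum(co$y_nonhdl), label = cov)
  }
  isco <- ft[ft$covariate == "isco_code", ]
  expect_equal(nrow(isco), 10L)
  expect_true(all(abs(isco$n - 200) < 60))
  small <- ft$n < 20 | ft$events < 5
  expect_true(all(nzchar(ft$flag[small])))
})

test_that("tertile cuts are recorded and custom cuts respected", {
  co <- make_cohort(900, nonhdl_model(), seed = 79)
  g <- lipidval:::make_subgroups(co, subgroup_definition("bmi", "tertiles"))
  expect_equal(nlevels(g), 3L)
  expect_true(max(table(g)) - min(table(g)) <= 2)
  g2 <- lipidval:::make_subgroups(
    co, subgroup_definition("dbp", "custom_cuts", cuts = c(60, 80),
                            labels = c("low", "mid", "high")))
  expect_setequal(levels(g2), c("low", "mid", "high"))
  expect_true(all(co$dbp[g2 == "low"] <= 60))
})
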