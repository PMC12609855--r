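test_that("generator recovers the requested marginal moments", {
  spec <- cohort_spec(n = 20000, seed = 42)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 20000L)

  n <- nrow(co)
  # Sample moments against the truncated-normal target's closed-form
  # moments (the sampler's true distribution), and those analytic
  # means against the requested spec values (the truncation shift must
  # stay materially small).
  bounds <- list(age = c(20, 40), bmi = c(12, Inf),
                 metabolic_age = c(0, Inf), dbp = c(35, Inf),
                 sbp = c(60, Inf))
  pars <- list(age = c("age_mean", "age_sd"),
               bmi = c("bmi_mean", "bmi_sd"),
               metabolic_age = c("metage_mean", "metage_sd"),
               dbp = c("dbp_mean", "dbp_sd"),
               sbp = c("sbp_mean", "sbp_sd"))
  for (v in names(pars)) {
    tm <- truncnorm_moments(spec[[pars[[v]][1]]], spec[[pars[[v]][2]]],
                            bounds[[v]][1], bounds[[v]][2])
    expect_lt(abs(mean(co[[v]]) - tm["mean"]), 3 * tm["sd"] / sqrt(n),
              label = sprintf("mean of %s", v))
    expect_lt(abs(sd(co[[v]]) - tm["sd"]), 4 * tm["sd"] / sqrt(2 * n),
              label = sprintf("sd of %s", v))
    expect_lt(abs(tm["mean"] - spec[[pars[[v]][1]]]), 0.5,
              label = sprintf("truncation shift of %s", v))
  }
  expect_lt(abs(mean(co$male) - spec$male_prob),
            3 * sqrt(spec$male_prob * (1 - spec$male_prob) / n))
})

test_that("degenerate variances collapse each predictor onto its mean", {
  spec <- cohort_spec(n = 1, age_sd = 1e-6, bmi_sd = 1e-6,
                      metage_sd = 1e-6, dbp_sd = 1e-6, sbp_sd = 1e-6,
                      seed = 3)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 1L)
  expect_lt(abs(co$age - spec$age_mean), 1e-3)
  expect_lt(abs(co$bmi - spec$bmi_mean), 1e-3)
  expect_lt(abs(co$metabolic_age - spec$metage_mean), 1e-3)
  expect_lt(abs(co$dbp - spec$dbp_mean), 1e-3)
})

test_that("generation is deterministic given the seed", {
  spec <- cohort_spec(n = 500, seed = 11)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  spec2 <- cohort_spec(n = 500, seed = 12)
  expect_false(identical(generate_cohort(spec), generate_cohort(spec2)))
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n = 0), "'n'")
  expect_error(cohort_spec(age_sd = -1), "'age_sd'")
  expect_error(cohort_spec(male_prob = 1.2), "'male_prob'")
  expect_error(cohort_spec(isco_probs = rep(0.1, 9)), "'isco_probs'")
  expect_error(cohort_spec(isco_probs = c(rep(0.1, 9), 0.2)),
               "'isco_probs'")
})

test_that("eq3_plus_noise mode ties metabolic age to age/BMI/gender", {
  spec <- cohort_spec(n = 5000, metage_mode = "eq3_plus_noise",
                      metage_noise_sd = 1e-6, seed = 5)
  co <- generate_cohort(spec)
  expect_equal(co$metabolic_age,
               impute_metabolic_age(co$age, co$bmi, co$male),
               tolerance = 1e-4)
  # positivity is enforced in direct mode (eq3 mode inherits the
  # proxy's unclamped range)
  direct <- generate_cohort(cohort_spec(n = 5000, seed = 5))
  expect_true(all(direct$metabolic_age > 0))
})

test_that("eligibility filter reproduces the screening worked example", {
  # 1105-strong roster, five prior hypercholesterolemia diagnoses and
  # one current pregnancy -> 1099 eligible.
  co <- generate_cohort(cohort_spec(n = 1105, seed = 9))
  co$icd10_codes[1:5] <- "E78.0"
  co$icd10_codes[6] <- "Z34"
  res <- apply_eligibility(co)
  expect_equal(nrow(res$eligible), 1099L)
  expect_equal(nrow(res$exclusion_log), 6L)
  expect_setequal(res$exclusion_log$reason, "icd10")
})

test_that("eligibility rules match prefixes, medications and age bounds", {
  co <- data.frame(id = c("a", "b", "c", "d", "e"),
                   age = c(30, 41, 30, 19, 30),
                   icd10_codes = c("E11", "", "E03.9", "", "E78"),
                   lipid_meds = c("", "", "", "", "statin"),
                   stringsAsFactors = FALSE)
  res <- apply_eligibility(co)
  # E11 is not an excluded prefix -> retained
  expect_true("a" %in% res$eligible$id)
  expect_equal(res$exclusion_log$reason[res$exclusion_log$id == "b"], "age")
  expect_equal(res$exclusion_log$reason[res$exclusion_log$id == "c"], "icd10")
  expect_equal(res$exclusion_log$reason[res$exclusion_log$id == "d"], "age")
  # icd10 outranks medication as the primary logged reason
  expect_equal(res$exclusion_log$reason[res$exclusion_log$id == "e"], "icd10")

  med <- data.frame(id = "f", age = 30, icd10_codes = "",
                    lipid_meds = "Statin", stringsAsFactors = FALSE)
  expect_equal(apply_eligibility(med)$exclusion_log$reason, "medication")
})

test_that("eligibility filtering is idempotent", {
  co <- generate_cohort(cohort_spec(n = 300, seed = 2))
  co$icd10_codes[1:10] <- "F50"
  once <- apply_eligibility(co)$eligible
  twice <- apply_eligibility(once)$eligible
  expect_identical(once, twice)
})

test_that("simulated outcomes are calibrated to the drifted truth", {
  co <- make_cohort(20000, nonhdl_model(), drift_a = 0, drift_b = 1,
                    seed = 21)
  p <- predicted_probability(nonhdl_model(), co)
  expect_lt(abs(mean(co$y_nonhdl) - mean(p)), 0.01)

  sat <- simulate_outcomes(co, outcome_sim_spec(nonhdl_model(),
                                                drift_intercept = -50,
                                                seed = 1))
  expect_true(all(sat$y_nonhdl == 0))

  sim <- outcome_sim_spec(ldl_model(), seed = 4)
  expect_identical(simulate_outcomes(co, sim)$y_ldl,
                   simulate_outcomes(co, sim)$y_ldl)
  expect_error(simulate_outcomes(co[, c("id", "age")], sim), "male")
})

test_that("cohorts round-trip through CSV unchanged", {
  co <- make_cohort(50, seed = 8)
  co$icd10_codes[1] <- "E78;E03"
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$icd10_codes, co$icd10_codes)
  expect_equal(back$metabolic_age, co$metabolic_age, tolerance = 1e-12)
  expect_equal(back$y_nonhdl, co$y_nonhdl)
})
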