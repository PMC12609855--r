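#' Cohort generator specification
#'
#' Marginal distributions for a synthetic screening cohort of
#' hospital-workforce adults. Defaults reproduce the validation-cohort
#' descriptive statistics (n = 1099 recruitment wave): 22.7% male, age
#' 30.4 (4.7) years, BMI 22.9 (4.5) kg/m^2, metabolic age 31.0 (12.6)
#' years, DBP 70.4 (10.1) mmHg, SBP 115.5 (13.2) mmHg. Continuous
#' predictors are drawn from independent truncated normals (rejection
#' sampling at plausibility bounds, see [generate_cohort()]); no joint
#' correlation structure is imposed by default because only marginals
#' are reported for the source population.
#'
#' @param n Number of participants (>= 1).
#' @param male_prob Probability of male gender.
#' @param age_mean,age_sd Age in years.
#' @param bmi_mean,bmi_sd Body mass index, kg/m^2.
#' @param metage_mode `"direct_normal"` draws metabolic age from its own
#'   truncated normal; `"eq3_plus_noise"` computes it from the linear
#'   age/BMI/gender proxy ([impute_metabolic_age()]) plus Gaussian noise.
#' @param metage_mean,metage_sd Metabolic age in years (direct mode).
#' @param metage_noise_sd Noise SD in years (eq3 mode).
#' @param dbp_mean,dbp_sd Diastolic blood pressure, mmHg.
#' @param sbp_mean,sbp_sd Systolic blood pressure, mmHg.
#' @param isco_probs Length-10 probability vector over ISCO-08 major
#'   groups 0-9. The default is a hospital-workforce mix dominated by
#'   professionals, technicians and service workers.
#' @param seed Root seed; per-stage child seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1099,
                        male_prob = 0.227,
                        age_mean = 30.4, age_sd = 4.7,
                        bmi_mean = 22.9, bmi_sd = 4.5,
                        metage_mode = c("direct_normal", "eq3_plus_noise"),
                        metage_mean = 31.0, metage_sd = 12.6,
                        metage_noise_sd = 4.5,
                        dbp_mean = 70.4, dbp_sd = 10.1,
                        sbp_mean = 115.5, sbp_sd = 13.2,
                        isco_probs = c(0.005, 0.03, 0.30, 0.20, 0.12,
                                       0.18, 0.01, 0.02, 0.025, 0.11),
                        seed = 1L) {
  metage_mode <- match.arg(metage_mode)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != floor(n))
    stopf("invalid 'n': must be a positive integer count")
  for (f in c("age_sd", "bmi_sd", "metage_sd", "dbp_sd", "sbp_sd",
              "metage_noise_sd")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stopf("invalid '%s': SDs must be > 0", f)
  }
  if (male_prob < 0 || male_prob > 1)
    stopf("invalid 'male_prob': must be a probability in [0, 1]")
  if (length(isco_probs) != 10L || any(isco_probs < 0) ||
      any(isco_probs > 1) || abs(sum(isco_probs) - 1) > 1e-9)
    stopf("invalid 'isco_probs': 10 probabilities summing to 1")
  spec <- list(n = as.integer(n), male_prob = male_prob,
               age_mean = age_mean, age_sd = age_sd,
               bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               metage_mode = metage_mode, metage_mean = metage_mean,
               metage_sd = metage_sd, metage_noise_sd = metage_noise_sd,
               dbp_mean = dbp_mean, dbp_sd = dbp_sd,
               sbp_mean = sbp_mean, sbp_sd = sbp_sd,
               isco_probs = isco_probs, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Truncated-normal draws by rejection resampling (keeps the conditional
# density; hard clipping would put probability atoms at the bounds).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:10000) {
    bad <- which(x < lower | x > upper)
    if (length(bad) == 0L) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stopf("truncated-normal rejection sampling failed to converge (bounds [%s, %s] too far in the tail of N(%s, %s))",
        lower, upper, mean, sd)
}

# Plausibility bounds used by the generator; age matches the 20-40 year
# eligibility window, the others only exclude physiologically impossible
# draws.
.trunc_bounds <- list(
  age = c(20, 40), bmi = c(12, Inf), metabolic_age = c(0, Inf),
  dbp = c(35, Inf), sbp = c(60, Inf)
)

#' Generate a synthetic cohort
#'
#' Draws one participant record per row: gender, age, BMI, metabolic age,
#' blood pressures and ISCO-08 occupation group, from the marginals in a
#' [cohort_spec()]. Deterministic given `spec$seed`. ICD-10 diagnosis and
#' lipid-medication columns are created empty; use them to stage
#' eligibility scenarios before [apply_eligibility()]. Binary endpoints
#' are attached later by [simulate_outcomes()] (never by thresholding a
#' continuous lipid draw).
#'
#' @param spec A [cohort_spec()].
#' @param include_lipids If `TRUE`, adds cosmetic continuous `ldl_mgdl` /
#'   `nonhdl_mgdl` columns drawn from the reported marginal normals
#'   (123.1 (33.1) and 136.5 (36.5) mg/dL); these are for descriptive
#'   tables only and carry no link to the simulated endpoints.
#' @return A `data.frame` with `spec$n` rows.
#' @export
generate_cohort <- function(spec, include_lipids = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  set.seed(derive_seed(spec$seed, "cohort"))
  male <- stats::rbinom(n, 1L, spec$male_prob)
  age <- rnorm_trunc(n, spec$age_mean, spec$age_sd,
                     .trunc_bounds$age[1], .trunc_bounds$age[2])
  bmi <- rnorm_trunc(n, spec$bmi_mean, spec$bmi_sd, .trunc_bounds$bmi[1])
  if (spec$metage_mode == "direct_normal") {
    metage <- rnorm_trunc(n, spec$metage_mean, spec$metage_sd,
                          .trunc_bounds$metabolic_age[1])
  } else {
    # eq3 mode inherits the proxy's unclamped range: the linear
    # estimate is negative for extreme young/lean/male combinations,
    # so no positivity bound is imposed here (direct mode truncates).
    base <- impute_metabolic_age(age, bmi, male)
    metage <- base + stats::rnorm(n, 0, spec$metage_noise_sd)
  }
  dbp <- rnorm_trunc(n, spec$dbp_mean, spec$dbp_sd, .trunc_bounds$dbp[1])
  sbp <- rnorm_trunc(n, spec$sbp_mean, spec$sbp_sd, .trunc_bounds$sbp[1])
  isco <- sample(0:9, n, replace = TRUE, prob = spec$isco_probs)
  cohort <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    male = male, age = age, bmi = bmi, metabolic_age = metage,
    dbp = dbp, sbp = sbp, isco_code = isco,
    icd10_codes = "", lipid_meds = "",
    stringsAsFactors = FALSE
  )
  if (include_lipids) {
    cohort$ldl_mgdl <- rnorm_trunc(n, 123.1, 33.1, 1)
    cohort$nonhdl_mgdl <- rnorm_trunc(n, 136.5, 36.5, 1)
  }
  cohort
}

#' Eligibility rules for the screening cohort
#'
#' Defaults mirror the study entry criteria: exclusion for any prior
#' ICD-10 diagnosis of hypercholesterolemia (E78), hypothyroidism (E03),
#' anorexia nervosa (F50), nephrotic syndrome (N04) or current pregnancy
#' (Z34); for lipid-modifying or lipid-affecting medication (statins,
#' ezetimibe, PCSK9 inhibitors, fibrates, thiazide diuretics,
#' glucocorticoids, amiodarone, cyclosporin); and for age outside 20-40
#' years.
#'
#' @param excluded_icd10_prefixes Character vector of ICD-10 code
#'   prefixes; a participant is excluded if any of their codes starts
#'   with one of these.
#' @param excluded_medications Character vector of medication names
#'   (matched case-insensitively).
#' @param age_min,age_max Inclusive age window in years.
#' @return An object of class `eligibility_rules`.
#' @export
eligibility_rules <- function(excluded_icd10_prefixes =
                                c("E78", "E03", "F50", "N04", "Z34"),
                              excluded_medications =
                                c("statin", "ezetimibe",
                                  "pcsk9_inhibitor", "fibrate",
                                  "thiazide", "glucocorticoid",
                                  "amiodarone", "cyclosporin"),
                              age_min = 20, age_max = 40) {
  stopifnot(age_min < age_max)
  structure(
    list(excluded_icd10_prefixes = excluded_icd10_prefixes,
         excluded_medications = tolower(excluded_medications),
         age_min = age_min, age_max = age_max),
    class = "eligibility_rules"
  )
}

split_codes <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)

#' Apply eligibility rules to a cohort
#'
#' A record is excluded iff any ICD-10 code matches an excluded prefix,
#' any medication matches the excluded set, or age falls outside the
#' window. One primary reason is logged per excluded record, taken as
#' the first matching rule in the fixed order icd10 -> medication -> age;
#' the filter is idempotent.
#'
#' @param records Cohort data frame (non-empty) with columns `id`, `age`
#'   and (optionally) `icd10_codes`, `lipid_meds` as `";"`-separated
#'   strings.
#' @param rules An [eligibility_rules()].
#' @return A list with `eligible` (the retained rows) and
#'   `exclusion_log` (data frame of `id`, `reason` with reasons
#'   `"icd10"`, `"medication"`, `"age"`).
#' @export
apply_eligibility <- function(records, rules = eligibility_rules()) {
  stopifnot(inherits(rules, "eligibility_rules"))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("'records' must be a non-empty data frame")
  codes <- split_codes(records$icd10_codes %||% rep("", nrow(records)))
  meds <- split_codes(records$lipid_meds %||% rep("", nrow(records)))
  icd_hit <- vapply(codes, function(cs) {
    any(vapply(rules$excluded_icd10_prefixes,
               function(p) any(startsWith(cs, p)), logical(1)))
  }, logical(1))
  med_hit <- vapply(meds, function(ms) {
    any(tolower(ms) %in% rules$excluded_medications)
  }, logical(1))
  age_hit <- records$age < rules$age_min | records$age > rules$age_max
  reason <- rep(NA_character_, nrow(records))
  reason[age_hit] <- "age"
  reason[med_hit] <- "medication"
  reason[icd_hit] <- "icd10"     # highest priority written last
  excluded <- !is.na(reason)
  list(
    eligible = records[!excluded, , drop = FALSE],
    exclusion_log = data.frame(id = records$id[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE)
  )
}

#' Outcome-simulation specification
#'
#' Simulated endpoints follow `y ~ Bernoulli(expit(a + b * LP))` where
#' `LP` is the linear predictor of `true_model`. The drift pair
#' `(a, b) = (0, 1)` produces outcomes perfectly calibrated to the
#' model; other values embed a known calibration-in-the-large (`a`) and
#' calibration-slope (`b`) miscalibration, so that downstream recovery
#' of these quantities is testable.
#'
#' @param true_model A [logistic_model()] supplying the linear predictor.
#' @param drift_intercept Intercept drift `a`, log-odds units.
#' @param drift_slope Slope drift `b` (> 0), dimensionless.
#' @param seed Seed for the Bernoulli draws.
#' @return An object of class `outcome_sim_spec`.
#' @export
outcome_sim_spec <- function(true_model, drift_intercept = 0,
                             drift_slope = 1, seed = 1L) {
  stopifnot(inherits(true_model, "logistic_model"))
  if (!is.numeric(drift_slope) || drift_slope <= 0)
    stopf("invalid 'drift_slope': must be > 0")
  structure(
    list(true_model = true_model, drift_intercept = drift_intercept,
         drift_slope = drift_slope, endpoint = true_model$endpoint,
         seed = as.integer(seed)),
    class = "outcome_sim_spec"
  )
}

#' Simulate binary endpoints for a cohort
#'
#' Fills the endpoint column (`y_ldl` or `y_nonhdl`, by the true model's
#' endpoint) with Bernoulli draws at probability
#' `expit(drift_intercept + drift_slope * LP)`. Deterministic given
#' `sim$seed`.
#'
#' @param records Cohort data frame with the model's predictors.
#' @param sim An [outcome_sim_spec()].
#' @return `records` with the endpoint column added/overwritten.
#' @export
simulate_outcomes <- function(records, sim) {
  stopifnot(inherits(sim, "outcome_sim_spec"))
  lp <- linear_predictor(sim$true_model, records)
  p <- expit(sim$drift_intercept + sim$drift_slope * lp)
  set.seed(derive_seed(sim$seed, "outcomes"))
  y <- stats::rbinom(nrow(records), 1L, p)
  records[[paste0("y_", sim$endpoint)]] <- y
  records
}

#' Write / read a cohort as CSV
#'
#' One row per participant, UTF-8, `"."` decimal separator; list-valued
#' fields (`icd10_codes`, `lipid_meds`) are `";"`-separated strings.
#'
#' @param cohort Cohort data frame.
#' @param path Destination CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("icd10_codes", "lipid_meds"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  df
}
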