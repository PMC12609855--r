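compute_cal_metrics <- function(y, lp) {
  list(auroc = auroc(y, expit(lp)),
       c_slope = calibration_slope(y, lp),
       citl = citl(y, lp))
}

#' Case-mix-adjusted reference performance by outcome simulation
#'
#' Benchmarks the performance a model could at best attain in the
#' validation population if its coefficients transferred perfectly:
#' in each of `B` replications, participants are resampled with
#' replacement, outcomes are simulated from the model's own predicted
#' probabilities, and AuROC, C-slope and CITL are computed. Because the
#' simulated outcomes are calibrated to the model by construction, the
#' C-slope centers on 1 and the CITL on 0; the AuROC reflects the
#' case-mix (the spread of predicted risk) alone, independent of the
#' cohort's observed outcomes.
#'
#' @param cohort Cohort data frame with the model's predictors
#'   (observed outcomes, if present, are ignored).
#' @param model A [logistic_model()].
#' @param B Number of bootstrap replications (>= 100 for CI output).
#' @param seed Seed for resampling and outcome simulation.
#' @param seed_model Optional second model whose linear predictor is
#'   used to *simulate* the outcomes while `model` is the one being
#'   scored; defaults to `model` itself. This exposes the choice of
#'   which equation (original or updated) seeds the reference
#'   simulation.
#' @return An object of class `benchmark_result`: means and 2.5/97.5
#'   percentile CIs of the three metrics over replications, plus the
#'   count of degenerate replications skipped.
#' @export
casemix_reference <- function(cohort, model, B = 1000, seed = 1L,
                              seed_model = NULL) {
  stopifnot(inherits(model, "logistic_model"), B >= 1)
  seed_model <- seed_model %||% model
  n <- nrow(cohort)
  p_sim <- predicted_probability(seed_model, cohort)
  lp_score <- linear_predictor(model, cohort)
  set.seed(derive_seed(seed, "casemix"))
  draws <- matrix(NA_real_, nrow = B, ncol = 3,
                  dimnames = list(NULL, c("auroc", "c_slope", "citl")))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    ysim <- stats::rbinom(n, 1L, p_sim[idx])
    if (length(unique(ysim)) < 2L) { skipped <- skipped + 1L; next }
    m <- tryCatch(compute_cal_metrics(ysim, lp_score[idx]),
                  error = function(e) NULL)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    draws[b, ] <- c(m$auroc$value, m$c_slope$value, m$citl$value)
  }
  if (skipped > 0.10 * B)
    stopf("more than 10%% of replications were degenerate (%d of %d)",
          skipped, B)
  ok <- stats::complete.cases(draws)
  summarize <- function(col) {
    v <- draws[ok, col]
    if (B >= 100) {
      qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    } else {
      qs <- c(NA_real_, NA_real_)
    }
    metric_estimate(mean(v), stats::sd(v), min(qs[1], mean(v), na.rm = TRUE),
                    max(qs[2], mean(v), na.rm = TRUE),
                    method = "bootstrap_percentile")
  }
  structure(
    list(strategy = "casemix_reference",
         auroc = summarize("auroc"), c_slope = summarize("c_slope"),
         citl = summarize("citl"), B = B, skipped = skipped,
         seed = seed, n = n),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Case-mix reference values (B = %d, n = %d, %d skipped):\n",
              x$B, x$n, x$skipped))
  cat(sprintf("  AuROC   %s\n  C-slope %s\n  CITL    %s\n",
              format(x$auroc), format(x$c_slope), format(x$citl)))
  invisible(x)
}

strategy_row <- function(strategy, stage, auroc, c_slope, citl) {
  data.frame(strategy = strategy, stage = stage,
             auroc = auroc$value, auroc_low = auroc$ci_low,
             auroc_high = auroc$ci_high,
             c_slope = c_slope$value, c_slope_low = c_slope$ci_low,
             c_slope_high = c_slope$ci_high,
             citl = citl$value, citl_low = citl$ci_low,
             citl_high = citl$ci_high,
             stringsAsFactors = FALSE)
}

#' Strategy matrix of alternative validation benchmarks
#'
#' Runs, for one model on one labeled cohort, the validation strategies
#' reported side by side in the study: temporal validation (before the
#' update and after recalibration), the case-mix-adjusted reference
#' value (bootstrap outcome simulation, before/after), refitting in the
#' validation cohort (after stage only, by construction), and
#' validation with metabolic age replaced by its age/BMI/gender linear
#' estimate.
#'
#' @param cohort Labeled cohort data frame (endpoint column matching
#'   the model, plus `age`/`bmi` for the imputation row).
#' @param model A [logistic_model()].
#' @param B Bootstrap replications for the reference rows.
#' @param seed Seed for the bootstrap rows.
#' @return A data frame, one row per strategy/stage, with point
#'   estimates and 95% CI bounds for AuROC, C-slope and CITL.
#' @export
strategy_matrix <- function(cohort, model, B = 1000, seed = 1L) {
  stopifnot(inherits(model, "logistic_model"))
  ycol <- paste0("y_", model$endpoint)
  if (!ycol %in% names(cohort))
    stopf("cohort lacks endpoint column '%s'", ycol)
  y <- cohort[[ycol]]
  rec <- recalibrate(model, cohort, with_metrics = FALSE)
  updated <- rec$updated_model

  temporal <- function(mod, stage) {
    lp <- linear_predictor(mod, cohort)
    m <- compute_cal_metrics(y, lp)
    strategy_row("temporal", stage, m$auroc, m$c_slope, m$citl)
  }
  reference <- function(mod, stage) {
    bm <- casemix_reference(cohort, mod, B = B, seed = seed,
                            seed_model = mod)
    strategy_row("casemix_reference", stage, bm$auroc, bm$c_slope, bm$citl)
  }
  refit_row <- {
    rf <- refit(cohort, names(model$terms), endpoint = model$endpoint)
    lp <- linear_predictor(rf, cohort)
    m <- compute_cal_metrics(y, lp)
    strategy_row("refit", "after_recalibration", m$auroc, m$c_slope, m$citl)
  }
  imputed <- function(mod, stage) {
    co <- cohort
    co$metabolic_age <- impute_metabolic_age(co$age, co$bmi, co$male)
    lp <- linear_predictor(mod, co)
    m <- compute_cal_metrics(y, lp)
    strategy_row("imputed_metage", stage, m$auroc, m$c_slope, m$citl)
  }
  out <- rbind(
    temporal(model, "before_update"),
    temporal(updated, "after_recalibration"),
    reference(model, "before_update"),
    reference(updated, "after_recalibration"),
    refit_row,
    imputed(model, "before_update"),
    imputed(updated, "after_recalibration")
  )
  rownames(out) <- NULL
  out
}

#' Agreement of measured and estimated metabolic age
#'
#' Linear-calibration summary of observed (BIA-measured) metabolic age
#' against its age/BMI/gender linear estimate: R-squared, linear
#' calibration-in-the-large (mean of observed minus estimated, years)
#' and the calibration slope of observed on estimated.
#'
#' @param cohort Data frame with `metabolic_age`, `age`, `bmi`, `male`.
#' @return A list with `n`, `r_squared`, `citl`, `c_slope`.
#' @export
evaluate_imputation <- function(cohort) {
  for (col in c("metabolic_age", "age", "bmi", "male"))
    if (!col %in% names(cohort)) stopf("cohort lacks column '%s'", col)
  imputed <- impute_metabolic_age(cohort$age, cohort$bmi, cohort$male)
  if (stats::sd(imputed) < 1e-12)
    stopf("unidentifiable input: imputed metabolic age has zero variance")
  fit <- stats::lm(cohort$metabolic_age ~ imputed)
  list(
    n = nrow(cohort),
    r_squared = summary(fit)$r.squared,
    citl = mean(cohort$metabolic_age - imputed),
    c_slope = unname(stats::coef(fit)[2])
  )
}
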