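z975 <- function() stats::qnorm(0.975)

check_two_classes <- function(y) {
  if (!all(y %in% c(0, 1))) stopf("outcome must be coded 0/1")
  if (length(unique(y)) < 2L)
    stopf("degenerate input: both outcome classes must be present")
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Point estimate is the Mann-Whitney concordance: the probability that
#' a randomly chosen case carries a higher predicted risk than a
#' randomly chosen non-case, ties counting one half. The variance is
#' DeLong's, computed from midrank placements, with a Wald 95% CI
#' clipped to `[0, 1]`.
#'
#' @param y Binary outcome vector (0/1), both classes present.
#' @param p Predicted risks (any monotone score works; AuROC is
#'   invariant to strictly monotone transforms).
#' @return A [metric_estimate()].
#' @export
auroc <- function(y, p) {
  if (length(y) != length(p)) stopf("y and p must have equal length")
  check_two_classes(y)
  is_case <- y == 1
  m <- sum(is_case); n <- sum(!is_case)
  r_all <- rank(p, ties.method = "average")
  r_x <- rank(p[is_case], ties.method = "average")
  r_y <- rank(p[!is_case], ties.method = "average")
  # midrank placements (DeLong, via the rank identity)
  v10 <- (r_all[is_case] - r_x) / n
  v01 <- 1 - (r_all[!is_case] - r_y) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  metric_estimate(auc, se,
                  max(0, auc - z975() * se), min(1, auc + z975() * se),
                  method = "delong")
}

glm_or_error <- function(formula, data, what, offset = NULL) {
  if (!is.null(offset)) {
    data$.off <- offset
    formula <- stats::update(formula, . ~ . + offset(.off))
  }
  environment(formula) <- environment()
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!fit$converged)
    stopf("estimation error in %s: IRLS did not converge (n = %d, events = %d)",
          what, nrow(data), sum(data$y))
  mu <- stats::fitted(fit)
  separated <- all(mu[data$y == 1] > 1 - 1e-4) &&
    all(mu[data$y == 0] < 1e-4)
  if (separated || any(abs(stats::coef(fit)) > 30))
    stopf("estimation error in %s: data are (quasi-)separated, the MLE is not finite",
          what)
  fit
}

wald_metric <- function(fit, term, method = "wald") {
  est <- stats::coef(fit)[[term]]
  se <- sqrt(diag(stats::vcov(fit)))[[term]]
  metric_estimate(est, se, est - z975() * se, est + z975() * se,
                  method = method)
}

#' Calibration-in-the-large
#'
#' Maximum-likelihood intercept `a` of the binomial model
#' `logit P(y = 1) = a + LP`, with the linear predictor entering as a
#' fixed offset. `a = 0` means overall predicted risk matches overall
#' observed risk; negative values indicate overestimation. Wald CI.
#'
#' @param y Binary outcome vector (0/1).
#' @param lp Linear predictor (log-odds) from the model under validation.
#' @return A [metric_estimate()].
#' @export
citl <- function(y, lp) {
  if (length(y) != length(lp)) stopf("y and lp must have equal length")
  check_two_classes(y)
  d <- data.frame(y = y, lp = lp)
  fit <- glm_or_error(y ~ 1, d, "calibration-in-the-large", offset = d$lp)
  wald_metric(fit, "(Intercept)")
}

#' Calibration slope
#'
#' Slope `b` of the binomial model `logit P(y = 1) = a + b * LP`, with
#' the intercept re-estimated jointly. `b = 1` means the linear
#' predictor is correctly scaled; `b < 1` indicates predictions that are
#' too extreme (overestimation at high risk, underestimation at low
#' risk). Wald CI.
#'
#' @inheritParams citl
#' @return A [metric_estimate()].
#' @export
calibration_slope <- function(y, lp) {
  if (length(y) != length(lp)) stopf("y and lp must have equal length")
  check_two_classes(y)
  if (stats::sd(lp) < 1e-12)
    stopf("unidentifiable input: linear predictor is constant")
  d <- data.frame(y = y, lp = lp)
  fit <- glm_or_error(y ~ lp, d, "calibration slope")
  wald_metric(fit, "lp")
}

#' Expected-to-observed ratio
#'
#' `mean(p) / mean(y)`: total expected events over total observed
#' events. 1 means overall calibration; above 1, risk overestimation.
#' The CI uses the log-normal approximation with
#' `SE(ln E:O) = sqrt((1 - phi) / (n * phi))` where `phi` is the
#' observed prevalence.
#'
#' @param y Binary outcome vector with at least one event.
#' @param p Predicted risks in (0, 1).
#' @return A [metric_estimate()]; `se` is on the log scale.
#' @export
eo_ratio <- function(y, p) {
  if (length(y) != length(p)) stopf("y and p must have equal length")
  if (!all(y %in% c(0, 1))) stopf("outcome must be coded 0/1")
  if (sum(y) == 0) stopf("undefined ratio: no observed events")
  phi <- mean(y)
  eo <- mean(p) / phi
  se_ln <- sqrt((1 - phi) / (length(y) * phi))
  metric_estimate(eo, se_ln,
                  eo * exp(-z975() * se_ln), eo * exp(z975() * se_ln),
                  method = "lognormal")
}

#' Calibration curve
#'
#' Observed event proportion against predicted risk, either by
#' equal-count quantile bins (each point: mean predicted risk, event
#' rate, exact binomial CI) or by a local-linear loess smoother on the
#' probability scale.
#'
#' @inheritParams eo_ratio
#' @param smoother `"quantile_bins"` or `"loess"`.
#' @param bins Number of quantile bins (bins mode); requires
#'   `length(y) >= 10 * bins`.
#' @param span Loess span (loess mode).
#' @return A data frame of class `calibration_curve` with columns
#'   `predicted`, `observed`, `ci_low`, `ci_high` (and `n`, `events` in
#'   bins mode), sorted by predicted risk.
#' @export
calibration_curve <- function(y, p, smoother = c("quantile_bins", "loess"),
                              bins = 10, span = 0.75) {
  smoother <- match.arg(smoother)
  if (length(y) != length(p)) stopf("y and p must have equal length")
  if (smoother == "quantile_bins") {
    if (length(y) < 10 * bins)
      stopf("binning error: need at least %d records for %d bins",
            10 * bins, bins)
    ord <- order(p)
    grp <- rep(seq_len(bins), each = ceiling(length(y) / bins),
               length.out = length(y))
    pts <- do.call(rbind, lapply(split(seq_along(ord), grp), function(i) {
      ii <- ord[i]
      ev <- sum(y[ii])
      ci <- stats::binom.test(ev, length(ii))$conf.int
      data.frame(predicted = mean(p[ii]), observed = ev / length(ii),
                 ci_low = ci[1], ci_high = ci[2],
                 n = length(ii), events = ev)
    }))
    rownames(pts) <- NULL
    curve <- pts[order(pts$predicted), , drop = FALSE]
  } else {
    fit <- stats::loess(y ~ p, degree = 1, span = span)
    grid <- sort(unique(p))
    if (length(grid) > 200)
      grid <- stats::quantile(p, probs = seq(0, 1, length.out = 200),
                              names = FALSE)
    pr <- stats::predict(fit, newdata = data.frame(p = grid), se = TRUE)
    curve <- data.frame(
      predicted = grid,
      observed = pmin(pmax(pr$fit, 0), 1),
      ci_low = pmin(pmax(pr$fit - z975() * pr$se.fit, 0), 1),
      ci_high = pmin(pmax(pr$fit + z975() * pr$se.fit, 0), 1)
    )
  }
  attr(curve, "smoother") <- smoother
  attr(curve, "bin_count") <- if (smoother == "quantile_bins") bins else NA
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

# Discrimination wording after the usual logistic-regression textbook
# convention: 0.5 none, (0.5, 0.7] poor, (0.7, 0.8] acceptable,
# (0.8, 0.9] excellent, > 0.9 outstanding.
discrimination_label <- function(auc) {
  if (auc <= 0.5) "no discrimination"
  else if (auc <= 0.7) "poor"
  else if (auc <= 0.8) "acceptable"
  else if (auc <= 0.9) "excellent"
  else "outstanding"
}

#' Validate a model on a labeled cohort
#'
#' Computes the full external-validation report for one model on one
#' cohort: AuROC (DeLong CI), calibration slope, calibration-in-the-large,
#' E:O ratio and a calibration curve.
#'
#' @param model A [logistic_model()].
#' @param cohort Cohort data frame carrying the model's predictors and
#'   the endpoint column `y_ldl` / `y_nonhdl` matching the model.
#' @param smoother,bins Passed to [calibration_curve()].
#' @return An object of class `validation_report`.
#' @export
validate_model <- function(model, cohort, smoother = "quantile_bins",
                           bins = 10) {
  stopifnot(inherits(model, "logistic_model"))
  ycol <- paste0("y_", model$endpoint)
  if (!ycol %in% names(cohort))
    stopf("cohort lacks endpoint column '%s'", ycol)
  y <- cohort[[ycol]]
  lp <- linear_predictor(model, cohort)
  p <- expit(lp)
  rep <- list(
    model = model$name, endpoint = model$endpoint,
    n = length(y), events = sum(y), prevalence = mean(y),
    auroc = auroc(y, p),
    c_slope = calibration_slope(y, lp),
    citl = citl(y, lp),
    eo_ratio = eo_ratio(y, p),
    curve = calibration_curve(y, p, smoother = smoother, bins = bins)
  )
  rep$discrimination_label <- discrimination_label(rep$auroc$value)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation: %s\n", x$model))
  cat(sprintf("  n = %d, events = %d (prevalence %.1f%%)\n",
              x$n, x$events, 100 * x$prevalence))
  cat(sprintf("  AuROC  %s  (%s discrimination)\n",
              format(x$auroc), x$discrimination_label))
  cat(sprintf("  C-slope %s\n", format(x$c_slope)))
  cat(sprintf("  CITL    %s\n", format(x$citl)))
  cat(sprintf("  E:O     %s\n", format(x$eo_ratio)))
  invisible(x)
}
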