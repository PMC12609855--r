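#' Recalibrate a model on validation data
#'
#' Logistic recalibration: estimate `(alpha, beta)` in
#' `logit P(y = 1) = alpha + beta * LP` and fold them back into the
#' model, so updated coefficients are `beta * original` and the updated
#' intercept is `alpha + beta * intercept0`. By construction, joint
#' maximum likelihood forces the calibration slope to 1 and the CITL to
#' 0 when the updated model is re-assessed on the same data.
#'
#' @param model A [logistic_model()].
#' @param cohort Labeled cohort data frame (endpoint column matching the
#'   model).
#' @param method `"joint"` (default) fits intercept and slope together;
#'   `"sequential"` estimates the slope first, then the intercept with
#'   the rescaled linear predictor as offset. Sequential updating leaves
#'   a same-data slope slightly off 1, which is why it is exposed for
#'   sensitivity analyses.
#' @param with_metrics If `TRUE`, attach pre-/post-update
#'   [validate_model()] reports.
#' @return An object of class `recalibration_result` with elements
#'   `alpha`, `beta`, `updated_model`, and optionally `pre_metrics`,
#'   `post_metrics`.
#' @export
recalibrate <- function(model, cohort, method = c("joint", "sequential"),
                        with_metrics = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(model, "logistic_model"))
  ycol <- paste0("y_", model$endpoint)
  if (!ycol %in% names(cohort))
    stopf("cohort lacks endpoint column '%s'", ycol)
  y <- cohort[[ycol]]
  check_two_classes(y)
  lp <- linear_predictor(model, cohort)
  if (stats::sd(lp) < 1e-12)
    stopf("unidentifiable input: linear predictor is constant")
  d <- data.frame(y = y, lp = lp)
  if (method == "joint") {
    fit <- glm_or_error(y ~ lp, d, "recalibration")
    alpha <- stats::coef(fit)[["(Intercept)"]]
    beta <- stats::coef(fit)[["lp"]]
  } else {
    beta <- calibration_slope(y, lp)$value
    fit2 <- glm_or_error(y ~ 1, d, "recalibration intercept",
                         offset = beta * d$lp)
    alpha <- stats::coef(fit2)[["(Intercept)"]]
  }
  updated <- logistic_model(
    name = paste0(model$name, " [recalibrated]"),
    terms = beta * model$terms,
    intercept = alpha + beta * model$intercept,
    endpoint = model$endpoint, provenance = "user_supplied"
  )
  out <- list(alpha = alpha, beta = beta, method = method,
              updated_model = updated)
  if (with_metrics) {
    out$pre_metrics <- validate_model(model, cohort)
    out$post_metrics <- validate_model(updated, cohort)
  }
  class(out) <- "recalibration_result"
  out
}

#' @export
print.recalibration_result <- function(x, ...) {
  cat(sprintf("Recalibration (%s): alpha = %.4f, beta = %.4f\n",
              x$method, x$alpha, x$beta))
  cat(emit_equation(x$updated_model), "\n")
  invisible(x)
}

#' Refit a model from scratch on validation data
#'
#' Full maximum-likelihood binomial fit of the stated predictor terms,
#' reflecting both case-mix and any true shift in the regression
#' coefficients.
#'
#' @param cohort Labeled cohort data frame.
#' @param terms Character vector of predictor names (subset of
#'   `male`, `metabolic_age`, `dbp`).
#' @param endpoint `"ldl"` or `"nonhdl"`; selects the endpoint column.
#' @param name Name for the refitted model.
#' @return A [logistic_model()] with provenance `"user_supplied"`.
#' @export
refit <- function(cohort, terms, endpoint = c("ldl", "nonhdl"),
                  name = NULL) {
  endpoint <- match.arg(endpoint)
  ycol <- paste0("y_", endpoint)
  if (!ycol %in% names(cohort))
    stopf("cohort lacks endpoint column '%s'", ycol)
  missing <- setdiff(terms, names(cohort))
  if (length(missing) > 0)
    stopf("cohort lacks predictor(s): %s", paste(missing, collapse = ", "))
  y <- cohort[[ycol]]
  check_two_classes(y)
  if (nrow(cohort) <= 10 * length(terms))
    stopf("refit needs n > 10 x number of terms (n = %d, terms = %d)",
          nrow(cohort), length(terms))
  for (tm in terms)
    if (stats::sd(cohort[[tm]]) < 1e-12)
      stopf("unidentifiable input: predictor '%s' has zero variance", tm)
  d <- cbind(data.frame(y = y), cohort[terms])
  fit <- glm_or_error(
    stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
    d, "refit")
  cf <- stats::coef(fit)
  logistic_model(
    name = name %||% sprintf("refitted %s model", endpoint),
    terms = cf[terms],
    intercept = cf[["(Intercept)"]],
    endpoint = endpoint, provenance = "user_supplied"
  )
}

#' Render a model as a prediction equation
#'
#' Deterministic plain-text rendering in the published layout,
#' `p = e^L / (1 + e^L)` with the linear predictor written out at four
#' decimals (explicit sign on every term).
#'
#' @param model A [logistic_model()].
#' @return A single string.
#' @export
emit_equation <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  pretty <- c(male = "(male)", metabolic_age = "(metabolic age (years))",
              dbp = "(DBP (mmHg))")
  parts <- sprintf("%+.4f*%s", model$terms,
                   pretty[names(model$terms)])
  lp <- paste0(paste(parts, collapse = ""), sprintf("%+.4f", model$intercept))
  lp <- sub("^\\+", "", lp)
  sprintf("Predicted probability of %s = e^(%s) / (1 + e^(%s))",
          model$name, lp, lp)
}
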