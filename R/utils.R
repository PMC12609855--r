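#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Numerically stable inverse logit: branch on sign so exp() never overflows
# (|x| > 700 would otherwise return Inf/Inf).
expit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos & !is.na(x)])
  out[!pos & !is.na(x)] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

logit <- function(p) log(p) - log1p(-p)

# Probabilities are clipped before logit so degenerate inputs (0 or 1)
# produce large finite log-odds instead of infinities.
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Construct a metric estimate
#'
#' A light container for a point estimate with its standard error and
#' 95% confidence interval, used for AuROC, calibration slope,
#' calibration-in-the-large and the E:O ratio.
#'
#' @param value Point estimate.
#' @param se Standard error (on the estimation scale; `NA` if unavailable).
#' @param ci_low,ci_high 95% confidence limits.
#' @param method Short label for the estimator (e.g. `"delong"`, `"wald"`).
#' @return An object of class `metric_estimate`.
#' @export
metric_estimate <- function(value, se, ci_low, ci_high, method = "") {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.na(se) && se < 0) stop("standard error must be non-negative")
  if (!any(is.na(c(ci_low, value, ci_high))) &&
      !(ci_low <= value && value <= ci_high)) {
    stop("confidence interval must bracket the point estimate")
  }
  structure(
    list(value = value, se = se, ci_low = ci_low, ci_high = ci_high,
         method = method),
    class = "metric_estimate"
  )
}

#' @export
print.metric_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s (95%% CI %s, %s) [%s]\n",
              format(round(x$value, digits), nsmall = digits),
              format(round(x$ci_low, digits), nsmall = digits),
              format(round(x$ci_high, digits), nsmall = digits),
              x$method))
  invisible(x)
}

#' @export
format.metric_estimate <- function(x, digits = 2, ...) {
  sprintf("%.*f (%.*f, %.*f)", digits, x$value, digits, x$ci_low,
          digits, x$ci_high)
}

# One root seed per run; each stochastic stage draws from its own child
# stream so inserting a stage never perturbs the draws of another.
# Child seed = (root * 2654435761 + stage hash) mod 2^31 - 1 (Knuth
# multiplicative hashing; stage hash from the stage label's UTF-8 bytes).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 65536 * 40503 + h * 9973 + abs(seed)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
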