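#' Define a subgroup scheme for fairness assessment
#'
#' @param covariate Column name in the cohort.
#' @param scheme `"categories"` uses the values as-is, `"tertiles"`
#'   cuts a continuous covariate at its sample tertiles, and
#'   `"custom_cuts"` cuts at user thresholds.
#' @param cuts Numeric thresholds (custom_cuts only).
#' @param labels Optional subgroup labels.
#' @return An object of class `subgroup_definition`.
#' @export
subgroup_definition <- function(covariate,
                                scheme = c("categories", "tertiles",
                                           "custom_cuts"),
                                cuts = NULL, labels = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "custom_cuts" && (is.null(cuts) || length(cuts) < 1))
    stopf("custom_cuts scheme needs at least one threshold")
  structure(list(covariate = covariate, scheme = scheme, cuts = cuts,
                 labels = labels),
            class = "subgroup_definition")
}

# Build the subgroup factor for one definition; every record is
# assigned (the subgroups partition the cohort).
make_subgroups <- function(cohort, def) {
  stopifnot(inherits(def, "subgroup_definition"))
  if (!def$covariate %in% names(cohort))
    stopf("cohort lacks covariate '%s'", def$covariate)
  x <- cohort[[def$covariate]]
  if (def$scheme == "categories") {
    f <- factor(x)
    if (!is.null(def$labels)) levels(f) <- def$labels
    return(f)
  }
  cuts <- if (def$scheme == "tertiles") {
    stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
  } else {
    def$cuts
  }
  breaks <- unique(c(-Inf, cuts, Inf))
  f <- cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE)
  if (!is.null(def$labels) && length(def$labels) == nlevels(f))
    levels(f) <- def$labels
  else if (def$scheme == "tertiles" && nlevels(f) == 3L)
    levels(f) <- c("lower", "middle", "upper")
  f
}

#' Subgroup-specific AuROC
#'
#' The covariate-conditional ROC: AuROC computed within each subgroup
#' independently (conditioning, never pooling across subgroups).
#' Subgroups where only one outcome class is present are returned as
#' flagged rows with `NA` estimates rather than dropped.
#'
#' @param y Binary outcome vector.
#' @param p Predicted risks.
#' @param groups Factor (or coercible) of subgroup membership.
#' @return Data frame with one row per subgroup: `subgroup`, `n`,
#'   `events`, `auroc`, `auroc_low`, `auroc_high`, `flag`.
#' @export
subgroup_auroc <- function(y, p, groups) {
  groups <- as.factor(groups)
  stopifnot(length(y) == length(p), length(y) == length(groups))
  out <- lapply(levels(groups), function(g) {
    i <- groups == g
    row <- data.frame(subgroup = g, n = sum(i), events = sum(y[i]),
                      auroc = NA_real_, auroc_low = NA_real_,
                      auroc_high = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    est <- tryCatch(auroc(y[i], p[i]), error = function(e) NULL)
    if (is.null(est)) {
      row$flag <- "single_class"
    } else {
      row$auroc <- est$value
      row$auroc_low <- est$ci_low
      row$auroc_high <- est$ci_high
    }
    row
  })
  do.call(rbind, out)
}

#' Subgroup calibration slope and CITL
#'
#' Fits the pooled binomial model with saturated effect modification,
#' `logit P(y=1) = sum_g 1[g] * (a_g + b_g * LP)`, so each subgroup
#' receives its own intercept and slope; estimates coincide with
#' separate per-group fits. `CITL_g` is additionally computed as the
#' offset-model intercept within the subgroup (the usual definition,
#' i.e. with slope fixed at 1).
#'
#' @param y Binary outcome vector.
#' @param lp Linear predictor (log-odds).
#' @param groups Factor of subgroup membership.
#' @return Data frame with one row per subgroup: `subgroup`, `n`,
#'   `events`, `c_slope` (+ CI), `citl` (+ CI), `flag`.
#' @export
subgroup_calibration <- function(y, lp, groups) {
  groups <- as.factor(groups)
  stopifnot(length(y) == length(lp), length(y) == length(groups))
  d <- data.frame(y = y, lp = lp, g = groups)
  form <- if (nlevels(groups) > 1L) y ~ 0 + g + g:lp else y ~ lp
  fit <- withCallingHandlers(
    stats::glm(form, data = d, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- lapply(levels(groups), function(g) {
    i <- groups == g
    slope_nm <- if (nlevels(groups) > 1L) paste0("g", g, ":lp") else "lp"
    row <- data.frame(subgroup = g, n = sum(i), events = sum(y[i]),
                      c_slope = NA_real_, c_slope_low = NA_real_,
                      c_slope_high = NA_real_, citl = NA_real_,
                      citl_low = NA_real_, citl_high = NA_real_,
                      flag = "", stringsAsFactors = FALSE)
    b <- cf[[slope_nm]]; sb <- se[[slope_nm]]
    ok <- is.finite(b) && is.finite(sb) && abs(b) < 30 && sb < 100
    ci <- tryCatch(citl(y[i], lp[i]), error = function(e) NULL)
    if (!ok || is.null(ci)) {
      row$flag <- "unstable_or_separated"
      return(row)
    }
    row$c_slope <- b
    row$c_slope_low <- b - z975() * sb
    row$c_slope_high <- b + z975() * sb
    row$citl <- ci$value
    row$citl_low <- ci$ci_low
    row$citl_high <- ci$ci_high
    row
  })
  do.call(rbind, out)
}

default_fairness_definitions <- function(cohort) {
  defs <- list(subgroup_definition("male", "categories",
                                   labels = c("female", "male")),
               subgroup_definition("age", "tertiles"),
               subgroup_definition("bmi", "tertiles"),
               subgroup_definition("metabolic_age", "tertiles"),
               subgroup_definition("dbp", "tertiles"),
               subgroup_definition("isco_code", "categories"))
  optional <- c("fat_pct", "muscle_pct", "waist_to_height")
  present <- intersect(optional, names(cohort))
  for (cov in present)
    defs <- c(defs, list(subgroup_definition(cov, "tertiles")))
  absent <- setdiff(optional, names(cohort))
  if (length(absent) > 0)
    warning(sprintf("derived covariate(s) not present, omitted: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  defs
}

#' Fairness report: subgroup heterogeneity of model performance
#'
#' Computes AuROC, calibration slope and CITL within subgroups defined
#' over participant characteristics. Continuous covariates default to
#' tertiles; ISCO occupation codes are handled as the 10 major-group
#' categories. Subgroups with fewer than 20 participants or fewer than
#' 5 events are flagged (`"small_subgroup"`) because their Wald CIs are
#' unstable; single-class subgroups are flagged, never silently
#' dropped.
#'
#' @param cohort Labeled cohort data frame.
#' @param model A [logistic_model()].
#' @param definitions List of [subgroup_definition()]s; defaults to
#'   gender, age, BMI, metabolic age and DBP tertiles plus ISCO
#'   categories, and fat/muscle percentage and waist-to-height ratio
#'   when those columns exist.
#' @return A data frame of class `fairness_table`, one row per
#'   subgroup, with the covariate, the subgroup cut labels and the
#'   three metrics with CIs.
#' @export
fairness_report <- function(cohort, model, definitions = NULL) {
  stopifnot(inherits(model, "logistic_model"))
  ycol <- paste0("y_", model$endpoint)
  if (!ycol %in% names(cohort))
    stopf("cohort lacks endpoint column '%s'", ycol)
  definitions <- definitions %||% default_fairness_definitions(cohort)
  y <- cohort[[ycol]]
  lp <- linear_predictor(model, cohort)
  p <- expit(lp)
  tables <- lapply(definitions, function(def) {
    g <- make_subgroups(cohort, def)
    a <- subgroup_auroc(y, p, g)
    cal <- subgroup_calibration(y, lp, g)
    tab <- cbind(data.frame(covariate = def$covariate,
                            stringsAsFactors = FALSE),
                 a[, c("subgroup", "n", "events", "auroc", "auroc_low",
                       "auroc_high")],
                 cal[, c("c_slope", "c_slope_low", "c_slope_high",
                         "citl", "citl_low", "citl_high")])
    tab$flag <- ifelse(nzchar(a$flag) | nzchar(cal$flag),
                       paste(a$flag, cal$flag, sep = ";"),
                       ifelse(tab$n < 20 | tab$events < 5,
                              "small_subgroup", ""))
    tab
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  class(out) <- c("fairness_table", "data.frame")
  out
}
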