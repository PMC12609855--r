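#' Define a logistic prediction model
#'
#' A logistic model is a named set of log-odds coefficients plus an
#' intercept. The linear predictor is `intercept + sum(coef * value)` and
#' the predicted probability its inverse logit. Allowed predictor names
#' are `male` (1 = male, 0 = female), `metabolic_age` (years) and
#' `dbp` (mmHg).
#'
#' @param name Model label.
#' @param terms Named numeric vector of coefficients (log-odds per unit).
#' @param intercept Intercept on the log-odds scale.
#' @param endpoint `"ldl"` or `"nonhdl"` — which 160 mg/dL endpoint the
#'   model predicts.
#' @param provenance `"updated_eq1"`, `"updated_eq2"` or `"user_supplied"`.
#' @return An object of class `logistic_model`.
#' @seealso [ldl_model()], [nonhdl_model()] for the shipped updated
#'   equations; [linear_predictor()], [predicted_probability()].
#' @export
logistic_model <- function(name, terms, intercept,
                           endpoint = c("ldl", "nonhdl"),
                           provenance = c("user_supplied", "updated_eq1",
                                          "updated_eq2")) {
  endpoint <- match.arg(endpoint)
  provenance <- match.arg(provenance)
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stopf("model terms must be a named numeric vector")
  allowed <- c("male", "metabolic_age", "dbp")
  bad <- setdiff(names(terms), allowed)
  if (length(bad) > 0)
    stopf("unknown predictor(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  if (any(!is.finite(terms)) || !is.finite(intercept))
    stopf("coefficients and intercept must be finite")
  structure(
    list(name = name, terms = terms, intercept = unname(intercept),
         endpoint = endpoint, provenance = provenance),
    class = "logistic_model"
  )
}

#' Updated elevated LDL-C screening model
#'
#' Diagnostic logistic model for elevated LDL-C (>= 160 mg/dL) in adults
#' aged 20-40, with predictors gender and metabolic age, after temporal
#' recalibration.
#'
#' @return A `logistic_model`.
#' @export
ldl_model <- function() {
  logistic_model(
    name = "elevated LDL-C (updated)",
    terms = c(male = 0.5542, metabolic_age = 0.0155),
    intercept = -2.6091,
    endpoint = "ldl",
    provenance = "updated_eq1"
  )
}

#' Updated elevated non-HDL-C screening model
#'
#' Diagnostic logistic model for elevated non-HDL-C (>= 160 mg/dL) with
#' predictors gender, metabolic age and diastolic blood pressure, after
#' temporal recalibration.
#'
#' @return A `logistic_model`.
#' @export
nonhdl_model <- function() {
  logistic_model(
    name = "elevated non-HDL-C (updated)",
    terms = c(male = 0.9008, metabolic_age = 0.0294, dbp = 0.0100),
    intercept = -3.1255,
    endpoint = "nonhdl",
    provenance = "updated_eq2"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model: %s [endpoint: %s, provenance: %s]\n",
              x$name, x$endpoint, x$provenance))
  cat(emit_equation(x), "\n")
  invisible(x)
}

check_predictors <- function(model, records) {
  need <- names(model$terms)
  missing <- setdiff(need, names(records))
  if (length(missing) > 0)
    stopf("records lack predictor(s) required by model '%s': %s",
          model$name, paste(missing, collapse = ", "))
  if ("male" %in% need) {
    m <- records[["male"]]
    if (!all(m %in% c(0, 1)))
      stopf("'male' must be coded 0 (female) / 1 (male); found other values")
  }
  invisible(TRUE)
}

#' Linear predictor of a logistic model
#'
#' Computes `intercept + sum(coef * predictor)` for each record. A linear
#' predictor of 0 corresponds to a predicted probability of 0.5.
#'
#' @param model A [logistic_model()].
#' @param records Data frame with one row per participant, containing all
#'   predictors the model uses.
#' @return Numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(model, records) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.list(records) && !is.data.frame(records))
    records <- as.data.frame(records)
  check_predictors(model, records)
  X <- as.matrix(records[names(model$terms)])
  storage.mode(X) <- "double"
  drop(X %*% model$terms) + model$intercept
}

#' Predicted probability of the endpoint
#'
#' Inverse logit of [linear_predictor()], computed with an
#' overflow-safe branch so extreme log-odds stay strictly inside (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predicted_probability <- function(model, records) {
  expit(linear_predictor(model, records))
}

#' Metabolic-age proxy from age, BMI and gender
#'
#' Linear estimate of BIA-derived metabolic age for settings without a
#' body-composition analyzer:
#' `0.541*age + 2.394*bmi - 7.326*male - 39.156` (years). The output is
#' deliberately not clamped and can be negative for extreme inputs.
#'
#' @param age Age in years (> 0).
#' @param bmi Body mass index in kg/m^2 (> 0).
#' @param male 1 = male, 0 = female.
#' @return Estimated metabolic age in years.
#' @export
impute_metabolic_age <- function(age, bmi, male) {
  if (any(age <= 0) || any(bmi <= 0))
    stopf("age and bmi must be positive")
  if (!all(male %in% c(0, 1)))
    stopf("'male' must be coded 0/1")
  0.541 * age + 2.394 * bmi - 7.326 * male - 39.156
}

#' Read a model definition from JSON or YAML
#'
#' The file must carry keys `name`, `endpoint` (`ldl`/`nonhdl`),
#' `intercept` (number) and `terms` (map predictor -> coefficient).
#' Example files for both shipped equations live under
#' `system.file("extdata", package = "lipidval")`.
#'
#' @param path File path; format chosen by extension
#'   (`.json` vs `.yml`/`.yaml`).
#' @return A `logistic_model` with provenance `"user_supplied"`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stopf("unsupported model file extension '.%s' (use .json/.yaml)", ext)
  )
  need <- c("name", "endpoint", "intercept", "terms")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0)
    stopf("model file %s lacks key(s): %s", path,
          paste(missing, collapse = ", "))
  terms <- unlist(obj$terms)
  logistic_model(obj$name, terms, as.numeric(obj$intercept),
                 endpoint = obj$endpoint, provenance = "user_supplied")
}

#' Write a model definition to JSON or YAML
#'
#' @param model A `logistic_model`.
#' @param path Destination path (`.json`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  obj <- list(name = model$name, endpoint = model$endpoint,
              intercept = model$intercept, terms = as.list(model$terms))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(obj, path)
  } else {
    stopf("unsupported model file extension '.%s'", ext)
  }
  invisible(path)
}
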