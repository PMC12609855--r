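metric_to_list <- function(m) {
  list(value = m$value, se = m$se, ci_low = m$ci_low, ci_high = m$ci_high,
       method = m$method)
}

report_to_list <- function(rep) {
  list(model = rep$model, endpoint = rep$endpoint, n = rep$n,
       events = rep$events, prevalence = rep$prevalence,
       discrimination = rep$discrimination_label,
       auroc = metric_to_list(rep$auroc),
       c_slope = metric_to_list(rep$c_slope),
       citl = metric_to_list(rep$citl),
       eo_ratio = metric_to_list(rep$eo_ratio))
}

resolve_model <- function(model) {
  if (inherits(model, "logistic_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    if (model == "ldl") return(ldl_model())
    if (model == "nonhdl") return(nonhdl_model())
    return(read_model(model))
  }
  if (is.list(model) && !is.null(model$file)) return(read_model(model$file))
  stopf("cannot resolve model from config (use 'ldl', 'nonhdl', or a file path)")
}

#' Demo study configuration
#'
#' A self-contained configuration for [run_validation()]: a synthetic
#' cohort of 1099 participants with the validation-wave marginals,
#' outcomes simulated from the non-HDL-C equation with injected
#' miscalibration (intercept drift -0.07, slope drift 0.71 — the regime
#' the temporal validation observed), followed by recalibration,
#' decision-curve analysis, sizing, benchmarking and fairness stages.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Root seed.
#' @return A named list accepted by [run_validation()].
#' @export
demo_config <- function(out_dir = tempfile("lipidval_demo_"), seed = 1L) {
  list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(spec = list(n = 1099)),
    model = "nonhdl",
    simulate = list(drift_intercept = -0.07, drift_slope = 0.71),
    recalibrate = list(method = "joint"),
    dca = list(grid_min = 0.01, grid_max = 0.60, grid_step = 0.01),
    samplesize = "nonhdl",
    benchmark = list(B = 200),
    fairness = TRUE,
    figures = FALSE
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  config
}

#' Run the full temporal-validation pipeline
#'
#' Orchestrates cohort load/synthesis, eligibility filtering, risk
#' scoring, performance assessment, recalibration, decision-curve
#' analysis, sample-size calculation, benchmarking strategies and the
#' fairness report, from a single configuration. Every table is written
#' to `out_dir` as CSV/JSON, a manifest with MD5 checksums lists the
#' artifacts, and the run is fully reproducible from the config and its
#' root seed.
#'
#' @param config Named list or YAML file path; see [demo_config()] for
#'   the accepted keys.
#' @return Invisibly, a list (`report_bundle`) holding every computed
#'   object plus the paths of the written artifacts.
#' @export
run_validation <- function(config) {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stopf("config lacks 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, file, writer = utils::write.csv) {
    path <- file.path(out_dir, file)
    if (identical(writer, utils::write.csv))
      utils::write.csv(obj, path, row.names = FALSE)
    else writer(obj, path)
    paths[[length(paths) + 1L]] <<- path
    path
  }
  emit_json <- function(obj, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths[[length(paths) + 1L]] <<- path
    path
  }

  ## cohort: load or synthesize
  if (!is.null(config$cohort$file)) {
    if (!file.exists(config$cohort$file))
      stopf("cohort file not found: %s", config$cohort$file)
    cohort <- read_cohort(config$cohort$file)
  } else {
    args <- config$cohort$spec %||% list()
    args$seed <- args$seed %||% derive_seed(seed, "spec")
    spec <- do.call(cohort_spec, args)
    cohort <- generate_cohort(spec)
  }
  elig <- apply_eligibility(cohort)
  cohort <- elig$eligible
  emit(elig$exclusion_log, "exclusion_log.csv")

  model <- resolve_model(config$model %||% "nonhdl")
  ycol <- paste0("y_", model$endpoint)
  if (!ycol %in% names(cohort)) {
    drift <- config$simulate %||% list()
    sim <- outcome_sim_spec(
      model,
      drift_intercept = drift$drift_intercept %||% 0,
      drift_slope = drift$drift_slope %||% 1,
      seed = derive_seed(seed, "sim"))
    cohort <- simulate_outcomes(cohort, sim)
  }
  emit(cohort, "cohort.csv")

  bundle <- list(cohort = cohort, model = model,
                 exclusion_log = elig$exclusion_log)

  ## performance + recalibration
  rec <- recalibrate(model, cohort,
                     method = (config$recalibrate$method %||% "joint"))
  bundle$recalibration <- rec
  emit_json(list(alpha = rec$alpha, beta = rec$beta, method = rec$method),
            "recalibration.json")
  emit_json(report_to_list(rec$pre_metrics), "validation_before.json")
  emit_json(report_to_list(rec$post_metrics), "validation_after.json")
  emit(as.data.frame(rec$pre_metrics$curve), "calibration_curve_before.csv")
  emit(as.data.frame(rec$post_metrics$curve), "calibration_curve_after.csv")
  path_model <- file.path(out_dir, "updated_model.json")
  write_model(rec$updated_model, path_model)
  paths[[length(paths) + 1L]] <- path_model
  writeLines(c(emit_equation(model), emit_equation(rec$updated_model)),
             file.path(out_dir, "equations.txt"))
  paths[[length(paths) + 1L]] <- file.path(out_dir, "equations.txt")

  ## decision curves (before and after update)
  g <- config$dca %||% list()
  grid <- seq(g$grid_min %||% 0.01, g$grid_max %||% 0.60,
              by = g$grid_step %||% 0.01)
  y <- cohort[[ycol]]
  dc_before <- decision_curve(y, predicted_probability(model, cohort), grid)
  dc_after <- decision_curve(
    y, predicted_probability(rec$updated_model, cohort), grid)
  bundle$decision_curves <- list(before = dc_before, after = dc_after)
  emit(as.data.frame(dc_before), "decision_curve_before.csv")
  emit(as.data.frame(dc_after), "decision_curve_after.csv")

  ## sample size
  if (!is.null(config$samplesize)) {
    ss_spec <- if (identical(config$samplesize, "ldl")) {
      samplesize_spec_ldl()
    } else if (identical(config$samplesize, "nonhdl")) {
      samplesize_spec_nonhdl()
    } else {
      do.call(samplesize_spec, config$samplesize)
    }
    ss <- validation_sample_size(ss_spec)
    bundle$samplesize <- ss
    emit_json(list(n_cstat = ss$n_cstat, n_slope = ss$n_slope,
                   n_oe = ss$n_oe, n_required = ss$n_required),
              "samplesize.json")
  }

  ## benchmarking strategies
  if (!is.null(config$benchmark)) {
    sm <- strategy_matrix(cohort, model,
                          B = config$benchmark$B %||% 1000,
                          seed = derive_seed(seed, "benchmark"))
    bundle$strategy_matrix <- sm
    emit(sm, "strategy_matrix.csv")
  }

  ## fairness
  if (isTRUE(config$fairness)) {
    ft <- fairness_report(cohort, model)
    bundle$fairness <- ft
    emit(as.data.frame(ft), "fairness.csv")
  }

  ## figures
  if (isTRUE(config$figures)) {
    figs <- list(
      roc = plot_roc(y, predicted_probability(rec$updated_model, cohort)),
      calibration = plot_calibration(rec$post_metrics),
      net_benefit = plot_decision_curve(dc_after, "net_benefit"),
      net_reduction = plot_decision_curve(dc_after, "net_reduction")
    )
    for (nm in names(figs)) {
      path <- file.path(out_dir, paste0(nm, ".png"))
      ggplot2::ggsave(path, figs[[nm]], width = 6, height = 5, dpi = 150)
      paths[[length(paths) + 1L]] <- path
    }
  }

  ## run metadata + manifest
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, force = TRUE)
  emit_json(list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("lipidval")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  ), "run_metadata.json")
  unlink(cfg_file)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  bundle$manifest <- manifest
  bundle$out_dir <- out_dir
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

#' Descriptive comparison of two cohorts
#'
#' Mean (SD) with independent-sample t-tests (or Wilcoxon rank-sum
#' where declared) for continuous columns, count (%) with Fisher's
#' exact test for categorical/binary columns; p < 0.05 flagged.
#'
#' @param cohort_a,cohort_b Data frames sharing at least one column.
#' @param tests Optional named character vector declaring the test per
#'   variable (`"t"`, `"wilcoxon"` or `"fisher"`); undeclared continuous
#'   variables default to the t-test, categorical to Fisher.
#' @param labels Length-2 labels for the two cohorts.
#' @return A data frame, one row per shared variable, with the summary
#'   of each cohort, the test used, the p-value and a significance flag.
#' @export
describe_cohorts <- function(cohort_a, cohort_b, tests = NULL,
                             labels = c("cohort_a", "cohort_b")) {
  shared <- intersect(names(cohort_a), names(cohort_b))
  shared <- setdiff(shared, "id")
  if (length(shared) == 0L) stopf("cohorts share no columns to compare")
  rows <- lapply(shared, function(v) {
    xa <- cohort_a[[v]]; xb <- cohort_b[[v]]
    categorical <- is.character(xa) || is.factor(xa) ||
      all(stats::na.omit(c(xa, xb)) %in% c(0, 1))
    test <- tests[v]
    if (is.null(test) || is.na(test)) test <- if (categorical) "fisher" else "t"
    if (categorical) {
      tab <- table(factor(rep(labels, c(length(xa), length(xb)))),
                   c(as.character(xa), as.character(xb)))
      pv <- if (ncol(tab) < 2L) {
        1   # no variation in the pooled variable
      } else {
        tryCatch(stats::fisher.test(tab)$p.value,
                 error = function(e) {
                   set.seed(20240318L)
                   stats::fisher.test(tab, simulate.p.value = TRUE,
                                      B = 10000)$p.value
                 })
      }
      summ_a <- if (is.numeric(xa))
        sprintf("%d (%.1f%%)", sum(xa), 100 * mean(xa)) else
          sprintf("%d levels", length(unique(xa)))
      summ_b <- if (is.numeric(xb))
        sprintf("%d (%.1f%%)", sum(xb), 100 * mean(xb)) else
          sprintf("%d levels", length(unique(xb)))
    } else {
      pv <- if (test == "wilcoxon") {
        stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      } else {
        test <- "t"
        tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
        if (is.null(tt)) 1 else tt$p.value
      }
      summ_a <- sprintf("%.1f (%.1f)", mean(xa), stats::sd(xa))
      summ_b <- sprintf("%.1f (%.1f)", mean(xb), stats::sd(xb))
    }
    if (is.na(pv)) pv <- 1   # zero-variance identical columns
    data.frame(variable = v, summary_a = summ_a, summary_b = summ_b,
               test = if (categorical) "fisher" else test, p_value = pv,
               significant = pv < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("summary_", make.names(labels))
  out
}
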