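#' Analysis pipeline
#'
#' Orchestrates the full chain — generate or load a cohort, score
#' cerebrovascular risk, preprocess, fit the structural model with nested
#' comparisons, compute sliding-window curves, the risk-factor regression
#' and mediation — from a single configuration, writing per-stage TSV/JSON
#' artifacts plus a run manifest.
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' @param input Path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param generator [cohort_params()] used when `input` is NULL.
#' @param stages Character vector of stages to run, in order. Any of
#'   `"score"`, `"preprocess"`, `"sem"`, `"window"`, `"regression"`,
#'   `"mediation"`.
#' @param sem_spec_path Optional JSON/YAML model specification; defaults to
#'   [fp_sem_spec()].
#' @param estimator `"ML"` or `"FIML"`.
#' @param window List: `frac`, `step_quantile`, `kernel`, `n_bins`, `width`.
#' @param strata Optional stratification column for window curves (e.g.
#'   `"on_bp_medication"`); `age_split` adds a mid-/late-life split at the
#'   given age.
#' @param output_dir Directory for artifacts.
#' @param seed Mandatory when any stochastic stage is enabled.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = cohort_params(),
                            stages = c("score", "preprocess", "sem",
                                       "window", "regression", "mediation"),
                            sem_spec_path = NULL,
                            estimator = "ML",
                            window = list(frac = 0.10, step_quantile = 0.01,
                                          kernel = 10, n_bins = 10,
                                          width = 16),
                            strata = "on_bp_medication", age_split = 70,
                            output_dir = tempfile("cvrsem_run_"),
                            seed = NULL) {
  bad <- setdiff(stages, c("score", "preprocess", "sem", "window",
                           "regression", "mediation"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(input) && is.null(seed))
    stop("a seed is required when the cohort is simulated")
  structure(list(input = input, generator = generator, stages = stages,
                 sem_spec_path = sem_spec_path, estimator = estimator,
                 window = window, strata = strata, age_split = age_split,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Configuration file. Fields mirror [pipeline_config()]
#'   arguments; `generator` entries override [cohort_params()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- cohort_params(n = obj$generator$n %||% NULL)
  args <- obj[setdiff(names(obj), "generator")]
  args$generator <- gen
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Deterministic given (input, config, seed). Every stage writes its
#' artifacts into `config$output_dir` and registers them in the manifest
#' (`manifest.json`, with MD5 hashes). A failing stage aborts with a
#' stage-named error; artifacts of completed stages are retained alongside
#' a failure marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, analysis table, fits and
#'   curve tables; also written to disk.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), seed = config$seed)
  artifacts <- character(0)
  results <- list()
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      status = "ok",
      files = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    artifacts <<- c(artifacts, files)
  }
  out_path <- function(...) file.path(config$output_dir, ...)
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("failed at stage: ", stage, "\n", conditionMessage(e)),
                 out_path("FAILED"))
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, out_path("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # input ---------------------------------------------------------------
  cohort <- run_stage("input", function() {
    if (!is.null(config$input)) {
      sep <- if (grepl("\\.tsv$", config$input)) "\t" else ","
      utils::read.table(config$input, header = TRUE, sep = sep,
                        stringsAsFactors = FALSE)
    } else {
      co <- generate_cohort(config$generator, seed = config$seed)
      write_cohort(co, out_path("cohort.csv"))
      co
    }
  })
  if (is.null(config$input))
    note("input", c(out_path("cohort.csv"),
                    out_path("cohort_provenance.json")))
  else manifest$stages[["input"]] <- list(
    status = "ok", files = list(list(path = config$input,
                                     md5 = unname(tools::md5sum(config$input)))))
  results$cohort <- cohort

  run_stage("validate", function() {
    if ("window" %in% config$stages && !is.null(config$strata) &&
        !config$strata %in% names(cohort))
      stop("stratification column '", config$strata,
           "' not found in the input table")
    invisible(NULL)
  })

  for (stage in config$stages) {
    if (stage == "score") run_stage("score", function() {
      br <- score_cohort(cohort)
      write_cvr_breakdown(cbind(id = cohort$id, br),
                          out_path("cvr_breakdown.tsv"))
      note("score", out_path("cvr_breakdown.tsv"))
      results$cvr <<- br
    })
    if (stage == "preprocess") run_stage("preprocess", function() {
      analysis <- prepare_analysis_table(cohort)
      utils::write.table(analysis, out_path("analysis_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_normalization_sidecar(analysis, out_path("normalization.json"))
      note("preprocess", c(out_path("analysis_table.tsv"),
                           out_path("normalization.json")))
      results$analysis <<- analysis
    })
    if (stage == "sem") run_stage("sem", function() {
      if (is.null(results$analysis))
        stop("sem stage requires the preprocess stage")
      spec <- if (!is.null(config$sem_spec_path))
        read_sem_spec(config$sem_spec_path) else fp_sem_spec()
      full <- fit_sem(spec, data = results$analysis,
                      estimator = config$estimator)
      write_sem_fit(full, out_path("sem_full.json"),
                    out_path("sem_full_parameters.tsv"))
      comparisons <- list()
      for (lv in intersect(c("gm", "wm"), names(spec$latents))) {
        nested <- fit_sem(constrain_variable_paths(spec, lv),
                          data = results$analysis,
                          estimator = config$estimator)
        cmp <- chi_square_difference(full, nested)
        comparisons[[lv]] <- c(cmp,
                               list(nested_fit = as.list(nested$fit)))
      }
      jsonlite::write_json(comparisons, out_path("sem_nested.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      note("sem", c(out_path("sem_full.json"),
                    out_path("sem_full_parameters.tsv"),
                    out_path("sem_nested.json")))
      results$sem <<- list(full = full, comparisons = comparisons)
    })
    if (stage == "window") run_stage("window", function() {
      if (is.null(results$analysis))
        stop("window stage requires the preprocess stage")
      sbp <- rowMeans(cbind(cohort$sbp_1, cohort$sbp_2), na.rm = TRUE)
      ef <- ef_sum_score(results$analysis)
      wcfg <- config$window
      files <- character(0)
      groups <- list(all = rep(TRUE, nrow(cohort)))
      if (!is.null(config$strata) && config$strata %in% names(cohort)) {
        gvar <- cohort[[config$strata]]
        for (gl in unique(gvar[!is.na(gvar)]))
          groups[[paste0(config$strata, "_", gl)]] <- !is.na(gvar) &
            gvar == gl
      }
      if (!is.null(config$age_split)) {
        groups[["midlife"]] <- cohort$age_at_scan < config$age_split
        groups[["latelife"]] <- cohort$age_at_scan >= config$age_split
      }
      curves <- list()
      for (g in names(groups)) {
        sel <- groups[[g]] & !is.na(sbp) & !is.na(ef)
        if (sum(sel) < 1 / wcfg$frac + 5) next
        cur <- sliding_window_curve(sbp[sel], ef[sel], frac = wcfg$frac,
                                    step_quantile = wcfg$step_quantile)
        cur$mean_smooth <- gaussian_smooth(cur$mean, kernel = wcfg$kernel)
        f <- out_path(paste0("window_", g, ".tsv"))
        write_curve(cur, f)
        files <- c(files, f)
        curves[[g]] <- cur
      }
      fb <- fixed_bin_curve(sbp[!is.na(sbp) & !is.na(ef)],
                            ef[!is.na(sbp) & !is.na(ef)],
                            n_bins = wcfg$n_bins, width = wcfg$width)
      f <- out_path("fixed_bins.tsv")
      write_curve(fb, f)
      files <- c(files, f)
      note("window", files)
      results$curves <<- c(curves, list(fixed = fb))
    })
    if (stage == "regression") run_stage("regression", function() {
      if (is.null(results$analysis))
        stop("regression stage requires the preprocess stage")
      ef <- ef_sum_score(results$analysis)
      X <- table1_predictors(cohort)
      reg <- fit_regression(ef, X)
      write_regression(reg, out_path("regression_table.tsv"),
                       out_path("regression_summary.json"))
      note("regression", c(out_path("regression_table.tsv"),
                           out_path("regression_summary.json")))
      results$regression <<- reg
    })
    if (stage == "mediation") run_stage("mediation", function() {
      if (is.null(results$analysis))
        stop("mediation stage requires the preprocess stage")
      a <- results$analysis
      gm_comp <- rowMeans(a[, c("ag", "prc", "cg", "sfg", "fp", "mtg")])
      wm_comp <- rowMeans(a[, c("icvf", "od")])
      ef <- ef_sum_score(a)
      med <- mediate(gm_comp, wm_comp, ef, n_boot = 2000,
                     seed = (config$seed %||% 1) + 7L)
      jsonlite::write_json(
        list(a = med$a, b = med$b, c_total = med$c_total,
             c_direct = med$c_direct, indirect = med$indirect,
             ci = as.data.frame(med$boot_ci), n_boot = med$n_boot,
             seed = med$seed),
        out_path("mediation.json"), auto_unbox = TRUE, pretty = TRUE,
        digits = NA, force = TRUE)
      note("mediation", out_path("mediation.json"))
      results$mediation <<- med
    })
  }

  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}

#' Executive-function sum score
#'
#' Equal-weight composite of the two normalised cognitive indicators
#' (reaction-time score and pairs score), z-scored. A simple observed proxy
#' for the executive-function latent variable, used by the window-curve and
#' regression stages.
#'
#' @param analysis Output of [prepare_analysis_table()].
#' @return Numeric vector (z-scored).
#' @export
ef_sum_score <- function(analysis) {
  as.vector(scale(rowMeans(analysis[, c("rt", "pairs")])))
}

#' Risk-factor predictor table for the executive-function regression
#'
#' The eight covariates regressed on the executive-function score:
#' waist-to-hip ratio, smoking points (0-2), cholesterol medication,
#' antihypertensive medication, diabetes, APOE e4 allele count, age at scan
#' and socio-economic deprivation (Townsend index).
#'
#' @param cohort Cohort data frame (package column dictionary).
#' @return Data frame with 8 numeric columns.
#' @export
table1_predictors <- function(cohort) {
  status <- tolower(as.character(cohort$smoking_status))
  end_age <- ifelse(status == "current", cohort$age_at_scan,
                    cohort$age_stopped_smoking)
  py <- ifelse(status == "never", 0,
               (cohort$cigarettes_per_day / 20) *
                 pmax(end_age - cohort$age_started_smoking, 0))
  data.frame(
    whr = cohort$waist_cm / cohort$hip_cm,
    smoking = as.numeric(smoking_points(status, py)),
    chol_med = as.numeric(cohort$on_cholesterol_medication),
    bp_med = as.numeric(cohort$on_bp_medication),
    diabetic = as.numeric(cohort$diabetic),
    apoe = as.numeric(apoe_points(cohort$apoe_genotype)),
    age = cohort$age_at_scan,
    townsend = cohort$townsend
  )
}
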