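# End-to-end orchestration: ingest (or simulate) -> trim -> features ->
# Rasch measurement and flow labels -> stepwise selection -> classifier
# evaluation -> permutation importance, with report CSVs written to an
# output directory. Every stage is a pure function of (inputs, config,
# seed), so two runs with the same configuration are identical.

#' Pipeline configuration
#'
#' @param input_dir Directory of E4-style session directories, or `NULL` to
#'   simulate a study instead.
#' @param simulate A [generator_config()] used when `input_dir` is `NULL`.
#' @param effects A [flow_effects()] spec for simulation.
#' @param trim A [trim_policy()].
#' @param baseline_mode `"preceding"` or `"mean_of_pre_post"`.
#' @param kurtosis `"excess"` or `"raw"`.
#' @param stepwise_alpha Entry level for feature selection.
#' @param cv_schemes Validation schemes to run.
#' @param classifiers Classifier kinds to run.
#' @param n_shuffles Permutation-importance shuffles.
#' @param seed Integer seed for all stage randomness.
#' @param output_dir Where to write report CSVs, or `NULL` for none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            simulate = generator_config(),
                            effects = flow_effects(),
                            trim = trim_policy(),
                            baseline_mode = "preceding",
                            kurtosis = c("excess", "raw"),
                            stepwise_alpha = 0.10,
                            cv_schemes = c("between_participant", "stratified_10fold", "resubstitution"),
                            classifiers = c("logistic", "gaussian_nb"),
                            n_shuffles = 1000L,
                            seed = 1L,
                            output_dir = NULL) {
  kurtosis <- match.arg(kurtosis)
  if (!(stepwise_alpha > 0 && stepwise_alpha < 1)) {
    abort_flowsense("stepwise_alpha must be in (0,1)", "flowsense_validation_error")
  }
  schemes <- c("between_participant", "stratified_10fold", "resubstitution", "leave_one_out")
  if (!all(cv_schemes %in% schemes)) {
    abort_flowsense("unknown CV scheme in cv_schemes", "flowsense_validation_error")
  }
  if (!all(classifiers %in% c("logistic", "gaussian_nb"))) {
    abort_flowsense("unknown classifier kind", "flowsense_validation_error")
  }
  seed <- as.integer(seed)
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be set from a YAML key-value
#' file; unknown keys are rejected before any computation.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("input_dir", "baseline_mode", "kurtosis", "stepwise_alpha",
               "cv_schemes", "classifiers", "n_shuffles", "seed", "output_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort_flowsense(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
                    "flowsense_validation_error")
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input (a directory of recorded
#' sessions, or a simulated study) and returns a report bundle. With an
#' `output_dir`, tidy CSV reports are written: the feature table, the
#' Rasch measurement report (measures, difficulties, thresholds,
#' infit/outfit, residual eigenvalues, reliabilities), the selection
#' report (estimate, SE, Wald chi-square, p, odds ratio per term plus the
#' entry trace), the per-scheme metric and confusion tables, and the
#' permutation-importance table.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result` list with elements `feature_table`,
#'   `rsm_fit`, `fit_stats`, `pca`, `reliability`, `stepwise`,
#'   `wald`, `cv` (list of `cv_result`s), `importance`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      abort_flowsense(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                      "flowsense_stage_error")
    })
    say("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  sessions <- stage("ingest", {
    if (is.null(config$input_dir)) {
      cfg <- config$simulate
      cfg$seed <- config$seed
      generate_study(cfg, config$effects)$sessions
    } else {
      dirs <- list.dirs(config$input_dir, recursive = FALSE)
      if (length(dirs) == 0L) {
        abort_flowsense("input_dir contains no session directories", "flowsense_validation_error")
      }
      lapply(dirs, read_e4_session)
    }
  })

  windows <- stage("windows", {
    unlist(lapply(sessions, function(s) {
      build_task_windows(s, config$trim, config$baseline_mode)
    }), recursive = FALSE)
  })

  feature_table <- stage("features", {
    build_feature_table(windows, excess_kurtosis = config$kurtosis == "excess")
  })

  fss <- do.call(rbind, lapply(windows, function(w) w$fss_response))
  rownames(fss) <- paste(feature_table$participant_id, feature_table$task_id, sep = ":")

  rasch <- stage("rasch", fit_rsm(fss))
  fstats <- person_item_fit(rasch)
  pca <- residual_pca(fstats)
  reliability <- separation_reliability(rasch)
  feature_table$flow <- label_flow(fss)

  stepwise <- stage("stepwise", {
    forward_stepwise(
      feature_table[, feature_names()], feature_table$flow,
      feature_table$participant_id, alpha = config$stepwise_alpha
    )
  })
  wald <- wald_summary(stepwise$final_fit)

  selected <- stepwise$selected
  cv <- list()
  importance <- NULL
  if (length(selected) > 0L && length(unique(feature_table$flow)) == 2L) {
    cv <- stage("evaluate", {
      out <- list()
      for (clf in config$classifiers) {
        for (sch in config$cv_schemes) {
          out[[paste(clf, sch, sep = ".")]] <- cross_validate(
            feature_table, sch, clf, features = selected, seed = config$seed
          )
        }
      }
      out
    })
    importance <- stage("importance", {
      clf <- train_classifier("logistic", as.matrix(feature_table[, selected]), feature_table$flow)
      permutation_importance(clf, as.matrix(feature_table[, selected]), feature_table$flow,
                             n_shuffles = config$n_shuffles, seed = config$seed)
    })
  } else {
    say("no features selected (or single-class labels); skipping evaluation")
  }

  result <- structure(
    list(
      feature_table = feature_table, fss = fss,
      rsm_fit = rasch, fit_stats = fstats, pca = pca, reliability = reliability,
      stepwise = stepwise, wald = wald, cv = cv, importance = importance,
      config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_reports(result, config$output_dir)
  result
}

write_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(result$feature_table, file.path(dir, "feature_table.csv"))
  utils::write.csv(wright_map(result$rsm_fit), file.path(dir, "rasch_measures.csv"), row.names = FALSE)
  utils::write.csv(result$fit_stats$items, file.path(dir, "rasch_item_fit.csv"), row.names = FALSE)
  rasch_summary <- data.frame(
    quantity = c("person_reliability", "item_reliability", "first_residual_eigenvalue",
                 paste0("tau_", seq_along(result$rsm_fit$tau))),
    value = c(result$reliability$person_reliability, result$reliability$item_reliability,
              result$pca$eigenvalues[1], result$rsm_fit$tau)
  )
  utils::write.csv(rasch_summary, file.path(dir, "rasch_summary.csv"), row.names = FALSE)
  utils::write.csv(result$wald, file.path(dir, "selection_report.csv"), row.names = FALSE)
  utils::write.csv(result$stepwise$trace, file.path(dir, "selection_trace.csv"), row.names = FALSE)
  if (length(result$cv)) {
    metrics <- dplyr::bind_rows(lapply(result$cv, function(r) {
      tibble::tibble(
        classifier = r$classifier, scheme = r$scheme,
        auc = r$metrics$auc, f1 = r$metrics$f1,
        precision = r$metrics$precision, recall = r$metrics$recall,
        TN = r$confusion$TN, FP = r$confusion$FP, FN = r$confusion$FN, TP = r$confusion$TP
      )
    }))
    utils::write.csv(metrics, file.path(dir, "cv_metrics.csv"), row.names = FALSE)
  }
  if (!is.null(result$importance)) {
    utils::write.csv(as.data.frame(result$importance),
                     file.path(dir, "permutation_importance.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d tasks, %d flow; %d feature(s) selected>\n",
              nrow(x$feature_table), sum(x$feature_table$flow),
              length(x$stepwise$selected)))
  if (length(x$stepwise$selected)) {
    cat("selected:", paste(x$stepwise$selected, collapse = ", "), "\n")
  }
  for (r in x$cv) print(r)
  invisible(x)
}
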