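#' Distributional sample moments
#'
#' Mean, median, sample standard deviation (n-1 denominator), and the
#' moment-based shape statistics: Fisher-Pearson skewness
#' g1 = m3 / m2^(3/2) and EXCESS kurtosis g2 = m4 / m2^2 - 3, both from
#' biased central moments m_k = mean((x - mean(x))^k). A platykurtic
#' (flat, heavy-shouldered) distribution therefore has negative kurtosis.
#' With `excess_kurtosis = FALSE` the raw m4/m2^2 value is returned
#' instead, for sensitivity analysis.
#'
#' Zero-variance input has no defined shape; by convention both shape
#' statistics are returned as 0 with a `degenerate` flag and a warning.
#'
#' @param values Numeric vector, length >= 2.
#' @param excess_kurtosis Report kurtosis as excess (default TRUE).
#' @return Named list: `mean`, `median`, `sd`, `skewness`, `kurtosis`,
#'   `degenerate`.
#' @export
sample_moments <- function(values, excess_kurtosis = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    abort_flowsense("sample_moments needs >= 2 non-missing values", "flowsense_insufficient_data_error")
  }
  m <- mean(values)
  ctr <- values - m
  m2 <- mean(ctr^2)
  degenerate <- m2 == 0
  if (degenerate) {
    warn_flowsense("zero-variance input: skewness and kurtosis set to 0", "flowsense_degenerate_warning")
    skew <- 0
    kurt <- if (excess_kurtosis) 0 else 3
  } else {
    skew <- mean(ctr^3) / m2^1.5
    kurt <- mean(ctr^4) / m2^2 - if (excess_kurtosis) 3 else 0
  }
  list(
    mean = m, median = stats::median(values), sd = stats::sd(values),
    skewness = skew, kurtosis = kurt, degenerate = degenerate
  )
}

#' Extract the 30 distributional features of one task window
#'
#' For each of the six scalar streams (HR, TEMP, EDA, ACC_X, ACC_Y, ACC_Z)
#' five features are computed: the mean, median and standard-deviation
#' changes of the task samples with respect to the baseline samples, and
#' the skewness and kurtosis of the task samples alone. Names follow the
#' frozen `<stat>_<channel>` convention of [feature_names()].
#'
#' @param window A `task_window` from [build_task_windows()].
#' @param excess_kurtosis Passed to [sample_moments()].
#' @return Named numeric vector of 30 features with attributes
#'   `participant_id`, `task_id`, `flow`.
#' @export
extract_features <- function(window, excess_kurtosis = TRUE) {
  stopifnot(inherits(window, "task_window"))
  out <- numeric(0)
  for (ch in SCALAR_CHANNELS) {
    task <- window$task[[ch]]
    base <- window$baseline[[ch]]
    mt <- tryCatch(
      sample_moments(task, excess_kurtosis),
      flowsense_insufficient_data_error = function(e) {
        abort_flowsense(sprintf("channel %s: %s", ch, conditionMessage(e)),
                        "flowsense_insufficient_data_error")
      }
    )
    mb <- tryCatch(
      sample_moments(base, excess_kurtosis),
      flowsense_insufficient_data_error = function(e) {
        abort_flowsense(sprintf("baseline %s: %s", ch, conditionMessage(e)),
                        "flowsense_insufficient_data_error")
      }
    )
    f <- c(
      mt$mean - mb$mean, mt$median - mb$median, mt$sd - mb$sd,
      mt$skewness, mt$kurtosis
    )
    names(f) <- paste(FEATURE_STATS, ch, sep = "_")
    out <- c(out, f)
  }
  structure(out,
    participant_id = window$participant_id, activity_id = window$activity_id,
    task_id = window$task_id, flow = window$flow
  )
}

#' Build the per-task feature table
#'
#' One row per task window: `participant_id`, `task_id`, the 30 features in
#' the frozen column order, and the binary `flow` label (possibly NA until
#' labeling).
#'
#' @param windows List of task windows.
#' @inheritParams extract_features
#' @return A tibble with `2 + 30 + 1` columns.
#' @export
build_feature_table <- function(windows, excess_kurtosis = TRUE) {
  if (length(windows) == 0L) abort_flowsense("no windows supplied", "flowsense_validation_error")
  rows <- lapply(windows, function(w) {
    f <- extract_features(w, excess_kurtosis)
    tibble::tibble(
      participant_id = w$participant_id, task_id = w$task_id,
      !!!as.list(f),
      flow = if (is.null(w$flow)) NA_integer_ else as.integer(w$flow)
    )
  })
  tab <- dplyr::bind_rows(rows)
  key <- paste(tab$participant_id, tab$task_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_flowsense("duplicate (participant, task) keys in feature table", "flowsense_validation_error")
  }
  tab[, c("participant_id", "task_id", feature_names(), "flow")]
}

#' Write / read the feature table with a schema-version header
#'
#' @param table Feature table from [build_feature_table()].
#' @param file CSV path.
#' @name feature_table_io
#' @export
write_feature_table <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# flowsense feature table schema v1", con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(file)
}

#' @rdname feature_table_io
#' @export
read_feature_table <- function(file) {
  tibble::as_tibble(utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE))
}
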