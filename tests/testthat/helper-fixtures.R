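# Shared fixtures: all built in code at test time.

# A small but complete session: 300 s baseline, two tasks, 120 s baseline.
make_tiny_session <- function(seed = 1, task_s = c(60, 90), baseline_s = 300,
                              tail_baseline_s = 120) {
  set.seed(seed)
  total <- baseline_s + sum(task_s) + tail_baseline_s
  ch <- list(
    HR = channel_series("HR", 1700000000, 75 + rnorm(total * 1, 0, 3)),
    TEMP = channel_series("TEMP", 1700000000, 33 + rnorm(total * 4, 0, 0.1)),
    EDA = channel_series("EDA", 1700000000, abs(0.5 + rnorm(total * 4, 0, 0.05))),
    ACC = channel_series("ACC", 1700000000,
                         matrix(rnorm(total * 32 * 3, 0, 0.05), ncol = 3))
  )
  fss1 <- c(3, 2, 4, 3, 3, 2, 1, 3, 4)
  fss2 <- c(1, 0, 2, 1, 2, 1, 0, 1, 2)
  segs <- list(
    segment("baseline", 0, baseline_s),
    segment("task", baseline_s, baseline_s + task_s[1], task_id = "T1", fss_response = fss1),
    segment("task", baseline_s + task_s[1], baseline_s + sum(task_s), task_id = "T2",
            fss_response = fss2),
    segment("baseline", baseline_s + sum(task_s), total)
  )
  session_record("P01", "A1", ch, segs)
}

# Simulate an FSS response matrix from the Rating Scale Model.
simulate_fss <- function(n, beta = NULL, delta = default_item_difficulties(),
                         tau = c(-1.5, -0.5, 0.5, 1.5), seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- rnorm(n, 0, 1.5)
  X <- t(vapply(seq_len(n), function(i) {
    generate_fss_responses(beta[i], delta, tau, seed = seed * 100000L + i)
  }, integer(9)))
  attr(X, "beta") <- beta
  X
}

# Feature table + labels for one full synthetic study.
study_feature_table <- function(seed = 1, ...) {
  bundle <- generate_study(generator_config(seed = seed, ...))
  windows <- unlist(lapply(bundle$sessions, build_task_windows), recursive = FALSE)
  tab <- build_feature_table(windows)
  fss <- do.call(rbind, lapply(windows, function(w) w$fss_response))
  tab$flow <- label_flow(fss)
  attr(tab, "truth") <- bundle$truth
  attr(tab, "fss") <- fss
  tab
}

PLANTED <- c("median_diff_TEMP", "skewness_TEMP", "skewness_ACC_X",
             "skewness_ACC_Y", "kurtosis_ACC_Y")
PLANTED_SIGNS <- c(1, -1, 1, -1, -1)
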