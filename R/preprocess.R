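#' Calibration trim policy
#'
#' The wristband needs a short stabilization period after it starts
#' recording, so the first seconds of every session are discarded: 20 s for
#' skin temperature, electrodermal activity and acceleration, and 10 s for
#' heart rate (the device reports heart rate as a 10 s moving average, so
#' only its first 10 readings are unusable).
#'
#' @param TEMP,EDA,ACC,HR Seconds to discard per channel.
#' @return A named list of class `trim_policy`.
#' @export
trim_policy <- function(TEMP = 20, EDA = 20, ACC = 20, HR = 10) {
  p <- list(HR = HR, TEMP = TEMP, EDA = EDA, ACC = ACC)
  if (any(unlist(p) < 0)) abort_flowsense("trim seconds must be >= 0", "flowsense_validation_error")
  structure(p, class = "trim_policy")
}

#' Remove device-calibration samples from a channel
#'
#' Drops the first `policy[[channel]]` seconds of the series (at 4 Hz and a
#' 20 s window that is 80 samples for EDA/TEMP; 640 for ACC at 32 Hz; 10 for
#' HR at 1 Hz) and advances the start time accordingly.
#'
#' @param series A [channel_series()].
#' @param policy A [trim_policy()].
#' @return List with elements `series` (trimmed [channel_series()]) and
#'   `removed_count`.
#' @export
trim_calibration <- function(series, policy = trim_policy()) {
  stopifnot(inherits(series, "channel_series"))
  trim_s <- policy[[series$channel]]
  removed <- round(series$rate * trim_s)
  if (removed >= n_samples(series)) {
    abort_flowsense(
      sprintf("channel %s: %.0f s of data cannot absorb a %.0f s calibration trim",
              series$channel, duration_s(series), trim_s),
      "flowsense_too_short_error"
    )
  }
  values <- if (series$channel == "ACC") {
    series$values[-seq_len(removed), , drop = FALSE]
  } else {
    series$values[-seq_len(removed)]
  }
  out <- channel_series(series$channel, series$start_time + trim_s, values, series$rate)
  list(series = out, removed_count = removed)
}

#' Trim a whole session once
#'
#' Applies [trim_calibration()] to every channel of a session. Trimming
#' happens once, at the session start (that is when the device calibrates);
#' a session already marked trimmed is refused rather than silently losing
#' another window of data.
#'
#' @param session A [session_record()].
#' @param policy A [trim_policy()].
#' @return The trimmed [session_record()] with `trimmed = TRUE`.
#' @export
trim_session <- function(session, policy = trim_policy()) {
  stopifnot(inherits(session, "session_record"))
  if (isTRUE(session$trimmed)) {
    abort_flowsense("session is already trimmed; refusing to trim twice", "flowsense_double_trim_error")
  }
  channels <- lapply(session$channels, function(s) trim_calibration(s, policy)$series)
  out <- session
  out$channels <- channels
  out$trimmed <- TRUE
  out
}

# Extract the samples of one scalar stream falling in [start_s, end_s)
# measured from the ORIGINAL session start. After trimming, the first
# `trim_s` seconds are gone, so sample indices shift left by rate*trim_s.
slice_stream <- function(values, rate, start_s, end_s, trim_offset_samples) {
  i0 <- floor(start_s * rate) - trim_offset_samples
  i1 <- floor(end_s * rate) - trim_offset_samples
  i0 <- max(i0, 0L)
  if (i1 <= i0) return(numeric(0))
  values[(i0 + 1):min(i1, length(values))]
}

#' Assemble task windows paired with their baseline
#'
#' Cuts each task segment out of the (trimmed) session streams, splits the
#' accelerometer into its three axis streams, and pairs every task with a
#' baseline segment: by default the nearest preceding baseline within the
#' session, or the pooled pre/post baselines with
#' `baseline_mode = "mean_of_pre_post"`.
#'
#' @param session A [session_record()]; trimmed, or it will be trimmed here.
#' @param policy A [trim_policy()] (used only if the session is untrimmed).
#' @param baseline_mode `"preceding"` or `"mean_of_pre_post"`.
#' @return List of `task_window` objects: per-channel task and baseline
#'   sample vectors over the six scalar streams, plus identifiers and the
#'   task's FSS response.
#' @export
build_task_windows <- function(session, policy = trim_policy(),
                               baseline_mode = c("preceding", "mean_of_pre_post")) {
  baseline_mode <- match.arg(baseline_mode)
  if (!isTRUE(session$trimmed)) session <- trim_session(session, policy)
  kinds <- vapply(session$segments, function(s) s$kind, character(1))
  if (!any(kinds == "baseline") || !any(kinds == "task")) {
    abort_flowsense("session needs at least one baseline and one task segment",
                    "flowsense_validation_error")
  }

  # scalar streams with their per-stream trim offsets (in samples)
  streams <- list(
    HR = list(v = session$channels$HR$values, rate = 1, off = round(policy$HR * 1)),
    TEMP = list(v = session$channels$TEMP$values, rate = 4, off = round(policy$TEMP * 4)),
    EDA = list(v = session$channels$EDA$values, rate = 4, off = round(policy$EDA * 4)),
    ACC_X = list(v = session$channels$ACC$values[, 1], rate = 32, off = round(policy$ACC * 32)),
    ACC_Y = list(v = session$channels$ACC$values[, 2], rate = 32, off = round(policy$ACC * 32)),
    ACC_Z = list(v = session$channels$ACC$values[, 3], rate = 32, off = round(policy$ACC * 32))
  )
  cut_segment <- function(seg) {
    lapply(streams, function(st) slice_stream(st$v, st$rate, seg$start_s, seg$end_s, st$off))
  }

  baselines <- which(kinds == "baseline")
  baseline_cuts <- lapply(session$segments[baselines], cut_segment)
  baseline_starts <- vapply(session$segments[baselines], function(s) s$start_s, numeric(1))

  pooled <- NULL
  if (baseline_mode == "mean_of_pre_post") {
    pooled <- lapply(SCALAR_CHANNELS, function(ch) {
      unlist(lapply(baseline_cuts, `[[`, ch), use.names = FALSE)
    })
    names(pooled) <- SCALAR_CHANNELS
  }

  windows <- list()
  for (i in which(kinds == "task")) {
    seg <- session$segments[[i]]
    task_samples <- cut_segment(seg)
    if (baseline_mode == "preceding") {
      prev <- which(baseline_starts < seg$start_s)
      if (length(prev) == 0L) {
        abort_flowsense(
          sprintf("task %s has no preceding baseline", seg$task_id),
          "flowsense_pairing_error"
        )
      }
      base_samples <- baseline_cuts[[max(prev)]]
    } else {
      base_samples <- pooled
    }
    for (ch in SCALAR_CHANNELS) {
      if (length(task_samples[[ch]]) == 0L) {
        abort_flowsense(sprintf("task %s: empty %s stream after trimming", seg$task_id, ch),
                        "flowsense_too_short_error")
      }
      if (length(base_samples[[ch]]) == 0L) {
        abort_flowsense(sprintf("task %s: empty baseline %s stream after trimming", seg$task_id, ch),
                        "flowsense_too_short_error")
      }
    }
    windows[[length(windows) + 1L]] <- structure(
      list(
        participant_id = session$participant_id,
        activity_id = session$activity_id,
        task_id = seg$task_id,
        task = task_samples,
        baseline = base_samples,
        fss_response = seg$fss_response,
        flow = NA_integer_
      ),
      class = "task_window"
    )
  }
  windows
}

#' Window metadata audit table
#'
#' @param windows List of task windows from [build_task_windows()].
#' @return Tibble with one row per window and per-channel sample counts.
#' @export
window_metadata <- function(windows) {
  rows <- lapply(windows, function(w) {
    counts <- vapply(SCALAR_CHANNELS, function(ch) length(w$task[[ch]]), numeric(1))
    tibble::tibble(
      participant_id = w$participant_id, activity_id = w$activity_id, task_id = w$task_id,
      !!!setNames(as.list(counts), paste0("n_", SCALAR_CHANNELS))
    )
  })
  dplyr::bind_rows(rows)
}
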