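#' Construct a physiological channel series
#'
#' A `channel_series` holds one channel of an E4-style recording: the UNIX
#' start time, the sampling rate, and the sample values. Acceleration is
#' stored as an n x 3 matrix of (x, y, z) triples in g; the scalar channels
#' are numeric vectors (heart rate in bpm, skin temperature in degrees C,
#' electrodermal activity in microsiemens).
#'
#' @param channel One of `"HR"`, `"TEMP"`, `"EDA"`, `"ACC"`.
#' @param start_time Session start, UNIX seconds. Sub-second values are
#'   rounded down with a warning (timestamps are kept at 1 s resolution).
#' @param values Numeric vector (scalar channels) or 3-column matrix (ACC).
#' @param rate Sampling rate in Hz; defaults to the channel's device rate
#'   (1 Hz HR, 4 Hz TEMP/EDA, 32 Hz ACC) and must equal it.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(channel, start_time, values, rate = e4_channel_rate(channel)) {
  channel <- match.arg(channel, c("HR", "TEMP", "EDA", "ACC"))
  if (rate != e4_channel_rate(channel)) {
    abort_flowsense(
      sprintf("channel %s declares rate %s Hz; expected %s Hz", channel, rate, e4_channel_rate(channel)),
      "flowsense_format_error"
    )
  }
  if (start_time %% 1 != 0) {
    warn_flowsense(
      sprintf("start_time %.3f rounded down to whole seconds", start_time),
      "flowsense_timestamp_warning"
    )
    start_time <- floor(start_time)
  }
  if (channel == "ACC") {
    values <- as.matrix(values)
    if (ncol(values) != 3L) {
      abort_flowsense("ACC values must have exactly 3 columns (x, y, z)", "flowsense_format_error")
    }
    colnames(values) <- c("x", "y", "z")
    n <- nrow(values)
  } else {
    values <- as.numeric(values)
    n <- length(values)
  }
  if (n == 0L) abort_flowsense(sprintf("channel %s has no samples", channel), "flowsense_format_error")
  structure(
    list(
      channel = channel, start_time = as.numeric(start_time), rate = rate,
      values = values, units = e4_channel_units(channel)
    ),
    class = "channel_series"
  )
}

n_samples <- function(series) {
  if (series$channel == "ACC") nrow(series$values) else length(series$values)
}

duration_s <- function(series) n_samples(series) / series$rate

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf(
    "<channel_series %s: %d samples @ %g Hz (%.1f s), start %d, units %s>\n",
    x$channel, n_samples(x), x$rate, duration_s(x), x$start_time, x$units
  ))
  invisible(x)
}

#' Construct a session segment
#'
#' Segments partition a session into baseline and task intervals, with
#' offsets in seconds from the session start. Task segments carry the
#' nine Flow State Scale responses (integers 0..4, strongly disagree = 0
#' to strongly agree = 4); baseline segments carry none.
#'
#' @param kind `"baseline"` or `"task"`.
#' @param start_s,end_s Half-open interval `[start_s, end_s)` in seconds
#'   from the session start.
#' @param task_id Task identifier (tasks only).
#' @param fss_response Integer 9-vector of ratings in 0..4 (tasks only).
#' @return An object of class `segment`.
#' @export
segment <- function(kind, start_s, end_s, task_id = NA_character_, fss_response = NULL) {
  kind <- match.arg(kind, c("baseline", "task"))
  if (!(start_s >= 0 && start_s < end_s)) {
    abort_flowsense(
      sprintf("segment needs 0 <= start < end, got [%s, %s)", start_s, end_s),
      "flowsense_validation_error"
    )
  }
  if (kind == "baseline" && !is.null(fss_response)) {
    abort_flowsense("baseline segments must not carry FSS responses", "flowsense_validation_error")
  }
  if (kind == "task") {
    if (is.null(fss_response)) {
      abort_flowsense("task segments require a 9-item FSS response", "flowsense_validation_error")
    }
    fss_response <- as.integer(fss_response)
    if (length(fss_response) != 9L || anyNA(fss_response) ||
        any(fss_response < 0L) || any(fss_response > 4L)) {
      abort_flowsense("FSS responses must be nine integers in 0..4", "flowsense_validation_error")
    }
    names(fss_response) <- FSS_ITEMS
  }
  structure(
    list(
      kind = kind, task_id = as.character(task_id),
      start_s = as.numeric(start_s), end_s = as.numeric(end_s),
      fss_response = fss_response
    ),
    class = "segment"
  )
}

#' Construct a session record
#'
#' Bundles the four channel series of one recording session with its
#' ordered, non-overlapping segment list and study identifiers.
#'
#' @param participant_id,activity_id Identifiers.
#' @param channels Named list with elements `HR`, `TEMP`, `EDA`, `ACC`,
#'   each a [channel_series()].
#' @param segments List of [segment()]s ordered by start offset.
#' @param trimmed Logical; whether calibration trimming has been applied.
#' @return An object of class `session_record`.
#' @export
session_record <- function(participant_id, activity_id, channels, segments, trimmed = FALSE) {
  need <- c("HR", "TEMP", "EDA", "ACC")
  if (!all(need %in% names(channels))) {
    abort_flowsense(
      paste("missing channel(s):", paste(setdiff(need, names(channels)), collapse = ", ")),
      "flowsense_missing_channel_error"
    )
  }
  channels <- channels[need]
  ok <- vapply(channels, inherits, logical(1), what = "channel_series")
  if (!all(ok)) abort_flowsense("all channels must be channel_series objects", "flowsense_validation_error")
  if (length(segments) == 0L) {
    abort_flowsense("a session needs at least one segment", "flowsense_validation_error")
  }
  starts <- vapply(segments, function(s) s$start_s, numeric(1))
  ends <- vapply(segments, function(s) s$end_s, numeric(1))
  if (is.unsorted(starts, strictly = TRUE)) {
    abort_flowsense("segments must be ordered by start offset", "flowsense_validation_error")
  }
  if (any(ends[-length(ends)] > starts[-1] + 1e-9)) {
    abort_flowsense("segments overlap", "flowsense_validation_error")
  }
  durations <- vapply(channels, duration_s, numeric(1))
  if (max(ends) > min(durations) + 1e-9) {
    abort_flowsense(
      sprintf(
        "segments extend to %.1f s but the shortest channel covers only %.1f s",
        max(ends), min(durations)
      ),
      "flowsense_validation_error"
    )
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      activity_id = as.character(activity_id),
      channels = channels, segments = segments, trimmed = isTRUE(trimmed)
    ),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  n_task <- sum(vapply(x$segments, function(s) s$kind == "task", logical(1)))
  cat(sprintf(
    "<session_record %s/%s: %d segments (%d tasks), trimmed=%s>\n",
    x$participant_id, x$activity_id, length(x$segments), n_task, x$trimmed
  ))
  invisible(x)
}

# ---- on-disk dialect ------------------------------------------------------

read_channel_csv <- function(path, channel, acc_scale) {
  if (!file.exists(path)) {
    abort_flowsense(sprintf("missing channel file: %s", path), "flowsense_missing_channel_error")
  }
  lines <- readLines(path)
  if (length(lines) < 3L) {
    abort_flowsense(sprintf("%s: need timestamp, rate and >=1 sample", path), "flowsense_parse_error")
  }
  parse_row <- function(line, lineno) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) {
      abort_flowsense(sprintf("%s: malformed row at line %d: '%s'", path, lineno, line),
                      "flowsense_parse_error")
    }
    vals
  }
  start_time <- parse_row(lines[1], 1L)[1]
  rate <- parse_row(lines[2], 2L)[1]
  if (rate != e4_channel_rate(channel)) {
    abort_flowsense(
      sprintf("%s declares rate %g Hz; %s is recorded at %g Hz", path, rate,
              channel, e4_channel_rate(channel)),
      "flowsense_format_error"
    )
  }
  body <- lines[-(1:2)]
  if (channel == "ACC") {
    rows <- lapply(seq_along(body), function(i) {
      v <- parse_row(body[i], i + 2L)
      if (length(v) != 3L) {
        abort_flowsense(sprintf("%s: line %d has %d columns, expected 3", path, i + 2L, length(v)),
                        "flowsense_parse_error")
      }
      v
    })
    values <- do.call(rbind, rows) * acc_scale
  } else {
    values <- vapply(seq_along(body), function(i) parse_row(body[i], i + 2L)[1], numeric(1))
  }
  channel_series(channel, start_time, values, rate)
}

#' Read an E4-style session directory
#'
#' Expects `HR.csv`, `TEMP.csv`, `EDA.csv`, `ACC.csv` in the de-facto E4
#' export dialect (line 1 = UNIX start timestamp, line 2 = sampling rate,
#' then one sample per line; `ACC.csv` has three comma-separated columns of
#' raw counts) plus an `annotations.csv` sidecar with segment boundaries and
#' Flow State Scale responses.
#'
#' @param dir Session directory.
#' @param acc_scale Accelerometer scale in g per raw count (default 1/64).
#' @return A [session_record()].
#' @export
read_e4_session <- function(dir, acc_scale = 1 / 64) {
  channels <- list(
    HR = read_channel_csv(file.path(dir, "HR.csv"), "HR", acc_scale),
    TEMP = read_channel_csv(file.path(dir, "TEMP.csv"), "TEMP", acc_scale),
    EDA = read_channel_csv(file.path(dir, "EDA.csv"), "EDA", acc_scale),
    ACC = read_channel_csv(file.path(dir, "ACC.csv"), "ACC", acc_scale)
  )
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  session_record(
    participant_id = attr(ann, "participant_id"),
    activity_id = attr(ann, "activity_id"),
    channels = channels, segments = ann
  )
}

# %.17g round-trips IEEE doubles exactly through as.numeric()
format_num <- function(x) sprintf("%.17g", x)

#' Write a session record as an E4-style directory
#'
#' Inverse of [read_e4_session()]: emits the per-channel CSVs (ACC values
#' divided by `acc_scale` back to raw counts) and the `annotations.csv`
#' sidecar, such that reading the directory back reproduces the record.
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if needed).
#' @inheritParams read_e4_session
#' @return `dir`, invisibly.
#' @export
write_e4_session <- function(session, dir, acc_scale = 1 / 64) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_flowsense(sprintf("cannot create %s", dir), "flowsense_io_error")
  for (ch in names(session$channels)) {
    s <- session$channels[[ch]]
    body <- if (ch == "ACC") {
      raw <- s$values / acc_scale
      apply(raw, 1, function(r) paste(format_num(r), collapse = ","))
    } else {
      format_num(s$values)
    }
    writeLines(c(format_num(s$start_time), format_num(s$rate), body),
               file.path(dir, paste0(ch, ".csv")))
  }
  write_annotations(session, file.path(dir, "annotations.csv"))
  invisible(dir)
}

#' Read the annotation sidecar
#'
#' `annotations.csv` has one row per segment with columns `participant_id`,
#' `activity_id`, `kind`, `task_id`, `start_s`, `end_s`, `fss_q1`..`fss_q9`.
#' Ratings are integers 0..4; baseline rows leave the rating columns empty.
#' Rows are returned sorted by start offset.
#'
#' @param file Path to the sidecar CSV.
#' @return List of [segment()]s with `participant_id`/`activity_id`
#'   attributes.
#' @export
read_annotations <- function(file) {
  if (!file.exists(file)) {
    abort_flowsense(sprintf("missing annotations file: %s", file), "flowsense_missing_channel_error")
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("participant_id", "activity_id", "kind", "task_id", "start_s", "end_s",
            paste0("fss_q", 1:9))
  if (!all(need %in% names(df))) {
    abort_flowsense(
      paste("annotations missing column(s):", paste(setdiff(need, names(df)), collapse = ", ")),
      "flowsense_parse_error"
    )
  }
  df <- df[order(df$start_s), , drop = FALSE]
  segs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ratings <- suppressWarnings(as.integer(row[paste0("fss_q", 1:9)]))
    if (row$kind == "baseline") {
      if (any(!is.na(ratings))) {
        abort_flowsense(sprintf("annotations row %d: baseline rows must not carry ratings", i),
                        "flowsense_validation_error")
      }
      segment("baseline", row$start_s, row$end_s)
    } else if (row$kind == "task") {
      if (anyNA(ratings) || any(ratings < 0L | ratings > 4L)) {
        abort_flowsense(sprintf("annotations row %d: ratings must be integers 0..4", i),
                        "flowsense_validation_error")
      }
      segment("task", row$start_s, row$end_s, task_id = row$task_id, fss_response = ratings)
    } else {
      abort_flowsense(sprintf("annotations row %d: unknown kind '%s'", i, row$kind),
                      "flowsense_parse_error")
    }
  })
  starts <- vapply(segs, function(s) s$start_s, numeric(1))
  ends <- vapply(segs, function(s) s$end_s, numeric(1))
  if (length(segs) > 1L && any(ends[-length(ends)] > starts[-1] + 1e-9)) {
    abort_flowsense("annotations contain overlapping segments", "flowsense_validation_error")
  }
  structure(segs,
    participant_id = as.character(df$participant_id[1]),
    activity_id = as.character(df$activity_id[1])
  )
}

write_annotations <- function(session, file) {
  rows <- lapply(session$segments, function(s) {
    ratings <- if (s$kind == "task") as.integer(s$fss_response) else rep(NA_integer_, 9)
    c(
      list(
        participant_id = session$participant_id, activity_id = session$activity_id,
        kind = s$kind, task_id = if (is.na(s$task_id)) "" else s$task_id,
        start_s = s$start_s, end_s = s$end_s
      ),
      setNames(as.list(ratings), paste0("fss_q", 1:9))
    )
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}
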