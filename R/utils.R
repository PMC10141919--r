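# Internal helpers shared across modules.

#' @importFrom stats median sd var qnorm rnorm runif rbeta rexp pchisq glm
#'   binomial coef logLik predict setNames quantile cor dnorm plogis fitted
#'   model.matrix as.formula glm.control reorder
#' @importFrom utils head tail
NULL

abort_flowsense <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "flowsense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_flowsense <- function(msg, class) {
  warning(structure(
    class = c(class, "flowsense_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Expected sampling rate for each E4 channel
#'
#' The wristband samples heart rate at 1 Hz, skin temperature and
#' electrodermal activity at 4 Hz, and the 3-axis accelerometer at 32 Hz.
#'
#' @param channel One of `"HR"`, `"TEMP"`, `"EDA"`, `"ACC"`.
#' @return Sampling rate in samples per second.
#' @export
e4_channel_rate <- function(channel) {
  rates <- c(HR = 1, TEMP = 4, EDA = 4, ACC = 32)
  channel <- match.arg(channel, names(rates))
  unname(rates[[channel]])
}

e4_channel_units <- function(channel) {
  units <- c(HR = "bpm", TEMP = "degC", EDA = "microsiemens", ACC = "g")
  unname(units[[match.arg(channel, names(units))]])
}

# Scalar stream names used downstream of ACC axis splitting.
SCALAR_CHANNELS <- c("HR", "TEMP", "EDA", "ACC_X", "ACC_Y", "ACC_Z")

# Canonical names of the nine Flow State Scale elements, in the
# conventional instrument order.
FSS_ITEMS <- c(
  "challenge_skill_balance",
  "action_awareness_merging",
  "clear_goals",
  "unambiguous_feedback",
  "concentration",
  "sense_of_control",
  "loss_of_self_consciousness",
  "transformation_of_time",
  "autotelic_experience"
)

#' @rdname feature_names
#' @format NULL
FEATURE_STATS <- c("mean_diff", "median_diff", "sd_diff", "skewness", "kurtosis")

#' Canonical feature names
#'
#' The 30 distributional features follow the fixed naming convention
#' `<stat>_<channel>` with stats `mean_diff`, `median_diff`, `sd_diff`,
#' `skewness`, `kurtosis` and channels `HR`, `TEMP`, `EDA`, `ACC_X`,
#' `ACC_Y`, `ACC_Z`. The order (stat fastest within channel) is frozen so
#' that model coefficients are portable across runs.
#'
#' @return Character vector of the 30 feature names.
#' @export
feature_names <- function() {
  as.vector(t(outer(SCALAR_CHANNELS, FEATURE_STATS, function(ch, st) paste(st, ch, sep = "_"))))
}

# Derive a per-stream seed from a master seed; kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 69069 + k * 12345 + 1) %% 2147483647
  as.integer(s)
}
utils::globalVariables(c("type", "measure", "id", "feature", "mean_auc_drop", "sd_auc_drop"))
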