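# Synthetic-study generator. Emulates the two study designs -- five
# participants x two activities x (5 min baseline, six 1-17 min tasks,
# 5 min baseline), and the single-participant ten-session daily-use design
# -- with flow-dependent distributional effects on the physiological
# channels whose directions match the inferential findings the pipeline is
# meant to recover: flow raises the task skin-temperature median relative
# to baseline, skews skin temperature negatively, skews x-axis
# acceleration positively, skews y-axis acceleration negatively, and makes
# y-axis acceleration more platykurtic. Heart-rate and EDA effects are
# deliberately dominated by between-person offsets, so those channels
# carry little cross-participant signal.

#' Flow effect specification
#'
#' How flow physiology is expressed in the synthetic channels. Each of the
#' five target features is driven by a latent "aspect" of the task-level
#' physiological state (a thermal state read out by both the TEMP median
#' and TEMP skewness, x-movement asymmetry, y-movement asymmetry, and
#' y-movement regime separation); the latent flow intensity loads
#' positively on every aspect, so flow tasks express, on average, a raised TEMP median,
#' negative TEMP skewness, positive ACC_X skewness, negative ACC_Y
#' skewness and platykurtic ACC_Y -- while each feature still carries
#' conditionally independent information about flow. Shape effects enter
#' through mean-zero, variance-normalized carriers so that mean and
#' spread difference features stay (near-)silent; only the direct TEMP
#' plateau shift touches the location features, and the TEMP median
#' carrier gives the median more flow signal than the mean. Heart rate
#' and EDA respond weakly relative to their person-level offsets.
#' `null_effects()` zeroes every flow-dependent term.
#'
#' @param temp_median_shift Direct, graded upward shift of the task TEMP
#'   plateau under flow, degC.
#' @param temp_aspect_w Weight shift of the TEMP two-regime carrier per SD
#'   of the thermal-shift aspect (upper-regime weight above 1/2 raises the
#'   median and skews negative).
#' @param temp_skew Amplitude of the TEMP skewness target (the population
#'   skewness approaches `-temp_skew * tanh(aspect)`).
#' @param temp_median_u Amplitude of the TEMP median carrier, in TEMP
#'   noise SD units.
#' @param u_jitter SD of the log-normal jitter on the carrier amplitude.
#' @param accx_skew Amplitude of the ACC_X skewness target (positive
#'   direction).
#' @param accy_asym Amplitude of the ACC_Y skewness target (negative
#'   direction; realized by shifting the mixture's upper-regime weight).
#' @param accy_kurtosis_drop Amplitude of the ACC_Y excess-kurtosis target
#'   around its neutral value -0.7 (wider regime separation is more
#'   platykurtic; the target is `-0.7 - accy_kurtosis_drop * tanh(aspect)`).
#' @param shape_noise_sd Task-level noise on each skewness-target argument.
#' @param asym_noise_sd Task-level noise on the TEMP carrier weight.
#' @param sep_noise_sd Task-level noise on the kurtosis-target argument.
#' @param hr_flow_shift,eda_flow_shift Weak graded within-person flow
#'   responses.
#' @param hr_drift_sd,temp_drift_sd,eda_drift_sd,acc_drift_sd Segment-level
#'   level drifts applied to every segment (the noise floor of the
#'   location difference features).
#' @param scale_noise_sd SD of the log-normal per-segment noise-scale
#'   multiplier (noise floor of the `sd_diff` features).
#' @param hr_between_person_sd,eda_between_person_sd,temp_between_person_sd,
#'   acc_between_person_sd Person-offset SDs.
#' @param hr_noise_sd,temp_noise_sd,eda_noise_sd,acc_noise_sd Sample noise.
#' @return A `flow_effects` list.
#' @export
flow_effects <- function(temp_median_shift = 0,
                         temp_aspect_w = 0.26,
                         temp_skew = 0.36,
                         temp_median_u = 1.2,
                         u_jitter = 0.04,
                         accx_skew = 0.45,
                         accy_asym = 0.5,
                         accy_kurtosis_drop = 0.45,
                         shape_noise_sd = 0.25,
                         asym_noise_sd = 0.012,
                         sep_noise_sd = 0.3,
                         hr_flow_shift = 1.0,
                         eda_flow_shift = 0.05,
                         hr_drift_sd = 2,
                         temp_drift_sd = 0.0008,
                         eda_drift_sd = 0.08,
                         acc_drift_sd = 0.006,
                         scale_noise_sd = 0.06,
                         hr_between_person_sd = 8,
                         eda_between_person_sd = 0.3,
                         temp_between_person_sd = 0.5,
                         acc_between_person_sd = 0.02,
                         hr_noise_sd = 3,
                         temp_noise_sd = 0.08,
                         eda_noise_sd = 0.05,
                         acc_noise_sd = 0.05) {
  eff <- as.list(environment())
  if (any(unlist(eff[c("hr_noise_sd", "temp_noise_sd", "eda_noise_sd", "acc_noise_sd")]) <= 0)) {
    abort_flowsense("noise scales must be > 0", "flowsense_validation_error")
  }
  if (temp_aspect_w < 0 || accy_asym < 0) {
    abort_flowsense("mixture weight effects must be >= 0", "flowsense_validation_error")
  }
  structure(eff, class = "flow_effects")
}

#' @rdname flow_effects
#' @export
null_effects <- function() {
  flow_effects(
    temp_median_shift = 0, temp_aspect_w = 0, temp_skew = 0,
    accx_skew = 0, accy_asym = 0, accy_kurtosis_drop = 0,
    hr_flow_shift = 0, eda_flow_shift = 0
  )
}

#' Generator configuration
#'
#' Defaults reproduce the Study-1 design: 5 participants x 2 activities x
#' (300 s baseline, six tasks of 60-1020 s with mean 375 s, 300 s
#' baseline), flow prevalence 22/60, and a Rating Scale Model for the nine
#' survey items whose difficulty ordering places the transformation of
#' time at the top of the hierarchy. [study2_config()] is the
#' single-participant daily-use preset: 10 one-task sessions of 600-4980 s.
#'
#' @param n_participants,activities_per_participant,tasks_per_activity
#'   Design counts.
#' @param baseline_s Baseline duration, seconds.
#' @param task_duration_range Task duration bounds, seconds.
#' @param task_duration_mean Target mean task duration, seconds (realized
#'   through a scaled Beta draw inside the range).
#' @param flow_prevalence Target proportion of full-flow tasks.
#' @param rsm_item_difficulties Named 9-vector of item difficulties
#'   (logits, mean 0, `transformation_of_time` the maximum).
#' @param rsm_thresholds Shared category thresholds (sum 0).
#' @param flow_to_beta `c(intercept, slope)` affine map from the
#'   threshold-centered latent flow intensity to the survey person measure:
#'   `beta = intercept + slope * (intensity - flow threshold)`.
#' @param flow_person_sd SD of the person-level flow propensity.
#' @param aspect_loading Loading of the latent flow intensity on each of
#'   the five physiological aspect variables.
#' @param intensity_noise_sd SD of the aspect-independent intensity noise.
#' @param seed Integer master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 5L,
                             activities_per_participant = 2L,
                             tasks_per_activity = 6L,
                             baseline_s = 300,
                             task_duration_range = c(60, 1020),
                             task_duration_mean = 375,
                             flow_prevalence = 22 / 60,
                             rsm_item_difficulties = default_item_difficulties(),
                             rsm_thresholds = c(-1.5, -0.5, 0.5, 1.5),
                             flow_to_beta = c(1.8, 2.5),
                             flow_person_sd = 0.5,
                             aspect_loading = 1.0,
                             intensity_noise_sd = 0.8,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (n_participants < 1L || activities_per_participant < 1L || tasks_per_activity < 1L) {
    abort_flowsense("design counts must be >= 1", "flowsense_validation_error")
  }
  if (task_duration_range[1] >= task_duration_range[2] ||
      task_duration_mean <= task_duration_range[1] ||
      task_duration_mean >= task_duration_range[2]) {
    abort_flowsense("task duration mean must lie inside the range", "flowsense_validation_error")
  }
  if (length(rsm_item_difficulties) != 9L ||
      names(which.max(rsm_item_difficulties)) != "transformation_of_time") {
    abort_flowsense("item difficulties must be 9 values with transformation_of_time the maximum",
                    "flowsense_validation_error")
  }
  if (abs(sum(rsm_thresholds)) > 1e-8) {
    abort_flowsense("thresholds must sum to 0", "flowsense_validation_error")
  }
  if (!(flow_prevalence > 0 && flow_prevalence < 1)) {
    abort_flowsense("flow prevalence must be in (0,1)", "flowsense_validation_error")
  }
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
study2_config <- function(seed = 1L, ...) {
  generator_config(
    n_participants = 1L, activities_per_participant = 10L, tasks_per_activity = 1L,
    task_duration_range = c(600, 4980), task_duration_mean = 2000,
    seed = seed, ...
  )
}

#' Default item difficulty hierarchy
#'
#' The nine flow elements ordered by difficulty of endorsement: clear
#' goals are endorsed first as immersion deepens, then the
#' challenge-skill balance, control and reward, concentration and
#' feedback, loss of self-consciousness, action-awareness merging, and
#' last the transformation of time. Magnitudes are generator choices (mean
#' 0 logits), not estimates from any dataset.
#'
#' @return Named numeric 9-vector, mean 0.
#' @export
default_item_difficulties <- function() {
  d <- c(
    clear_goals = -1.3,
    challenge_skill_balance = -0.9,
    sense_of_control = -0.5,
    autotelic_experience = -0.4,
    concentration = -0.1,
    unambiguous_feedback = 0.0,
    loss_of_self_consciousness = 0.7,
    action_awareness_merging = 1.0,
    transformation_of_time = 1.5
  )
  d[FSS_ITEMS]
}

#' Sample a 9-item FSS response vector from the Rating Scale Model
#'
#' @param beta Person measure for the task.
#' @param delta Named item difficulties (length 9).
#' @param tau Shared thresholds (sum 0).
#' @param seed Optional integer seed.
#' @return Named integer 9-vector of ratings 0..M.
#' @export
generate_fss_responses <- function(beta, delta = default_item_difficulties(),
                                   tau = c(-1.5, -0.5, 0.5, 1.5), seed = NULL) {
  if (abs(sum(tau)) > 1e-8) abort_flowsense("thresholds must sum to 0", "flowsense_validation_error")
  if (length(delta) != 9L) abort_flowsense("delta must have length 9", "flowsense_validation_error")
  if (!is.null(seed)) set.seed(seed)
  M <- length(tau)
  resp <- vapply(delta, function(d) {
    p <- rsm_category_probs(beta, d, tau)
    sample(0:M, 1L, prob = p)
  }, numeric(1))
  out <- as.integer(resp)
  names(out) <- names(delta)
  out
}

# ---- moment-targeted shape machinery -------------------------------------
# Shape effects are delivered by solving mixture parameters so that the
# POPULATION skewness / excess kurtosis of the segment's deviation stream
# equals an analytic target; the observed feature then differs from the
# target only by sampling noise.

# central moments of unit Gaussian noise + two-point mixture (+a w.p. w,
# -a otherwise)
mix_moments <- function(sep, w) {
  v <- 4 * sep^2 * w * (1 - w)
  m2 <- 1 + v
  m3 <- 8 * sep^3 * w * (1 - w) * (1 - 2 * w)
  m4 <- 3 + 6 * v + 16 * sep^4 * w * (1 - w) * ((1 - w)^3 + w^3)
  list(m2 = m2, g1 = m3 / m2^1.5, g2 = m4 / m2^2 - 3)
}

# solve (sep, w) of the two-regime mixture so its skewness and excess
# kurtosis match the targets; grid search with local refinement, clamped
# to the family's attainable region
solve_mixture <- function(g1_target, g2_target) {
  seps <- seq(0.05, 3.5, length.out = 45)
  ws <- seq(0.08, 0.92, length.out = 45)
  grid <- expand.grid(sep = seps, w = ws)
  mo <- mix_moments(grid$sep, grid$w)
  err <- (mo$g1 - g1_target)^2 + (mo$g2 - g2_target)^2
  best <- which.min(err)
  list(sep = grid$sep[best], w = grid$w[best])
}

# rare-tail three-point component: mass p at distance b on the target
# side and p at distance a on the opposite side (unit-noise SD units).
# The blurred median is untouched; the theoretical mean is subtracted
# exactly. Third moment ~ p*(b^3 - a^3) toward the target side.
threepoint_var <- function(p, a = 4.5, b = 5.5) p * (a^2 + b^2)

rthreepoint <- function(n, p, side, a = 4.5, b = 5.5) {
  if (p <= 0 || side == 0) return(numeric(n))
  u <- runif(n)
  far <- b * side
  near <- -a * side
  x <- ifelse(u < p, far, ifelse(u < 2 * p, near, 0))
  x - p * (far + near)
}

# choose the tail mass p (and side) delivering a population skewness
# g1_target for the stream (noise + base component of variance var_base
# and third moment m3_base + tails); grid over p, exact closed forms
solve_tail_skew <- function(g1_target, var_base, m3_base, a = 4.5, b = 5.5, p_max = 0.05) {
  delivered <- function(p, side) {
    (side * p * (b^3 - a^3) + m3_base) / (1 + var_base + threepoint_var(p, a, b))^1.5
  }
  side <- if (g1_target >= delivered(0, 1)) 1 else -1
  ps <- seq(0, p_max, length.out = 80)
  dv <- delivered(ps, side)
  best <- which.min(abs(dv - g1_target))
  list(p = ps[best], side = side)
}

# two-regime mixture draw: +a w.p. w, -a otherwise. Centering "mean"
# zeroes the mean exactly, leaving the regime asymmetry in the median
# (the TEMP median carrier); "midpoint" splits it between mean and
# median (ACC_Y, where neither location feature is a target).
rtwopoint <- function(n, a, w = 0.5, center = c("mean", "median")) {
  center <- match.arg(center)
  v <- ifelse(runif(n) < w, a, -a)
  v - if (center == "mean") a * (2 * w - 1) else twopoint_noise_median(a, w)
}

# median of (two-point mixture + standard normal noise)
twopoint_noise_median <- function(a, w) {
  if (abs(w - 0.5) < 1e-12) return(0)
  f <- function(q) w * stats::pnorm(q - a) + (1 - w) * stats::pnorm(q + a) - 0.5
  stats::uniroot(f, c(-a - 6, a + 6))$root
}

#' Synthesize one segment of one channel
#'
#' Baseline-condition streams are stationary noise around the
#' person-specific level (person offset plus a segment-level drift) at a
#' neutral physiological state. Task streams express the task\'s latent
#' physiological aspects (see [flow_effects()]): the TEMP median carrier,
#' the TEMP/ACC_X skew-normal shapes, and the ACC_Y two-regime mixture,
#' plus graded HR/EDA level shifts. Under flow the aspects are elevated on
#' average, producing the five target effect directions.
#'
#' @param channel One of `"HR"`, `"TEMP"`, `"EDA"`, `"ACC"`.
#' @param duration_s Segment duration, seconds.
#' @param flow Binary flow indicator for the segment (0 for baselines).
#' @param intensity Latent flow intensity, centered at the flow threshold
#'   (use `-Inf` for baseline segments).
#' @param effects A [flow_effects()] spec.
#' @param person_offsets Named list of person offsets (`HR`, `TEMP`, `EDA`,
#'   `ACC_X`, `ACC_Y`, `ACC_Z`).
#' @param seed Integer seed for this segment.
#' @param aspects Numeric 5-vector of latent aspect values (thermal
#'   shift, thermal asymmetry, x-asymmetry, y-asymmetry, y-regime
#'   separation); zeros for baseline segments.
#' @return Numeric vector (scalar channels) or n x 3 matrix (ACC) of
#'   samples at the channel\'s device rate.
#' @export
generate_channel <- function(channel, duration_s, flow, intensity, effects,
                             person_offsets, seed, aspects = rep(0, 5)) {
  channel <- match.arg(channel, c("HR", "TEMP", "EDA", "ACC"))
  rate <- e4_channel_rate(channel)
  n <- round(duration_s * rate)
  if (n < 2L) abort_flowsense("segment too short for its channel rate", "flowsense_validation_error")
  set.seed(seed)
  flow <- as.integer(flow)
  # graded flow expression for the direct (non-aspect) responses
  g <- stats::plogis(intensity / 0.7)
  shape_noise <- function() effects$shape_noise_sd * rnorm(1)
  drift <- function(sd) rnorm(1, 0, sd)
  scale_mult <- function() exp(rnorm(1, 0, effects$scale_noise_sd))
  clip_w <- function(w) min(max(w, 0.05), 0.95)

  if (channel == "HR") {
    level <- person_offsets$HR + drift(effects$hr_drift_sd) + g * effects$hr_flow_shift
    return(level + effects$hr_noise_sd * scale_mult() * rnorm(n))
  }
  if (channel == "EDA") {
    level <- person_offsets$EDA + drift(effects$eda_drift_sd) + g * effects$eda_flow_shift
    return(pmax(level + effects$eda_noise_sd * scale_mult() * rnorm(n), 0))
  }
  if (channel == "TEMP") {
    level <- person_offsets$TEMP + drift(effects$temp_drift_sd) +
      g * effects$temp_median_shift
    u <- effects$temp_median_u * exp(rnorm(1, 0, effects$u_jitter))
    w <- clip_w(0.5 + effects$temp_aspect_w * aspects[1] +
                  effects$asym_noise_sd * rnorm(1))
    var_c <- 4 * u^2 * w * (1 - w)
    carrier_m3 <- 8 * u^3 * w * (1 - w) * (1 - 2 * w)
    # skewness channel: rare-tail component sized so the population
    # skewness equals the thermal-asymmetry target, cancelling the median
    # carrier's own skewness; tails keep the median (and, after exact
    # mean-centering, the mean) clean
    g1_t <- -effects$temp_skew * tanh(aspects[2] + shape_noise())
    tail <- solve_tail_skew(g1_t, var_c, carrier_m3)
    dev <- (rnorm(n) + rtwopoint(n, u, w) + rthreepoint(n, tail$p, tail$side)) /
      sqrt(1 + var_c + threepoint_var(tail$p))
    return(level + effects$temp_noise_sd * scale_mult() * dev)
  }
  # ACC: three axes
  s <- effects$acc_noise_sd
  g1_x <- effects$accx_skew * tanh(aspects[3] + shape_noise())
  tail_x <- solve_tail_skew(g1_x, 0, 0)
  x <- person_offsets$ACC_X + drift(effects$acc_drift_sd) +
    s * scale_mult() * (rnorm(n) + rthreepoint(n, tail_x$p, tail_x$side)) /
      sqrt(1 + threepoint_var(tail_x$p))
  # ACC_Y: two-regime mixture solved so its population skewness and
  # excess kurtosis equal the aspect targets
  g1_y <- -effects$accy_asym * tanh(aspects[4] + shape_noise())
  g2_y <- -(0.7 + effects$accy_kurtosis_drop * tanh(aspects[5] + effects$sep_noise_sd * rnorm(1)))
  mix <- solve_mixture(g1_y, g2_y)
  dev_y <- (rnorm(n) + rtwopoint(n, mix$sep, mix$w, center = "median")) /
    sqrt(1 + 4 * mix$sep^2 * mix$w * (1 - mix$w))
  y <- person_offsets$ACC_Y + drift(effects$acc_drift_sd) + s * scale_mult() * dev_y
  z <- person_offsets$ACC_Z + drift(effects$acc_drift_sd) + s * scale_mult() * rnorm(n)
  cbind(x, y, z)
}

draw_person_offsets <- function(effects) {
  list(
    HR = 75 + rnorm(1, 0, effects$hr_between_person_sd),
    TEMP = 33 + rnorm(1, 0, effects$temp_between_person_sd),
    EDA = abs(0.5 + rnorm(1, 0, effects$eda_between_person_sd)),
    ACC_X = rnorm(1, 0, effects$acc_between_person_sd),
    ACC_Y = rnorm(1, 0, effects$acc_between_person_sd),
    ACC_Z = 0.98 + rnorm(1, 0, effects$acc_between_person_sd)
  )
}

draw_task_duration <- function(cfg) {
  lo <- cfg$task_duration_range[1]
  hi <- cfg$task_duration_range[2]
  frac <- (cfg$task_duration_mean - lo) / (hi - lo)
  a <- 1.4
  b <- a * (1 - frac) / frac
  # whole seconds keep segment boundaries aligned with sample indices
  round(lo + (hi - lo) * rbeta(1, a, b))
}

#' Generate a complete synthetic study
#'
#' Produces session records, annotations and ground truth for every
#' participant x activity of the configured design: latent flow intensity
#' per task (person propensity + task draw), a true binary flow label by
#' thresholding the intensity at the configured prevalence, FSS responses
#' from the Rating Scale Model at the intensity-mapped person measure, and
#' physiological channels synthesized segment by segment. Deterministic
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param effects A [flow_effects()] spec.
#' @return A `study_bundle`: `sessions` (list of [session_record()]s),
#'   `truth` (tibble: participant, activity, task, intensity, flow_true,
#'   beta), `config`, `effects`.
#' @export
generate_study <- function(config = generator_config(), effects = flow_effects()) {
  stopifnot(inherits(config, "generator_config"), inherits(effects, "flow_effects"))
  # intensity = person propensity + loading * (sum of 5 aspects) + noise;
  # threshold its marginal distribution at the target prevalence
  # loadings compensate the channels' readout quality (TEMP features
  # are sampling- and drift-limited at 4 Hz) so each aspect carries a
  # comparable share of label information
  asp_w <- c(1.25, 1.25, 0.9, 1.1, 1.05) * config$aspect_loading
  marg_sd <- sqrt(config$flow_person_sd^2 + sum(asp_w^2) +
                    config$intensity_noise_sd^2)
  thr <- stats::qnorm(1 - config$flow_prevalence, 0, marg_sd)
  sessions <- list()
  truth <- list()
  t0 <- 1700000000
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    set.seed(derive_seed(config$seed, p, 1))
    offsets <- draw_person_offsets(effects)
    propensity <- rnorm(1, 0, config$flow_person_sd)
    for (a in seq_len(config$activities_per_participant)) {
      aid <- sprintf("A%d", a)
      set.seed(derive_seed(config$seed, p, a, 2))
      durations <- vapply(seq_len(config$tasks_per_activity), function(i) draw_task_duration(config), numeric(1))
      aspects <- matrix(rnorm(5 * config$tasks_per_activity), ncol = 5)
      intensities <- propensity + drop(aspects %*% asp_w) +
        rnorm(config$tasks_per_activity, 0, config$intensity_noise_sd)
      flows <- as.integer(intensities > thr)
      betas <- config$flow_to_beta[1] + config$flow_to_beta[2] * (intensities - thr)

      segs <- list()
      seg_meta <- list()  # per segment: kind, duration, flow, intensity
      cursor <- 0
      add_seg <- function(kind, dur, task_id = NA, fss = NULL, flow = 0L,
                          intensity = 0, asp = rep(0, 5)) {
        seg <- if (kind == "baseline") {
          segment("baseline", cursor, cursor + dur)
        } else {
          segment("task", cursor, cursor + dur, task_id = task_id, fss_response = fss)
        }
        segs[[length(segs) + 1L]] <<- seg
        seg_meta[[length(seg_meta) + 1L]] <<- list(dur = dur, flow = flow,
                                                   intensity = intensity, asp = asp)
        cursor <<- cursor + dur
      }
      add_seg("baseline", config$baseline_s, intensity = -20)
      for (k in seq_len(config$tasks_per_activity)) {
        tid <- sprintf("%s_T%d", aid, k)
        fss <- generate_fss_responses(
          betas[k], config$rsm_item_difficulties, config$rsm_thresholds,
          seed = derive_seed(config$seed, p, a, k, 3)
        )
        add_seg("task", durations[k], task_id = tid, fss = fss,
                flow = flows[k], intensity = intensities[k] - thr,
                asp = aspects[k, ])
        truth[[length(truth) + 1L]] <- tibble::tibble(
          participant_id = pid, activity_id = aid, task_id = tid,
          intensity = intensities[k], flow_true = flows[k], beta = betas[k],
          duration_s = durations[k]
        )
      }
      add_seg("baseline", config$baseline_s, intensity = -20)

      channels <- lapply(c("HR", "TEMP", "EDA", "ACC"), function(ch) {
        parts <- lapply(seq_along(seg_meta), function(si) {
          m <- seg_meta[[si]]
          generate_channel(ch, m$dur, m$flow, m$intensity, effects, offsets,
                           seed = derive_seed(config$seed, p, a, si, match(ch, c("HR", "TEMP", "EDA", "ACC")), 4),
                           aspects = m$asp)
        })
        vals <- if (ch == "ACC") do.call(rbind, parts) else unlist(parts, use.names = FALSE)
        channel_series(ch, t0 + (p * 100 + a) * 100000, vals)
      })
      names(channels) <- c("HR", "TEMP", "EDA", "ACC")
      sessions[[length(sessions) + 1L]] <- session_record(pid, aid, channels, segs)
    }
  }
  structure(
    list(
      sessions = sessions,
      truth = dplyr::bind_rows(truth),
      config = config, effects = effects
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle: %d sessions, %d tasks (%d flow), seed %d>\n",
    length(x$sessions), nrow(x$truth), sum(x$truth$flow_true), x$config$seed
  ))
  invisible(x)
}

#' Write a study bundle to disk
#'
#' One E4-style session directory per session plus `truth.json`.
#'
#' @param bundle A [generate_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in bundle$sessions) {
    write_e4_session(s, file.path(dir, sprintf("%s_%s", s$participant_id, s$activity_id)))
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
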