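# Two-level forward-stepwise logistic regression: the participant factor is
# forced into the model first; candidate features then enter one at a time
# by smallest likelihood-ratio p-value while p < alpha (default 0.10, the
# 90% confidence entry criterion). Forward-only: entered terms are never
# removed.

#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper over an iteratively reweighted least squares binomial fit
#' that adds the validation, separation detection and the accessors the
#' stepwise layer needs. Standard errors come from the observed
#' information.
#'
#' @param X Numeric design matrix (no intercept column; one is added).
#' @param y Binary 0/1 response.
#' @return A `logistic_fit` object: `coefficients`, `se`, `loglik`,
#'   `converged`, `separation`, `n`, `terms`, `glm` (the underlying fit).
#' @export
fit_logistic_ml <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort_flowsense("y must be binary 0/1", "flowsense_validation_error")
  if (nrow(X) != length(y)) abort_flowsense("X and y sizes differ", "flowsense_validation_error")
  if (ncol(X) > 0) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    const <- apply(X, 2, function(col) stats::var(col) == 0)
    if (any(const)) {
      abort_flowsense(
        paste("constant column(s) in design:", paste(colnames(X)[const], collapse = ", ")),
        "flowsense_rank_error"
      )
    }
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      dependent <- colnames(X)[setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L]
      abort_flowsense(
        paste("rank-deficient design; collinear column(s):", paste(dependent, collapse = ", ")),
        "flowsense_rank_error"
      )
    }
  }
  if (length(y) <= ncol(X) + 1L) {
    abort_flowsense("need more rows than model terms", "flowsense_validation_error")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  form <- if (ncol(X) == 0) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  mu <- stats::fitted(fit)
  separation <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (separation) {
    warn_flowsense("(quasi-)separation detected: estimates and SEs unreliable",
                   "flowsense_separation_warning")
  }
  sm <- summary(fit)
  structure(
    list(
      coefficients = stats::coef(fit),
      se = sm$coefficients[, "Std. Error"],
      loglik = as.numeric(stats::logLik(fit)),
      converged = fit$converged,
      separation = separation,
      n = length(y),
      terms = names(stats::coef(fit)),
      glm = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %d terms, n = %d, logLik = %.3f%s>\n",
              length(x$coefficients), x$n, x$loglik,
              if (x$separation) ", SEPARATION" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param null,alt `logistic_fit` objects on the same rows, with the null
#'   model's terms a subset of the alternative's.
#' @return List: `chisq` = 2 (llik_alt - llik_null), `df`, `p`.
#' @export
likelihood_ratio_test <- function(null, alt) {
  stopifnot(inherits(null, "logistic_fit"), inherits(alt, "logistic_fit"))
  if (null$n != alt$n) abort_flowsense("fits use different rows", "flowsense_validation_error")
  if (!all(null$terms %in% alt$terms)) {
    abort_flowsense("models are not nested (null terms not a subset)", "flowsense_validation_error")
  }
  chisq <- max(2 * (alt$loglik - null$loglik), 0)
  df <- length(alt$terms) - length(null$terms)
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

participant_dummies <- function(participant) {
  f <- factor(participant)
  if (nlevels(f) < 2L) {
    abort_flowsense("need >= 2 participants for the forced factor", "flowsense_validation_error")
  }
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]  # reference-cell coding
  colnames(mm) <- paste0("participant_", levels(f)[-1])
  mm
}

#' Forward-stepwise feature selection with a forced participant factor
#'
#' Starts from the two-level null model (intercept + participant dummies,
#' reference-cell coded). At each step every remaining candidate feature is
#' added one at a time; the candidate with the smallest likelihood-ratio
#' p-value enters if p < `alpha` (ties broken by larger chi-square, then by
#' candidate column order). Stops when no candidate qualifies.
#'
#' @param features Data frame / tibble of candidate feature columns.
#' @param labels Binary 0/1 outcome.
#' @param participant Participant identifier vector (forced factor).
#' @param alpha Entry significance level (default 0.10).
#' @return A `stepwise_result`: `trace` tibble (step, feature, chisq, df,
#'   p), `selected`, `forced_fit`, `final_fit`, `alpha`.
#' @export
forward_stepwise <- function(features, labels, participant, alpha = 0.10) {
  features <- as.data.frame(features, check.names = FALSE)
  if (!(alpha > 0 && alpha < 1)) abort_flowsense("alpha must be in (0,1)", "flowsense_validation_error")
  forced <- participant_dummies(participant)
  current_X <- forced
  current <- fit_logistic_ml(current_X, labels)
  forced_fit <- current
  candidates <- colnames(features)
  trace <- list()
  step_no <- 0L
  while (length(candidates) > 0L) {
    scan <- lapply(candidates, function(fname) {
      alt <- tryCatch(
        fit_logistic_ml(cbind(current_X, stats::setNames(features[fname], fname)), labels),
        flowsense_rank_error = function(e) NULL
      )
      if (is.null(alt)) return(NULL)
      c(likelihood_ratio_test(current, alt), list(fit = alt, feature = fname))
    })
    scan <- Filter(Negate(is.null), scan)
    if (length(scan) == 0L) break
    ps <- vapply(scan, `[[`, numeric(1), "p")
    chis <- vapply(scan, `[[`, numeric(1), "chisq")
    # smallest p, then largest chisq, then candidate order
    best <- order(ps, -chis)[1]
    if (ps[best] >= alpha) break
    step_no <- step_no + 1L
    chosen <- scan[[best]]
    trace[[step_no]] <- tibble::tibble(
      step = step_no, feature = chosen$feature,
      chisq = chosen$chisq, df = chosen$df, p = chosen$p
    )
    current_X <- cbind(current_X, stats::setNames(features[chosen$feature], chosen$feature))
    current <- chosen$fit
    candidates <- setdiff(candidates, chosen$feature)
  }
  structure(
    list(
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble::tibble(step = integer(), feature = character(),
                       chisq = numeric(), df = integer(), p = numeric()),
      selected = if (length(trace)) vapply(trace, function(t) t$feature, character(1)) else character(0),
      forced_fit = forced_fit,
      final_fit = current,
      alpha = alpha
    ),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result: %d feature(s) entered at alpha = %g>\n",
              length(x$selected), x$alpha))
  print(x$trace)
  invisible(x)
}

#' Wald tests and odds ratios for a logistic fit
#'
#' Per term: Wald chi-square `(b / SE)^2` on 1 df, its upper-tail p-value,
#' and the odds ratio `exp(b)`.
#'
#' @param fit A converged, non-separated `logistic_fit`.
#' @return Tibble with columns `term`, `estimate`, `se`, `wald_chisq`, `p`,
#'   `odds_ratio`. Terms with non-finite SE are flagged (`reliable = FALSE`)
#'   and carry no test.
#' @export
wald_summary <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$separation) {
    warn_flowsense("Wald summary on a separated fit: SEs unreliable", "flowsense_separation_warning")
  }
  b <- fit$coefficients
  se <- fit$se
  reliable <- is.finite(se) & se > 0
  chisq <- ifelse(reliable, (b / se)^2, NA_real_)
  tibble::tibble(
    term = names(b), estimate = unname(b), se = unname(se),
    wald_chisq = unname(chisq),
    p = unname(ifelse(reliable, stats::pchisq(chisq, 1, lower.tail = FALSE), NA_real_)),
    odds_ratio = unname(exp(b)),
    reliable = unname(reliable)
  )
}
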