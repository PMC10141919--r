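# Rasch Rating Scale Model (RSM) by joint maximum likelihood.
#
# Model: for person n with measure beta_n, item i with difficulty delta_i
# and shared category thresholds tau_1..tau_M (sum tau = 0, mean delta = 0),
#   P(X_ni = k) = exp(k*(beta_n - delta_i) - sum_{j<=k} tau_j) / psi_ni,
# k = 0..M, with the empty sum for k = 0. All quantities live on a common
# logit scale.

#' RSM category probabilities
#'
#' @param beta Person measure (scalar or vector).
#' @param delta Item difficulty (scalar).
#' @param tau Threshold vector tau_1..tau_M, sum(tau) = 0.
#' @return Matrix `length(beta)` x `M+1` of category probabilities.
#' @export
rsm_category_probs <- function(beta, delta, tau) {
  if (abs(sum(tau)) > 1e-8) {
    abort_flowsense("thresholds tau must sum to 0", "flowsense_validation_error")
  }
  M <- length(tau)
  ct <- c(0, cumsum(tau))            # cumulative thresholds, k = 0..M
  eta <- outer(beta - delta, 0:M) - matrix(ct, length(beta), M + 1, byrow = TRUE)
  eta <- eta - apply(eta, 1, max)    # guard overflow
  p <- exp(eta)
  p / rowSums(p)
}

# probability array P[n, i, k+1] for beta (N), delta (I), tau (M)
rsm_prob_array <- function(beta, delta, tau) {
  N <- length(beta); I <- length(delta); M <- length(tau)
  ct <- c(0, cumsum(tau))
  k <- 0:M
  # eta[n,i,k] = k*(beta_n - delta_i) - ct[k], flattened to (N*I) x (M+1)
  bd <- as.vector(outer(beta, delta, `-`))
  eta <- outer(bd, k) - rep(ct, each = N * I)
  eta <- eta - do.call(pmax, as.data.frame(eta))
  p <- exp(eta)
  p <- p / rowSums(p)
  array(p, dim = c(N, I, M + 1L))
}

rsm_moments <- function(P) {
  d <- dim(P)
  k <- 0:(d[3] - 1L)
  Pm <- matrix(P, d[1] * d[2], d[3])
  E <- matrix(Pm %*% k, d[1], d[2])
  E2 <- matrix(Pm %*% k^2, d[1], d[2])
  list(E = E, W = pmax(E2 - E^2, 0))
}

#' RSM expected item score
#'
#' @inheritParams rsm_category_probs
#' @return Expected score `sum_k k P(X = k)` for each element of `beta`.
#' @export
rsm_expected_score <- function(beta, delta, tau) {
  P <- rsm_category_probs(beta, delta, tau)
  drop(P %*% (0:length(tau)))
}

# solve sum_i E(beta | delta_i, tau) = target by Newton (for extreme rows)
solve_beta_for_score <- function(target, delta, tau, tol = 1e-8, max_iter = 100) {
  beta <- 0
  for (it in seq_len(max_iter)) {
    P <- rsm_prob_array(beta, delta, tau)
    mo <- rsm_moments(P)
    f <- sum(mo$E) - target
    df <- sum(mo$W)
    step <- f / max(df, 1e-10)
    step <- sign(step) * min(abs(step), 2)
    beta <- beta - step
    if (abs(step) < tol) break
  }
  beta
}

#' Fit the Rating Scale Model by joint maximum likelihood
#'
#' Alternating damped Newton updates of person measures, item difficulties
#' and shared thresholds under the constraints mean(delta) = 0 and
#' sum(tau) = 0. Persons or items with extreme (all-minimum or all-maximum)
#' raw scores carry no information about their own parameter and are
#' excluded from estimation; they receive finite measures via the
#' conventional fractional score-point adjustment (default 0.25) and are
#' flagged.
#'
#' @param responses Integer matrix, persons x items, entries 0..M. Column
#'   names identify the items (defaults to the nine flow elements when the
#'   matrix has 9 unnamed columns).
#' @param m_categories Highest category M (default 4). Unobserved
#'   categories are collapsed with a warning.
#' @param tol Convergence tolerance, logits (default 1e-4).
#' @param max_iter Maximum alternating iterations (default 200).
#' @param extreme_adjust Score-point adjustment for extreme scores.
#' @param bias_correct Apply the (L-1)/L joint-likelihood shrinkage to item
#'   difficulties (off by default).
#' @return An `rsm_fit` object: `beta`, `se_beta`, `delta`, `se_delta`,
#'   `tau`, `se_tau`, `loglik`, `iterations`, `converged`,
#'   `extreme_persons`, `extreme_items`, `m_categories`, `category_map`.
#' @export
fit_rsm <- function(responses, m_categories = 4L, tol = 1e-4, max_iter = 200L,
                    extreme_adjust = 0.25, bias_correct = FALSE) {
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  if (anyNA(X)) abort_flowsense("missing responses are not supported", "flowsense_validation_error")
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) == 9L) FSS_ITEMS else paste0("item_", seq_len(ncol(X)))
  }
  if (is.null(rownames(X))) rownames(X) <- paste0("row_", seq_len(nrow(X)))
  if (any(X < 0L) || any(X > m_categories)) {
    abort_flowsense(sprintf("responses must lie in 0..%d", m_categories), "flowsense_validation_error")
  }

  # collapse unobserved categories so every scored category occurs
  observed <- sort(unique(as.vector(X)))
  category_map <- NULL
  if (!identical(observed, 0:m_categories)) {
    warn_flowsense(
      sprintf("categories {%s} unobserved; collapsing to %d contiguous categories",
              paste(setdiff(0:m_categories, observed), collapse = ","), length(observed)),
      "flowsense_category_collapse_warning"
    )
    category_map <- stats::setNames(seq_along(observed) - 1L, observed)
    X <- matrix(category_map[as.character(X)], nrow(X), ncol(X),
                dimnames = dimnames(X))
    m_categories <- length(observed) - 1L
  }
  M <- m_categories
  if (M < 1L) abort_flowsense("all responses identical; model unidentifiable", "flowsense_unidentifiable_error")

  max_row <- M * ncol(X)
  r <- rowSums(X)
  extreme_rows <- r == 0L | r == max_row
  s <- colSums(X)
  extreme_cols <- s == 0L | s == M * nrow(X)
  if (all(extreme_rows)) {
    abort_flowsense("every person has an extreme score; model unidentifiable",
                    "flowsense_unidentifiable_error")
  }
  Xe <- X[!extreme_rows, !extreme_cols, drop = FALSE]
  if (nrow(Xe) < 2L || ncol(Xe) < 2L) {
    abort_flowsense("need >= 2 non-extreme persons and items", "flowsense_unidentifiable_error")
  }
  N <- nrow(Xe); I <- ncol(Xe)
  rn <- rowSums(Xe); si <- colSums(Xe)

  # logit-of-proportion starting values
  beta <- log((rn + 0.5) / (M * I - rn + 0.5))
  p_i <- si / (M * N)
  delta <- -log((p_i + 1e-3) / (1 - p_i + 1e-3))
  delta <- delta - mean(delta)
  tau <- seq(-1, 1, length.out = M)
  tau <- tau - mean(tau)

  damp <- function(step, cap = 1) sign(step) * pmin(abs(step), cap)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    P <- rsm_prob_array(beta, delta, tau)
    mo <- rsm_moments(P)
    step_b <- damp((rn - rowSums(mo$E)) / pmax(rowSums(mo$W), 1e-10))
    beta_new <- beta + step_b

    P <- rsm_prob_array(beta_new, delta, tau)
    mo <- rsm_moments(P)
    step_d <- damp((colSums(mo$E) - si) / pmax(colSums(mo$W), 1e-10))
    delta_new <- delta + step_d
    delta_new <- delta_new - mean(delta_new)

    P <- rsm_prob_array(beta_new, delta_new, tau)
    K <- dim(P)[3]
    Pm <- matrix(P, N * I, K)
    step_t <- numeric(M)
    for (j in seq_len(M)) {
      q <- rowSums(Pm[, (j + 1):K, drop = FALSE])  # P(X >= j)
      score <- sum(q) - sum(Xe >= j)
      info <- sum(q * (1 - q))
      step_t[j] <- damp(score / max(info, 1e-10))
    }
    tau_new <- tau + step_t
    tau_new <- tau_new - mean(tau_new)

    delta_max <- max(abs(beta_new - beta), abs(delta_new - delta), abs(tau_new - tau))
    beta <- beta_new; delta <- delta_new; tau <- tau_new
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort_flowsense(
      sprintf("RSM estimation did not converge in %d iterations (last max step %.3g)",
              max_iter, delta_max),
      "flowsense_convergence_error", last_delta = delta_max
    )
  }
  if (bias_correct) {
    delta <- delta * (I - 1) / I
    beta <- beta * (I - 1) / I
  }

  P <- rsm_prob_array(beta, delta, tau)
  mo <- rsm_moments(P)
  se_beta <- 1 / sqrt(rowSums(mo$W))
  se_delta <- 1 / sqrt(colSums(mo$W))
  Pm <- matrix(P, N * I, M + 1L)
  se_tau <- vapply(seq_len(M), function(j) {
    q <- rowSums(Pm[, (j + 1):(M + 1), drop = FALSE])
    1 / sqrt(sum(q * (1 - q)))
  }, numeric(1))
  K <- 0:M
  ll <- sum(log(vapply(seq_len(N), function(n) {
    prod(P[cbind(n, seq_len(I), Xe[n, ] + 1L)])
  }, numeric(1))))

  # finite measures for extreme persons via fractional-score adjustment
  beta_all <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
  se_all <- beta_all
  beta_all[rownames(Xe)] <- beta
  se_all[rownames(Xe)] <- se_beta
  for (nm in rownames(X)[extreme_rows]) {
    rr <- sum(X[nm, !extreme_cols])
    target <- if (rr == 0L) extreme_adjust else M * I - extreme_adjust
    b <- solve_beta_for_score(target, delta, tau)
    w <- rsm_moments(rsm_prob_array(b, delta, tau))$W
    beta_all[nm] <- b
    se_all[nm] <- 1 / sqrt(sum(w))
  }
  delta_all <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  sed_all <- delta_all
  delta_all[colnames(Xe)] <- delta
  sed_all[colnames(Xe)] <- se_delta

  structure(
    list(
      beta = beta_all, se_beta = se_all,
      delta = delta_all, se_delta = sed_all,
      tau = tau, se_tau = se_tau,
      loglik = ll, iterations = iterations, converged = converged,
      extreme_persons = rownames(X)[extreme_rows],
      extreme_items = colnames(X)[extreme_cols],
      m_categories = M, category_map = category_map,
      responses = X
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf(
    "<rsm_fit: %d persons (%d extreme), %d items, M=%d; logLik %.2f, %d iterations>\n",
    length(x$beta), length(x$extreme_persons), length(x$delta), x$m_categories,
    x$loglik, x$iterations
  ))
  cat("item difficulties (logits):\n")
  print(round(sort(x$delta), 3))
  invisible(x)
}

# E, W, z over the non-extreme block of a fit
rsm_residual_block <- function(fit) {
  keep_r <- setdiff(names(fit$beta), fit$extreme_persons)
  keep_c <- setdiff(names(fit$delta), fit$extreme_items)
  X <- fit$responses[keep_r, keep_c, drop = FALSE]
  P <- rsm_prob_array(fit$beta[keep_r], fit$delta[keep_c], fit$tau)
  mo <- rsm_moments(P)
  z <- (X - mo$E) / sqrt(pmax(mo$W, 1e-12))
  list(X = X, E = mo$E, W = mo$W, z = z)
}

#' Infit and outfit mean-square statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals
#' (outlier-sensitive); infit is information-weighted:
#' `sum((x - E)^2) / sum(W)`. Both have expectation 1 under the model;
#' values above 1.5 flag an item or person whose responses fit worse than
#' the model expects.
#'
#' @param fit A converged [fit_rsm()] result.
#' @param misfit_threshold Mean-square value above which an item or person
#'   is reported as misfitting (default 1.5).
#' @return A `fit_stats` object with tibbles `items` and `persons`
#'   (columns `infit`, `outfit`, `misfit`) and matrices `E`, `W`, `z`.
#' @export
person_item_fit <- function(fit, misfit_threshold = 1.5) {
  stopifnot(inherits(fit, "rsm_fit"), isTRUE(fit$converged))
  blk <- rsm_residual_block(fit)
  zero_w <- blk$W <= 1e-12
  if (any(zero_w)) {
    warn_flowsense(sprintf("%d cell(s) with zero model variance excluded from fit sums", sum(zero_w)),
                   "flowsense_zero_variance_warning")
  }
  z2 <- blk$z^2
  z2[zero_w] <- NA
  sqres <- (blk$X - blk$E)^2
  sqres[zero_w] <- NA
  W <- blk$W
  W[zero_w] <- NA

  item_out <- colMeans(z2, na.rm = TRUE)
  item_in <- colSums(sqres, na.rm = TRUE) / colSums(W, na.rm = TRUE)
  pers_out <- rowMeans(z2, na.rm = TRUE)
  pers_in <- rowSums(sqres, na.rm = TRUE) / rowSums(W, na.rm = TRUE)

  structure(
    list(
      items = tibble::tibble(
        item = colnames(blk$X), infit = unname(item_in), outfit = unname(item_out),
        misfit = unname(item_in > misfit_threshold | item_out > misfit_threshold)
      ),
      persons = tibble::tibble(
        person = rownames(blk$X), infit = unname(pers_in), outfit = unname(pers_out),
        misfit = unname(pers_in > misfit_threshold | pers_out > misfit_threshold)
      ),
      E = blk$E, W = blk$W, z = blk$z
    ),
    class = "fit_stats"
  )
}

#' Principal components of model residuals
#'
#' Eigen-decomposition of the item-by-item correlation matrix of the
#' standardized residuals. Eigenvalues are in "item units" (they sum to the
#' number of retained items); a first eigenvalue below 2 is read as random
#' residuals, i.e. conformity with unidimensionality.
#'
#' @param fitstats Result of [person_item_fit()].
#' @param eigen_cutoff Unidimensionality cutoff (default 2).
#' @return List: `eigenvalues`, `loadings` (items on the first residual
#'   component), `unidimensional`, `dropped_items`.
#' @export
residual_pca <- function(fitstats, eigen_cutoff = 2) {
  stopifnot(inherits(fitstats, "fit_stats"))
  z <- fitstats$z
  if (ncol(z) < 2L) abort_flowsense("need >= 2 items for residual PCA", "flowsense_validation_error")
  sds <- apply(z, 2, stats::sd)
  constant <- sds <= 1e-12 | !is.finite(sds)
  if (any(constant)) {
    warn_flowsense(
      paste("constant residual column(s) excluded from PCA:",
            paste(colnames(z)[constant], collapse = ", ")),
      "flowsense_constant_residual_warning"
    )
    z <- z[, !constant, drop = FALSE]
  }
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  load1 <- eig$vectors[, 1] * sqrt(eig$values[1])
  # orient so the largest-magnitude loading is positive
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  list(
    eigenvalues = eig$values,
    loadings = stats::setNames(load1, colnames(z)),
    unidimensional = eig$values[1] < eigen_cutoff,
    dropped_items = colnames(fitstats$z)[constant]
  )
}

#' Person and item separation reliability
#'
#' `(observed variance of measures - mean squared SE) / observed variance`,
#' clipped to `[0, 1]`; the proportion of the observed spread of measures
#' that is not attributable to estimation error. Extreme persons/items are
#' excluded.
#'
#' @param fit A [fit_rsm()] result.
#' @return List with `person_reliability` and `item_reliability`.
#' @export
separation_reliability <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  rel <- function(measure, se) {
    if (length(measure) < 2L) return(NA_real_)
    v <- stats::var(measure)
    if (v <= 0) {
      warn_flowsense("zero variance of measures; reliability 0", "flowsense_zero_variance_warning")
      return(0)
    }
    min(max((v - mean(se^2)) / v, 0), 1)
  }
  keep_p <- setdiff(names(fit$beta), fit$extreme_persons)
  keep_i <- setdiff(names(fit$delta), fit$extreme_items)
  list(
    person_reliability = rel(fit$beta[keep_p], fit$se_beta[keep_p]),
    item_reliability = rel(fit$delta[keep_i], fit$se_delta[keep_i])
  )
}

#' Wright map table
#'
#' Person measures and item difficulties on the common logit scale, as a
#' tidy table suitable for a person-item map. An item's difficulty marks
#' the scale point where a person is equally likely to give the lowest and
#' the highest rating for that flow element. Items are sorted by
#' difficulty.
#'
#' @param fit A [fit_rsm()] result.
#' @return Tibble with columns `type` ("person"/"item"), `id`, `measure`,
#'   `se`, `extreme`.
#' @export
wright_map <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  items <- tibble::tibble(
    type = "item", id = names(fit$delta), measure = unname(fit$delta),
    se = unname(fit$se_delta), extreme = names(fit$delta) %in% fit$extreme_items
  )
  items <- items[order(items$measure), ]
  persons <- tibble::tibble(
    type = "person", id = names(fit$beta), measure = unname(fit$beta),
    se = unname(fit$se_beta), extreme = names(fit$beta) %in% fit$extreme_persons
  )
  dplyr::bind_rows(persons, items)
}

#' Plot a Wright map
#'
#' @param fit A [fit_rsm()] result.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_wright_map <- function(fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_flowsense("ggplot2 is required for plotting", "flowsense_validation_error")
  }
  tab <- wright_map(fit)
  ggplot2::ggplot(tab, ggplot2::aes(x = type, y = measure)) +
    ggplot2::geom_jitter(data = tab[tab$type == "person", ], width = 0.08, alpha = 0.6) +
    ggplot2::geom_point(data = tab[tab$type == "item", ], size = 2) +
    ggplot2::geom_text(
      data = tab[tab$type == "item", ],
      ggplot2::aes(label = id), hjust = -0.1, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "measure (logits)", title = "Person-item map") +
    ggplot2::theme_minimal()
}
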