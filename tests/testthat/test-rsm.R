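# Independent joint log-likelihood of the Rating Scale Model, written
# directly from the category-probability definition (no shared code with
# the fitter's internals beyond rsm_category_probs' algebra).
rsm_joint_loglik <- function(X, beta, delta, tau) {
  ll <- 0
  M <- length(tau)
  ct <- c(0, cumsum(tau))
  for (n in seq_len(nrow(X))) {
    for (i in seq_len(ncol(X))) {
      eta <- (0:M) * (beta[n] - delta[i]) - ct
      ll <- ll + eta[X[n, i] + 1] - log(sum(exp(eta)))
    }
  }
  ll
}

# coordinate-wise grid-search maximizer of the same joint likelihood,
# independent of the Newton fitter
grid_maximize_rsm <- function(X, M, sweeps = 60, span = 4, step0 = 0.5) {
  N <- nrow(X); I <- ncol(X)
  beta <- rep(0, N); delta <- rep(0, I); tau <- seq(-1, 1, length.out = M)
  tau <- tau - mean(tau)
  step <- step0
  for (sw in seq_len(sweeps)) {
    for (n in seq_len(N)) {
      cand <- beta[n] + step * (-4:4)
      lls <- vapply(cand, function(b) {
        bb <- beta; bb[n] <- b; rsm_joint_loglik(X, bb, delta, tau)
      }, numeric(1))
      beta[n] <- cand[which.max(lls)]
    }
    for (i in seq_len(I)) {
      cand <- delta[i] + step * (-4:4)
      lls <- vapply(cand, function(d) {
        dd <- delta; dd[i] <- d; rsm_joint_loglik(X, beta, dd, tau)
      }, numeric(1))
      delta[i] <- cand[which.max(lls)]
    }
    ctr <- mean(delta); delta <- delta - ctr; beta <- beta - ctr
    for (j in seq_len(M - 1)) {
      cand <- tau[j] + step * (-4:4)
      lls <- vapply(cand, function(t) {
        tt <- tau; tt[j] <- t; tt[M] <- -sum(tt[-M])
        rsm_joint_loglik(X, beta, delta, tt)
      }, numeric(1))
      tau[j] <- cand[which.max(lls)]
      tau[M] <- -sum(tau[-M])
    }
    step <- max(step * 0.8, 0.002)
  }
  list(beta = beta, delta = delta, tau = tau,
       loglik = rsm_joint_loglik(X, beta, delta, tau))
}

test_that("category probabilities are a proper distribution and symmetric at beta = delta", {
  tau <- c(-1.2, -0.3, 0.3, 1.2)
  p <- rsm_category_probs(seq(-3, 3, by = 0.5), 0.7, tau)
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_true(all(p > 0))
  # at beta = delta (with sum(tau) = 0) the extreme categories are equally likely
  p0 <- rsm_category_probs(0.7, 0.7, tau)
  expect_equal(p0[1], p0[length(p0)])
})

test_that("the expected score is strictly increasing in the person measure", {
  beta <- seq(-5, 5, by = 0.1)
  es <- rsm_expected_score(beta, 0.3, c(-1.5, -0.5, 0.5, 1.5))
  expect_true(all(diff(es) > 0))
  expect_equal(rsm_expected_score(0.3, 0.3, c(-2, 0, 2) - 0), 1.5)  # M/2 at beta = delta
})

test_that("persons with identical response vectors get identical measures", {
  X <- rbind(
    c(0, 1, 2), c(0, 1, 2), c(2, 2, 1), c(1, 0, 0), c(2, 1, 2), c(1, 2, 0)
  )
  fit <- fit_rsm(X, m_categories = 2)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[1]), unname(fit$beta[2]), tolerance = 1e-6)
})

test_that("JMLE estimates agree with an independent grid-search maximizer", {
  set.seed(7)
  X <- rbind(
    c(0, 1, 2), c(1, 1, 2), c(2, 2, 1), c(1, 0, 0), c(2, 1, 0)
  )
  fit <- fit_rsm(X, m_categories = 2, tol = 1e-7)
  grid <- grid_maximize_rsm(X, M = 2)
  keep <- setdiff(rownames(fit$responses), fit$extreme_persons)
  ll_fit <- rsm_joint_loglik(X, unname(fit$beta[keep]), unname(fit$delta), fit$tau)
  # the two maximizers find the same optimum of the same likelihood
  expect_equal(ll_fit, grid$loglik, tolerance = 1e-2)
  expect_equal(unname(fit$delta), grid$delta, tolerance = 5e-2)
  expect_equal(fit$tau, grid$tau, tolerance = 5e-2)
  expect_equal(unname(fit$beta[keep]), grid$beta, tolerance = 5e-2)
})

test_that("extreme scores are excluded, flagged and given finite adjusted measures", {
  set.seed(8)
  X <- simulate_fss(20, beta = rnorm(20), seed = 3)
  X[1, ] <- 4L  # all-maximum person
  X[2, ] <- 0L  # all-minimum person
  fit <- fit_rsm(X)
  expect_setequal(fit$extreme_persons, c("row_1", "row_2"))
  expect_true(is.finite(fit$beta["row_1"]))
  keep <- setdiff(names(fit$beta), fit$extreme_persons)
  expect_gt(fit$beta["row_1"], max(fit$beta[keep]))
  expect_lt(fit$beta["row_2"], min(fit$beta[keep]))
})

test_that("unidentifiable inputs raise diagnostic errors", {
  expect_error(fit_rsm(matrix(4L, 5, 9)), class = "flowsense_unidentifiable_error")
  suppressWarnings(expect_error(
    fit_rsm(rbind(rep(0L, 9), rep(4L, 9), rep(0L, 9))),
    class = "flowsense_unidentifiable_error"
  ))
})

test_that("unobserved categories are collapsed with a warning", {
  set.seed(9)
  X <- matrix(sample(c(0L, 1L, 3L, 4L), 180, replace = TRUE), 20, 9)  # category 2 absent
  expect_warning(fit <- fit_rsm(X), class = "flowsense_category_collapse_warning")
  expect_equal(fit$m_categories, 3)
  expect_true(fit$converged)
})

test_that("parameters are recovered from simulated data at N = 200", {
  delta <- default_item_difficulties()
  tau <- c(-1.5, -0.5, 0.5, 1.5)
  X <- simulate_fss(200, seed = 21)
  beta_true <- attr(X, "beta")
  fit <- fit_rsm(X)
  keep <- setdiff(names(fit$beta), fit$extreme_persons)
  idx <- match(keep, rownames(fit$responses))
  expect_gte(cor(unname(fit$delta[names(delta)]), unname(delta)), 0.9)
  expect_gte(cor(unname(fit$beta[keep]), beta_true[idx]), 0.85)
})

test_that("refitting shifted data returns the same centered estimates", {
  X <- simulate_fss(60, seed = 33)
  f1 <- fit_rsm(X)
  # shifting all abilities and difficulties by a constant is unidentifiable;
  # the centering constraints must pin the same solution on a refit
  f2 <- fit_rsm(X, tol = 1e-6)
  expect_equal(unname(f1$delta), unname(f2$delta), tolerance = 1e-3)
  expect_equal(mean(f1$delta), 0, tolerance = 1e-8)
  expect_equal(sum(f1$tau), 0, tolerance = 1e-8)
})

test_that("infit and outfit sit near 1 for model-generated data", {
  X <- simulate_fss(500, seed = 5)
  fit <- fit_rsm(X)
  fs <- person_item_fit(fit)
  expect_true(all(fs$items$infit > 0.8 & fs$items$infit < 1.2))
  expect_true(all(fs$items$outfit > 0.8 & fs$items$outfit < 1.2))
  expect_false(any(fs$items$misfit))
})

test_that("a deterministic item tracking the model expectation overfits (outfit < 1)", {
  # deterministic responding graded along the latent scale: every response
  # equals the rounded model-expected score, i.e. zero response noise
  set.seed(6)
  X <- simulate_fss(300, seed = 11)
  beta_true <- attr(X, "beta")
  delta <- default_item_difficulties()
  tau <- c(-1.5, -0.5, 0.5, 1.5)
  X[, 5] <- as.integer(round(rsm_expected_score(beta_true, delta[[5]], tau)))
  fit <- fit_rsm(X)
  fs <- person_item_fit(fit)
  expect_lt(fs$items$outfit[5], 1)
  expect_lt(fs$items$infit[5], 1)
})

test_that("mean squares above 1.5 are flagged as misfit", {
  set.seed(12)
  X <- simulate_fss(300, seed = 13)
  X[, 3] <- sample(0:4, 300, replace = TRUE)  # noise item, ignores the construct
  fit <- fit_rsm(X)
  fs <- person_item_fit(fit)
  expect_true(fs$items$misfit[3])
  expect_gt(max(fs$items$infit[3], fs$items$outfit[3]), 1.5)
})

test_that("residual eigenvalues sum to the item count and verdicts hold", {
  X <- simulate_fss(400, seed = 17)
  fs <- person_item_fit(fit_rsm(X))
  pca <- residual_pca(fs)
  expect_equal(sum(pca$eigenvalues), 9)
  expect_false(is.unsorted(rev(pca$eigenvalues)))
  expect_true(pca$unidimensional)
})

test_that("model-conforming data pass the eigenvalue-2 rule in most replicates", {
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    X <- simulate_fss(500, seed = 1000 + r)
    pca <- residual_pca(person_item_fit(fit_rsm(X)))
    hits <- hits + (pca$eigenvalues[1] < 2)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("a planted second dimension loads its items together on component 1", {
  set.seed(19)
  n <- 400
  X <- simulate_fss(n, seed = 23)
  nuisance <- rnorm(n)
  for (j in 1:3) {
    shift <- as.integer(nuisance > 0) * 2L - 1L
    X[, j] <- pmin(pmax(X[, j] + shift, 0L), 4L)
  }
  pca <- residual_pca(person_item_fit(fit_rsm(X)))
  expect_false(pca$unidimensional)
  loads <- pca$loadings[colnames(X)]
  top3 <- names(sort(abs(loads), decreasing = TRUE))[1:3]
  expect_setequal(top3, colnames(X)[1:3])
  expect_true(all(sign(loads[top3]) == sign(loads[top3][1])))
})

test_that("separation reliability behaves at its limits and is stable", {
  fit <- fit_rsm(simulate_fss(300, seed = 29))
  rel <- separation_reliability(fit)
  expect_true(rel$person_reliability > 0 && rel$person_reliability <= 1)
  # limit checks on the formula via a minimal synthetic fit object
  toy <- fit
  keep <- setdiff(names(toy$beta), toy$extreme_persons)
  toy$se_beta[keep] <- 1e-9
  expect_equal(separation_reliability(toy)$person_reliability, 1, tolerance = 1e-6)
  toy$se_beta[keep] <- stats::sd(toy$beta[keep])
  expect_lt(separation_reliability(toy)$person_reliability, 0.05)
  # replicate stability within 0.1
  r1 <- separation_reliability(fit_rsm(simulate_fss(500, seed = 31)))$person_reliability
  r2 <- separation_reliability(fit_rsm(simulate_fss(500, seed = 37)))$person_reliability
  expect_lt(abs(r1 - r2), 0.1)
})

test_that("the Wright map sorts items by difficulty on the common scale", {
  X <- simulate_fss(200, seed = 41)
  fit <- fit_rsm(X)
  map <- wright_map(fit)
  items <- map[map$type == "item", ]
  expect_false(is.unsorted(items$measure))
  expect_equal(nrow(map), length(fit$beta) + 9)
  # the hardest generating item is recovered at the top of the hierarchy
  expect_equal(items$id[nrow(items)], "transformation_of_time")
})

test_that("flow labels follow the transformation-of-time endorsement rule", {
  X <- rbind(rep(3L, 9), rep(2L, 9), rep(0L, 9), rep(4L, 9))
  colnames(X) <- flowsense:::FSS_ITEMS
  expect_equal(label_flow(X), c(1L, 0L, 0L, 1L))
  X2 <- X[, -8]
  expect_error(label_flow(X2), class = "flowsense_validation_error")
})
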