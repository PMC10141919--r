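# brute-force maximizer of a 2-parameter logistic likelihood (intercept +
# one slope) on a grid, as an independent oracle
grid_logistic_loglik <- function(x, y) {
  best <- -Inf
  for (b0 in seq(-3, 3, by = 0.02)) {
    for (b1 in seq(-4, 4, by = 0.02)) {
      eta <- b0 + b1 * x
      ll <- sum(y * eta - log1p(exp(eta)))
      if (ll > best) best <- ll
    }
  }
  best
}

test_that("the intercept-only fit reproduces the log-odds closed form", {
  y <- c(rep(1, 22), rep(0, 38))
  fit <- fit_logistic_ml(matrix(numeric(0), 60, 0), y)
  expect_equal(unname(fit$coefficients[1]), log(22 / 38), tolerance = 1e-6)
  expect_equal(fit$n, 60)
})

test_that("a null predictor gets a near-zero coefficient at n = 1000", {
  set.seed(14)
  x <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x"))
  y <- rbinom(1000, 1, 0.4)
  fit <- fit_logistic_ml(x, y)
  expect_lt(abs(fit$coefficients["x"]), 0.2)
  expect_false(fit$separation)
})

test_that("perfect separation is detected and warned", {
  x <- matrix(c(1:5, 11:15), ncol = 1, dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 5)
  expect_warning(fit <- fit_logistic_ml(x, y), class = "flowsense_separation_warning")
  expect_true(fit$separation)
})

test_that("degenerate designs raise rank errors naming the columns", {
  set.seed(15)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  y <- rbinom(30, 1, 0.5)
  expect_error(fit_logistic_ml(X, y), class = "flowsense_rank_error")
  expect_error(fit_logistic_ml(cbind(k = rep(1, 30)), y), class = "flowsense_rank_error")
})

test_that("the likelihood-ratio test matches its definition and a grid oracle", {
  set.seed(16)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.5 + 0.8 * x))
  null <- fit_logistic_ml(matrix(numeric(0), 40, 0), y)
  alt <- fit_logistic_ml(matrix(x, dimnames = list(NULL, "x")), y)
  lr <- likelihood_ratio_test(null, alt)
  expect_gte(lr$chisq, 0)
  expect_equal(lr$df, 1)
  # same fit twice: chisq 0, p 1
  self <- likelihood_ratio_test(alt, alt)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)
  # chi-square upper tail: 3.84 on 1 df is the 5% point
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # alt log-likelihood equals an independent grid maximization
  expect_equal(alt$loglik, grid_logistic_loglik(x, y), tolerance = 1e-4)
  # non-nested inputs refused
  z <- fit_logistic_ml(matrix(rnorm(40), dimnames = list(NULL, "z")), y)
  expect_error(likelihood_ratio_test(z, alt), class = "flowsense_validation_error")
})

test_that("adding a column never decreases the maximized log-likelihood (property)", {
  set.seed(17)
  for (r in 1:5) {
    X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(50, 1, plogis(X[, 1]))
    f2 <- fit_logistic_ml(X[, 1:2], y)
    f3 <- fit_logistic_ml(X, y)
    expect_gte(f3$loglik + 1e-8, f2$loglik)
  }
})

test_that("a planted strong feature enters at step one (exhaustive scan oracle)", {
  set.seed(18)
  n <- 60
  participant <- rep(sprintf("P%d", 1:5), each = 12)
  feats <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(feats) <- sprintf("f%02d", 1:10)
  y <- rbinom(n, 1, plogis(2 * feats$f07))
  sw <- forward_stepwise(feats, y, participant)
  expect_equal(sw$trace$feature[1], "f07")
  # oracle: exhaustive single-candidate scan picks the same first entry
  forced <- flowsense:::participant_dummies(participant)
  base <- fit_logistic_ml(forced, y)
  ps <- vapply(names(feats), function(f) {
    alt <- fit_logistic_ml(cbind(forced, setNames(feats[f], f)), y)
    likelihood_ratio_test(base, alt)$p
  }, numeric(1))
  expect_equal(names(which.min(ps)), "f07")
})

test_that("stepwise respects the entry level and stops on null candidates", {
  set.seed(19)
  n <- 60
  participant <- rep(sprintf("P%d", 1:5), each = 12)
  feats <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(feats) <- sprintf("f%02d", 1:30)
  y <- rbinom(n, 1, 0.37)
  # with 30 null candidates, about 3 pass the 10% screen at step one
  n_screen <- vapply(1:10, function(r) {
    set.seed(100 + r)
    feats_r <- as.data.frame(matrix(rnorm(n * 30), n, 30))
    names(feats_r) <- names(feats)
    y_r <- rbinom(n, 1, 0.37)
    sw <- suppressWarnings(forward_stepwise(feats_r, y_r, participant))
    expect_true(all(sw$trace$p < 0.10))
    expect_lt(length(sw$selected), 15)
    forced <- flowsense:::participant_dummies(participant)
    base <- fit_logistic_ml(forced, y_r)
    ps <- vapply(names(feats_r), function(f) {
      alt <- fit_logistic_ml(cbind(forced, setNames(feats_r[f], f)), y_r)
      likelihood_ratio_test(base, alt)$p
    }, numeric(1))
    sum(ps < 0.10)
  }, numeric(1))
  expect_gt(mean(n_screen), 0.5)
  expect_lt(mean(n_screen), 7)
  # deterministic given the data
  set.seed(101)
  feats_r <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(feats_r) <- names(feats)
  y_r <- rbinom(n, 1, 0.37)
  s1 <- suppressWarnings(forward_stepwise(feats_r, y_r, participant))
  s2 <- suppressWarnings(forward_stepwise(feats_r, y_r, participant))
  expect_identical(s1$trace, s2$trace)
})

test_that("with no qualifying candidate the forced model is returned", {
  set.seed(20)
  participant <- rep(c("A", "B"), each = 10)
  feats <- data.frame(f1 = rep(0.001 * (1:20)))   # essentially uninformative
  y <- rep(c(0, 1), 10)
  sw <- forward_stepwise(feats, y, participant, alpha = 1e-6)
  expect_equal(nrow(sw$trace), 0)
  expect_equal(length(sw$selected), 0)
  expect_equal(sw$final_fit$loglik, sw$forced_fit$loglik)
  expect_error(forward_stepwise(feats, y, rep("A", 20)),
               class = "flowsense_validation_error")
})

test_that("Wald summaries reproduce the odds-ratio arithmetic", {
  fit <- structure(
    list(
      coefficients = c(`(Intercept)` = 0.1, median_diff_TEMP = 2.33,
                       skewness_TEMP = -2.58, kurtosis_ACC_Y = -0.300, null = 0),
      se = c(0.5, 1.26, 0.969, 0.112, 1),
      loglik = -20, converged = TRUE, separation = FALSE, n = 60,
      terms = c("(Intercept)", "median_diff_TEMP", "skewness_TEMP",
                "kurtosis_ACC_Y", "null"),
      glm = NULL
    ),
    class = "logistic_fit"
  )
  ws <- wald_summary(fit)
  expect_equal(ws$odds_ratio[ws$term == "kurtosis_ACC_Y"], 0.741, tolerance = 3e-3)
  expect_equal(ws$odds_ratio[ws$term == "median_diff_TEMP"], 10.3, tolerance = 3e-3)
  expect_equal(ws$odds_ratio[ws$term == "skewness_TEMP"], 0.0756, tolerance = 3e-3)
  expect_equal(ws$wald_chisq[ws$term == "skewness_TEMP"], 7.10, tolerance = 2e-3)
  expect_equal(ws$p[ws$term == "skewness_TEMP"], 0.0077, tolerance = 2e-2)
  expect_equal(ws$odds_ratio[ws$term == "null"], 1)
  expect_equal(ws$wald_chisq[ws$term == "null"], 0)
})
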