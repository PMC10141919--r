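# brute-force AUC oracle over all positive x negative pairs
pair_count_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

test_that("Gaussian naive Bayes is symmetric and matches hand-computed Bayes rule", {
  # mirrored classes, equal priors: the midpoint scores 1/2
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 1, 1)
  clf <- train_classifier("gaussian_nb", X, y)
  expect_equal(predict(clf, matrix(0, 1, 1, dimnames = list(NULL, "f"))), 0.5)
  # 4-point toy set: posterior from the closed-form normal Bayes rule
  X2 <- matrix(c(0, 1, 3, 5), ncol = 1, dimnames = list(NULL, "f"))
  y2 <- c(0, 0, 1, 1)
  clf2 <- train_classifier("gaussian_nb", X2, y2)
  eps <- 1e-9 * max(apply(X2, 2, var))
  lik <- function(x, mu, v) dnorm(x, mu, sqrt(v))
  v0 <- var(c(0, 1)) + eps; v1 <- var(c(3, 5)) + eps
  x_new <- 2
  post <- 0.5 * lik(x_new, 4, v1) / (0.5 * lik(x_new, 0.5, v0) + 0.5 * lik(x_new, 4, v1))
  expect_equal(predict(clf2, matrix(x_new, 1, 1, dimnames = list(NULL, "f"))), post,
               tolerance = 1e-9)
  expect_error(train_classifier("gaussian_nb", X, rep(1, 4)),
               class = "flowsense_validation_error")
})

test_that("naive Bayes posteriors agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  X <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(X[, 1]))
  clf <- train_classifier("gaussian_nb", X, y)
  ref <- e1071::naiveBayes(data.frame(X), factor(y))
  p_ref <- predict(ref, data.frame(X), type = "raw")[, "1"]
  expect_equal(unname(predict(clf, X)), unname(p_ref), tolerance = 1e-6)
})

test_that("weighted metrics reproduce the published confusion-matrix arithmetic", {
  m1 <- metrics_from_confusion(list(TN = 26, FP = 12, FN = 5, TP = 17))
  # tolerances sized to the two-decimal printed precision of the values
  expect_equal(m1$f1, 0.72, tolerance = 8e-3)
  expect_equal(m1$precision, 0.75, tolerance = 8e-3)
  expect_equal(m1$recall, 0.72, tolerance = 8e-3)
  m2 <- metrics_from_confusion(list(TN = 3, FP = 1, FN = 1, TP = 5))
  expect_equal(m2$f1, 0.80, tolerance = 5e-3)
  m3 <- metrics_from_confusion(list(TN = 30, FP = 0, FN = 0, TP = 30))
  expect_equal(m3$precision, 1)
  expect_equal(m3$recall, 1)
  expect_equal(m3$f1, 1)
})

test_that("weighted recall equals accuracy on random confusion matrices (property)", {
  set.seed(22)
  for (r in 1:20) {
    cm <- as.list(setNames(rpois(4, 10) + 1, c("TN", "FP", "FN", "TP")))
    m <- metrics_from_confusion(cm)
    acc <- (cm$TN + cm$TP) / (cm$TN + cm$FP + cm$FN + cm$TP)
    expect_equal(m$recall, acc)
  }
})

test_that("rank-based AUC equals the brute-force pair count", {
  set.seed(23)
  p <- runif(50)
  p[sample(50, 8)] <- p[sample(50, 3)][1]  # inject ties
  y <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(p, y), pair_count_auc(p, y))
  expect_equal(roc_auc(y, y), 1)
  expect_equal(roc_auc(rep(0.3, 20), rep(c(0, 1), 10)), 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "flowsense_validation_error")
})

test_that("AUC is invariant under strictly monotone score transforms (property)", {
  set.seed(24)
  p <- runif(40)
  y <- rbinom(40, 1, p)
  a0 <- roc_auc(p, y)
  expect_equal(roc_auc(qlogis(p), y), a0)
  expect_equal(roc_auc(p^3, y), a0)
  expect_equal(roc_auc(exp(5 * p), y), a0)
})

test_that("the ROC table enumerates thresholds with monotone rates", {
  set.seed(25)
  p <- round(runif(30), 2)
  y <- rbinom(30, 1, 0.5)
  tab <- roc_table(p, y)
  expect_equal(nrow(tab), length(unique(p)))
  expect_true(all(diff(tab$tpr) <= 0))
  expect_true(all(diff(tab$tnr) >= 0))
  # at the lowest threshold everything is called positive
  expect_equal(tab$tpr[1], 1)
})

test_that("between-participant folds partition the rows by participant", {
  tab <- study_feature_table(seed = 6)
  cv <- suppressWarnings(
    cross_validate(tab, "between_participant", "logistic", features = PLANTED, seed = 1)
  )
  expect_equal(length(unique(cv$predictions$fold)), 5)
  expect_equal(sort(cv$predictions$row), 1:60)
  expect_equal(with(cv$confusion, TN + FP + FN + TP), 60)
  # no row is predicted by a model trained on its own participant
  for (f in unique(cv$predictions$fold)) {
    rows <- cv$predictions$row[cv$predictions$fold == f]
    expect_equal(unique(tab$participant_id[rows]), f)
  }
})

test_that("all schemes produce one pooled prediction per row", {
  tab <- study_feature_table(seed = 7)
  for (scheme in c("between_participant", "stratified_10fold", "leave_one_out")) {
    cv <- suppressWarnings(
      cross_validate(tab, scheme, "gaussian_nb", features = PLANTED, seed = 2)
    )
    expect_equal(nrow(cv$predictions), 60, info = scheme)
  }
  cv10 <- suppressWarnings(
    cross_validate(tab, "stratified_10fold", "logistic", features = PLANTED, seed = 2)
  )
  expect_equal(length(unique(cv10$predictions$fold)), 10)
})

test_that("resubstitution is the optimism ceiling", {
  tab <- study_feature_table(seed = 8)
  re <- suppressWarnings(
    cross_validate(tab, "resubstitution", "logistic", features = PLANTED, seed = 3)
  )
  bp <- suppressWarnings(
    cross_validate(tab, "between_participant", "logistic", features = PLANTED, seed = 3)
  )
  expect_gte(re$metrics$auc, bp$metrics$auc - 0.05)
  expect_true(re$metrics$auc > 0.5)
})

test_that("transfer prediction applies frozen coefficients without refitting", {
  tab1 <- study_feature_table(seed = 9)
  clf <- train_classifier("logistic", as.matrix(tab1[, PLANTED]), tab1$flow)
  # transfer to the training table reproduces resubstitution
  tr_self <- transfer_predict(clf, tab1)
  re <- cross_validate(tab1, "resubstitution", "logistic", features = PLANTED, seed = 1)
  expect_equal(tr_self$metrics$auc, re$metrics$auc, tolerance = 1e-10)
  # zero coefficients give constant probabilities and AUC 1/2
  clf0 <- clf
  clf0$model$coefficients[] <- 0
  tr0 <- suppressWarnings(transfer_predict(clf0, tab1))
  expect_equal(tr0$metrics$auc, 0.5)
  # association-destroying permutation drives transfer AUC to chance, on average
  aucs <- vapply(1:10, function(r) {
    set.seed(400 + r)
    tab_p <- tab1
    for (f in PLANTED) tab_p[[f]] <- sample(tab_p[[f]])
    transfer_predict(clf, tab_p)$metrics$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # schema mismatch is an error
  expect_error(transfer_predict(clf, tab1[, 1:4]), class = "flowsense_schema_error")
})

test_that("a model trained on one study predicts a new study's flow above chance", {
  tab1 <- study_feature_table(seed = 10, n_participants = 12L)
  clf <- train_classifier("logistic", as.matrix(tab1[, PLANTED]), tab1$flow)
  bundle2 <- generate_study(study2_config(seed = 11))
  w2 <- unlist(lapply(bundle2$sessions, build_task_windows), recursive = FALSE)
  tab2 <- build_feature_table(w2)
  tab2$flow <- label_flow(do.call(rbind, lapply(w2, function(w) w$fss_response)))
  if (length(unique(tab2$flow)) == 2) {
    tr <- transfer_predict(clf, tab2)
    expect_gte(tr$metrics$auc, 0.5)
  }
  # leave-one-out retraining on the new participant's own sessions
  if (min(table(tab2$flow)) >= 2) {
    cv <- suppressWarnings(
      cross_validate(tab2, "leave_one_out", "gaussian_nb", features = PLANTED, seed = 4)
    )
    expect_equal(nrow(cv$predictions), nrow(tab2))
  }
})

test_that("permutation importance isolates informative features and is seeded", {
  set.seed(26)
  n <- 400
  X <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * X[, "signal"]))
  clf <- train_classifier("logistic", X, y)
  imp <- permutation_importance(clf, X, y, n_shuffles = 100, seed = 5)
  base_auc <- attr(imp, "baseline_auc")
  sig <- imp[imp$feature == "signal", ]
  nul <- imp[imp$feature == "noise", ]
  # the sole informative feature loses close to all discrimination
  expect_equal(sig$mean_auc_drop, base_auc - 0.5, tolerance = 0.05)
  # a null feature's mean drop is within sampling noise of zero
  expect_lt(abs(nul$mean_auc_drop), 2 * nul$sd_auc_drop / sqrt(100) + 0.01)
  # identical seed, identical result
  imp2 <- permutation_importance(clf, X, y, n_shuffles = 100, seed = 5)
  expect_identical(as.data.frame(imp), as.data.frame(imp2))
  imp3 <- permutation_importance(clf, X, y, n_shuffles = 100, seed = 6)
  expect_false(identical(imp$mean_auc_drop, imp3$mean_auc_drop))
})
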