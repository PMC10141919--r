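# Classifier evaluation: logistic regression and Gaussian naive Bayes on
# the selected features, under four validation schemes, with pooled
# out-of-fold predictions, confusion matrices at cutoff 0.5,
# support-weighted precision/recall/F1, rank-based AUC, and permutation
# feature importance.

#' Train a probabilistic flow classifier
#'
#' `"logistic"` is a maximum-likelihood logistic regression on the feature
#' columns. `"gaussian_nb"` is a Gaussian naive Bayes: per-class, per-feature
#' normal likelihoods with class priors from the training frequencies and
#' variance smoothing `eps = 1e-9 * max(feature variance)` added to every
#' class variance.
#'
#' @param kind `"logistic"` or `"gaussian_nb"`.
#' @param X Numeric matrix / data frame of features.
#' @param y Binary 0/1 labels (both classes must be present).
#' @return A `flow_classifier` with a `predict(object, newdata)` method
#'   returning P(flow | x) in (0, 1).
#' @export
train_classifier <- function(kind = c("logistic", "gaussian_nb"), X, y) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort_flowsense("training labels contain a single class", "flowsense_validation_error")
  }
  model <- if (kind == "logistic") {
    fit_logistic_ml(X, y)
  } else {
    vars <- apply(X, 2, stats::var)
    eps <- 1e-9 * max(vars, 0)
    by_class <- lapply(c(0L, 1L), function(cl) {
      Xc <- X[y == cl, , drop = FALSE]
      list(
        prior = mean(y == cl),
        mu = colMeans(Xc),
        var = apply(Xc, 2, stats::var) + eps
      )
    })
    names(by_class) <- c("0", "1")
    by_class
  }
  structure(
    list(kind = kind, model = model, features = colnames(X)),
    class = "flow_classifier"
  )
}

#' @export
predict.flow_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(X))) {
      abort_flowsense("newdata lacks the model's feature columns", "flowsense_schema_error")
    }
    X <- X[, object$features, drop = FALSE]
  }
  if (object$kind == "logistic") {
    b <- object$model$coefficients
    eta <- drop(cbind(1, X) %*% b)
    stats::plogis(eta)
  } else {
    log_post <- sapply(c("0", "1"), function(cl) {
      p <- object$model[[cl]]
      ll <- rep(log(p$prior), nrow(X))
      for (j in seq_along(p$mu)) {
        ll <- ll + stats::dnorm(X[, j], p$mu[j], sqrt(p$var[j]), log = TRUE)
      }
      ll
    })
    log_post <- matrix(log_post, nrow = nrow(X), ncol = 2)
    log_post <- log_post - apply(log_post, 1, max)
    post <- exp(log_post)
    unname(post[, 2] / rowSums(post))
  }
}

#' Confusion matrix at a probability cutoff
#'
#' @param probabilities Predicted P(flow).
#' @param labels Observed 0/1 labels.
#' @param cutoff Classification threshold (default 0.5).
#' @return Named list `TN`, `FP`, `FN`, `TP` of class `confusion_matrix`.
#' @export
confusion_matrix <- function(probabilities, labels, cutoff = 0.5) {
  pred <- as.integer(probabilities >= cutoff)
  labels <- as.integer(labels)
  structure(
    list(
      TN = sum(pred == 0 & labels == 0), FP = sum(pred == 1 & labels == 0),
      FN = sum(pred == 0 & labels == 1), TP = sum(pred == 1 & labels == 1)
    ),
    class = "confusion_matrix"
  )
}

#' Support-weighted precision, recall and F1 from a confusion matrix
#'
#' Per-class precision, recall and F1 are computed for both classes
#' (no-flow = 0, flow = 1) and averaged with the observed class supports as
#' weights. Division-by-zero cells yield 0 for that class metric with a
#' warning. Weighted recall equals overall accuracy by construction.
#'
#' @param cm A [confusion_matrix()] (or list with TN, FP, FN, TP).
#' @return List: `precision`, `recall`, `f1` (all weighted), plus
#'   `per_class` tibble.
#' @export
metrics_from_confusion <- function(cm) {
  counts <- c(TN = cm$TN, FP = cm$FP, FN = cm$FN, TP = cm$TP)
  if (any(counts < 0)) abort_flowsense("negative counts", "flowsense_validation_error")
  total <- sum(counts)
  if (total == 0) abort_flowsense("empty confusion matrix", "flowsense_validation_error")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn_flowsense(sprintf("%s undefined (0/0); reported as 0", what),
                     "flowsense_degenerate_warning")
      return(0)
    }
    num / den
  }
  # class 0 = no-flow, class 1 = flow
  prec0 <- safe_div(cm$TN, cm$TN + cm$FN, "no-flow precision")
  rec0 <- safe_div(cm$TN, cm$TN + cm$FP, "no-flow recall")
  prec1 <- safe_div(cm$TP, cm$TP + cm$FP, "flow precision")
  rec1 <- safe_div(cm$TP, cm$TP + cm$FN, "flow recall")
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  per_class <- tibble::tibble(
    class = c("no_flow", "flow"),
    support = c(cm$TN + cm$FP, cm$TP + cm$FN),
    precision = c(prec0, prec1), recall = c(rec0, rec1),
    f1 = c(f1(prec0, rec0), f1(prec1, rec1))
  )
  w <- per_class$support / total
  list(
    precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f1 = sum(w * per_class$f1),
    per_class = per_class
  )
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve as the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param probabilities Predicted scores.
#' @param labels Observed 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort_flowsense("AUC undefined: labels contain a single class", "flowsense_validation_error")
  }
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC operating points at every distinct threshold
#'
#' Enumerates the true positive rate (sensitivity) and true negative rate
#' (specificity) at every distinct predicted probability, supporting a
#' specificity-first choice of operating threshold.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `tpr`, `tnr`; a prediction is
#'   positive when `probability >= threshold`.
#' @export
roc_table <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort_flowsense("ROC undefined: labels contain a single class", "flowsense_validation_error")
  }
  thresholds <- sort(unique(probabilities))
  rows <- lapply(thresholds, function(th) {
    pred <- probabilities >= th
    tibble::tibble(
      threshold = th,
      tpr = sum(pred & labels == 1) / sum(labels == 1),
      tnr = sum(!pred & labels == 0) / sum(labels == 0)
    )
  })
  dplyr::bind_rows(rows)
}

make_folds <- function(table, scheme, seed) {
  n <- nrow(table)
  switch(scheme,
    between_participant = {
      split(seq_len(n), table$participant_id)
    },
    stratified_10fold = {
      # folds balanced jointly on participant and label as far as counts allow
      k <- 10L
      fold <- integer(n)
      set.seed(derive_seed(seed, 101))
      strata <- split(seq_len(n), paste(table$participant_id, table$flow))
      counter <- 0L
      for (st in strata) {
        st <- sample(st)
        for (idx in st) {
          fold[idx] <- (counter %% k) + 1L
          counter <- counter + 1L
        }
      }
      split(seq_len(n), fold)
    },
    resubstitution = list(all = seq_len(n)),
    leave_one_out = split(seq_len(n), seq_len(n)),
    abort_flowsense(sprintf("unknown CV scheme '%s'", scheme), "flowsense_validation_error")
  )
}

#' Cross-validated evaluation of a classifier
#'
#' Supported schemes: `between_participant` (leave-one-participant-out, the
#' headline generalization test), `stratified_10fold` (folds balanced on
#' participant and label, seeded), `resubstitution` (train = test, the
#' optimism ceiling) and `leave_one_out` (per-row; the single-participant
#' daily-use mode). Out-of-fold probabilities are pooled across folds, then
#' a single confusion matrix (cutoff 0.5) and metric set are computed on
#' the pooled predictions; a pooled matrix over 60 tasks sums to 60.
#'
#' @param table Feature table with `participant_id`, feature columns and a
#'   binary `flow` column.
#' @param scheme CV scheme (see above).
#' @param classifier `"logistic"` or `"gaussian_nb"`.
#' @param features Feature columns to use (defaults to all feature columns
#'   present in the table).
#' @param seed Integer seed controlling fold assignment.
#' @param cutoff Probability cutoff for the confusion matrix.
#' @return A `cv_result`: `scheme`, `classifier`, `predictions` tibble
#'   (row, fold, probability, label), `confusion`, `metrics` (with `auc`),
#'   `skipped_folds`.
#' @export
cross_validate <- function(table, scheme = c("between_participant", "stratified_10fold",
                                             "resubstitution", "leave_one_out"),
                           classifier = c("logistic", "gaussian_nb"),
                           features = NULL, seed = 1L, cutoff = 0.5) {
  scheme <- match.arg(scheme)
  classifier <- match.arg(classifier)
  if (is.null(features)) features <- intersect(feature_names(), colnames(table))
  if (!all(features %in% colnames(table))) {
    abort_flowsense("feature columns missing from table", "flowsense_schema_error")
  }
  if (anyNA(table$flow)) abort_flowsense("flow labels contain NA", "flowsense_validation_error")
  if (scheme == "between_participant" && length(unique(table$participant_id)) < 2L) {
    abort_flowsense("between-participant CV needs >= 2 participants", "flowsense_validation_error")
  }
  if (nrow(table) < 2L) abort_flowsense("need >= 2 rows", "flowsense_validation_error")

  folds <- make_folds(table, scheme, seed)
  X <- as.matrix(table[, features, drop = FALSE])
  y <- as.integer(table$flow)

  prob <- rep(NA_real_, nrow(table))
  fold_of <- rep(NA_character_, nrow(table))
  skipped <- character(0)
  for (fname in names(folds)) {
    test_idx <- folds[[fname]]
    train_idx <- if (scheme == "resubstitution") test_idx else setdiff(seq_len(nrow(table)), test_idx)
    min_class <- min(table(y[train_idx]))
    need <- if (classifier == "gaussian_nb") 2L else 1L
    if (length(unique(y[train_idx])) < 2L || min_class < need) {
      warn_flowsense(sprintf("fold %s skipped: training labels too sparse", fname),
                     "flowsense_fold_warning")
      skipped <- c(skipped, fname)
      next
    }
    clf <- train_classifier(classifier, X[train_idx, , drop = FALSE], y[train_idx])
    prob[test_idx] <- predict(clf, X[test_idx, , drop = FALSE])
    fold_of[test_idx] <- fname
  }
  keep <- !is.na(prob)
  cm <- confusion_matrix(prob[keep], y[keep], cutoff)
  met <- metrics_from_confusion(cm)
  met$auc <- if (length(unique(y[keep])) == 2L) {
    roc_auc(prob[keep], y[keep])
  } else {
    warn_flowsense("pooled out-of-fold labels have a single class; AUC undefined",
                   "flowsense_degenerate_warning")
    NA_real_
  }
  structure(
    list(
      scheme = scheme, classifier = classifier,
      predictions = tibble::tibble(
        row = which(keep), fold = fold_of[keep],
        probability = prob[keep], label = y[keep]
      ),
      confusion = cm, metrics = met, skipped_folds = skipped, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result %s / %s: AUC %.3f, F1 %.3f, precision %.3f, recall %.3f (n = %d)>\n",
    x$classifier, x$scheme, x$metrics$auc, x$metrics$f1, x$metrics$precision,
    x$metrics$recall, nrow(x$predictions)
  ))
  cat(sprintf("confusion (cutoff): TN %d FP %d / FN %d TP %d\n",
              x$confusion$TN, x$confusion$FP, x$confusion$FN, x$confusion$TP))
  invisible(x)
}

#' Apply a frozen classifier to a new study
#'
#' Applies an already-trained classifier, without refitting, to a feature
#' table from another study (the Study-1-coefficients-on-Study-2 transfer
#' test). Feature names must match exactly.
#'
#' @param classifier A `flow_classifier`.
#' @param table Feature table with the classifier's feature columns and a
#'   `flow` column.
#' @param cutoff Probability cutoff for the confusion matrix.
#' @return List: `probabilities`, `confusion`, `metrics` (with `auc`).
#' @export
transfer_predict <- function(classifier, table, cutoff = 0.5) {
  stopifnot(inherits(classifier, "flow_classifier"))
  if (!all(classifier$features %in% colnames(table))) {
    abort_flowsense(
      paste("transfer table lacks feature(s):",
            paste(setdiff(classifier$features, colnames(table)), collapse = ", ")),
      "flowsense_schema_error"
    )
  }
  prob <- predict(classifier, as.matrix(table[, classifier$features, drop = FALSE]))
  y <- as.integer(table$flow)
  cm <- confusion_matrix(prob, y, cutoff)
  met <- metrics_from_confusion(cm)
  met$auc <- roc_auc(prob, y)
  list(probabilities = prob, confusion = cm, metrics = met)
}

#' Permutation feature importance as AUC reduction
#'
#' For each feature, the feature column is shuffled `n_shuffles` times
#' (seeded) and the mean and standard deviation of the drop in AUC relative
#' to the unshuffled baseline are recorded.
#'
#' @param classifier A trained `flow_classifier`.
#' @param X Feature matrix / data frame (evaluation data).
#' @param y Binary labels.
#' @param n_shuffles Number of shuffles per feature (default 1000).
#' @param seed Integer seed.
#' @return A `perm_importance` tibble: `feature`, `mean_auc_drop`,
#'   `sd_auc_drop`, with attributes `n_shuffles`, `seed`, `baseline_auc`.
#' @export
permutation_importance <- function(classifier, X, y, n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(classifier, "flow_classifier"), n_shuffles >= 1L)
  X <- as.matrix(X)
  if (!all(classifier$features %in% colnames(X))) {
    abort_flowsense("X lacks the model's feature columns", "flowsense_schema_error")
  }
  X <- X[, classifier$features, drop = FALSE]
  y <- as.integer(y)
  baseline <- roc_auc(predict(classifier, X), y)
  rows <- lapply(seq_along(classifier$features), function(j) {
    set.seed(derive_seed(seed, 7000 + j))
    drops <- vapply(seq_len(n_shuffles), function(s) {
      Xs <- X
      Xs[, j] <- sample(Xs[, j])
      baseline - roc_auc(predict(classifier, Xs), y)
    }, numeric(1))
    tibble::tibble(
      feature = classifier$features[j],
      mean_auc_drop = mean(drops),
      sd_auc_drop = stats::sd(drops)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "seed") <- seed
  attr(out, "baseline_auc") <- baseline
  class(out) <- c("perm_importance", class(out))
  out
}

#' Plot permutation importance
#'
#' Bar chart of mean AUC reduction per feature with +/- 1 SD whiskers.
#'
#' @param importance A [permutation_importance()] result.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_importance <- function(importance) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_flowsense("ggplot2 is required for plotting", "flowsense_validation_error")
  }
  df <- as.data.frame(importance)
  df$feature <- stats::reorder(df$feature, df$mean_auc_drop)
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = mean_auc_drop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_auc_drop - sd_auc_drop, ymax = mean_auc_drop + sd_auc_drop),
      width = 0.25
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean AUC reduction") +
    ggplot2::theme_minimal()
}
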