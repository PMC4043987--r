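# Downstream utility of a selection: rank-based AUC and a seeded,
# leakage-free holdout harness.

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Wilcoxon rank-sum
#' statistic; tied scores contribute 1/2.
#'
#' @param scores Real-valued scores, higher meaning more positive.
#' @param labels Labels in `{+1, -1}`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1)) # 1
auc_score <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(scores) != length(y)) stop_shape("scores and labels differ in length")
  npos <- sum(y > 0)
  nneg <- sum(y < 0)
  if (npos == 0L || nneg == 0L) {
    stop_validation("AUC needs both classes in the labels")
  }
  r <- rank(scores)
  (sum(r[y > 0]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Linear SVM scorer (fit-then-score contract)
#'
#' Returns a scorer `function(x_train, y_train, x_test)` producing decision
#' values oriented so that larger means more positive. A soft-margin linear
#' SVM with fixed cost (default 1) — standard apparatus for small-sample
#' expression classification.
#'
#' @param cost Soft-margin cost parameter.
#' @return A scorer function for [holdout_eval()].
#' @export
scorer_svm_linear <- function(cost = 1) {
  function(x_train, y_train, x_test) {
    fit <- e1071::svm(x = x_train, y = factor(y_train, levels = c(-1, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, x_test, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    scores <- dv[, 1L]
    if (colnames(dv)[1L] == "-1/1") scores <- -scores
    unname(scores)
  }
}

#' A selector contract wrapping the single-task filter
#'
#' Returns a `function(train_data, seed)` that runs [st_bip()] on the
#' training split and returns the selected feature indices — the form
#' [holdout_eval()] expects, guaranteeing the selection is re-computed
#' inside each split.
#'
#' @inheritParams st_bip
#' @return A selector function.
#' @export
selector_st_bip <- function(m, k = NULL, lambda = NULL) {
  function(train_data, seed) {
    st_bip(train_data, m = m, k = k, lambda = lambda, seed = seed)$selected
  }
}

#' Class-stratified holdout evaluation of a feature selector
#'
#' For each repetition: draw `n_pos_train` positive and `n_neg_train`
#' negative samples as the training split, standardize using training
#' statistics only, re-run the feature selector on the training split,
#' fit the scorer on the selected features, and compute the AUC on the
#' held-out remainder. Nothing upstream of scoring ever sees the test
#' labels, and the test features are transformed with training-derived
#' statistics only.
#'
#' @param data A labeled, unstandardized [expression_dataset()].
#' @param selector `function(train_data, seed)` returning selected feature
#'   indices (see [selector_st_bip()]).
#' @param n_pos_train,n_neg_train Training samples per class; the remainder
#'   (which must contain both classes) is the test set.
#' @param repetitions Number of random splits.
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @param scorer `function(x_train, y_train, x_test)` returning test scores
#'   (default: linear SVM with cost 1).
#' @param details Also return per-repetition splits, selections and scores.
#' @return A `data.frame` with columns `repetition`, `auc`, `m`; when
#'   `details = TRUE`, a list with elements `results` and `details`.
#' @export
holdout_eval <- function(data, selector, n_pos_train, n_neg_train,
                         repetitions = 10L, seed = 1L,
                         scorer = scorer_svm_linear(), details = FALSE) {
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(data$y)) stop_validation("holdout evaluation needs labels")
  pos <- which(data$y > 0)
  neg <- which(data$y < 0)
  if (length(pos) <= n_pos_train || length(neg) <= n_neg_train) {
    stop_validation(sprintf(
      "need more than %d positive and %d negative samples (have %d / %d)",
      n_pos_train, n_neg_train, length(pos), length(neg)
    ))
  }
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, repetitions))
  res <- vector("list", repetitions)
  det <- if (details) vector("list", repetitions) else NULL
  for (r in seq_len(repetitions)) {
    split <- with_seed(rep_seeds[r], {
      list(pos = sample(pos, n_pos_train), neg = sample(neg, n_neg_train))
    })
    train_idx <- sort(c(split$pos, split$neg))
    test_idx <- setdiff(seq_len(nrow(data$x)), train_idx)
    train <- expression_dataset(data$x[train_idx, , drop = FALSE],
                                labels = data$y[train_idx],
                                feature_ids = data$feature_ids,
                                sample_ids = data$sample_ids[train_idx])
    train <- standardize(train)
    test_x <- sweep(sweep(data$x[test_idx, , drop = FALSE], 2L, train$center),
                    2L, train$scale, "/")
    sel <- selector(train, rep_seeds[r])
    scores <- scorer(train$x[, sel, drop = FALSE], train$y,
                     test_x[, sel, drop = FALSE])
    auc <- auc_score(scores, data$y[test_idx])
    res[[r]] <- data.frame(repetition = r, auc = auc, m = length(sel))
    if (details) {
      det[[r]] <- list(train = train_idx, test = test_idx, selected = sel,
                       scores = scores)
    }
  }
  results <- do.call(rbind, res)
  if (details) list(results = results, details = det) else results
}
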