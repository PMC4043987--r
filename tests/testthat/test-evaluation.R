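test_that("rank-based AUC handles perfect, inverted and tied score vectors", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(-1, -1, 1, 1)), 0)
  expect_equal(auc_score(rep(1, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), class = "bipfs_validation_error")
  # complement symmetry for tie-free scores
  set.seed(90)
  s <- rnorm(20)
  y <- rep(c(1, -1), 10)
  expect_equal(auc_score(s, y) + auc_score(-s, y), 1, tolerance = 1e-12)
})

test_that("the rank statistic matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  for (i in 1:5) {
    s <- rnorm(40)
    y <- sample(rep(c(1, -1), 20))
    ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y, levels = c(-1, 1)),
                                          predictor = s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(s, y), ref, tolerance = 1e-10)
  }
})

test_that("an oracle scorer achieves AUC 1 in every repetition, deterministically", {
  # feature 1 is the class itself, so a scorer reading it back is an oracle
  sim <- generate_expression(synthetic_config(n = 40, m_features = 60,
                                              n_informative = 5, seed = 92))
  data <- sim$data
  data$x[, 1] <- data$y
  oracle <- function(x_train, y_train, x_test) x_test[, 1]
  res <- holdout_eval(data, selector = function(d, seed) 1:5,
                      n_pos_train = 10, n_neg_train = 10,
                      repetitions = 3, seed = 9, scorer = oracle,
                      details = TRUE)
  expect_equal(res$results$auc, rep(1, 3))
  # determinism: identical splits for an identical master seed
  res2 <- holdout_eval(data, selector = function(d, seed) 1:5,
                       n_pos_train = 10, n_neg_train = 10,
                       repetitions = 3, seed = 9, scorer = oracle,
                       details = TRUE)
  expect_identical(lapply(res2$details, `[[`, "train"),
                   lapply(res$details, `[[`, "train"))
  expect_equal(res2$results$auc, res$results$auc)
})

test_that("nothing upstream of scoring depends on the held-out labels", {
  sim <- generate_expression(synthetic_config(n = 36, m_features = 80,
                                              n_informative = 5, seed = 93))
  run <- holdout_eval(sim$data, selector = selector_st_bip(m = 8),
                      n_pos_train = 9, n_neg_train = 9,
                      repetitions = 1, seed = 11, details = TRUE)
  det <- run$details[[1]]
  train_idx <- det$train
  test_idx <- det$test
  # rebuild the split by hand, with the test labels corrupted, and check that
  # standardization, selection and scores are unchanged
  corrupted <- sim$data
  corrupted$y[test_idx] <- -corrupted$y[test_idx]
  train <- expression_dataset(corrupted$x[train_idx, ],
                              labels = corrupted$y[train_idx],
                              feature_ids = corrupted$feature_ids)
  train <- standardize(train)
  seed_used <- withr::with_seed(11, sample.int(.Machine$integer.max - 1L, 1))
  sel <- selector_st_bip(m = 8)(train, seed_used)
  expect_identical(sel, det$selected)
  test_x <- sweep(sweep(corrupted$x[test_idx, ], 2, train$center), 2, train$scale, "/")
  scores <- scorer_svm_linear()(train$x[, sel], train$y, test_x[, sel])
  expect_equal(scores, det$scores, tolerance = 1e-10)
})

test_that("with no class signal the holdout AUC sits at chance level", {
  # a reasonably sized test split keeps the dataset-conditional mean AUC
  # close to its 0.5 expectation
  sim <- generate_expression(synthetic_config(n = 60, m_features = 80,
                                              n_informative = 10, delta = 0,
                                              seed = 94))
  res <- suppressWarnings(
    holdout_eval(sim$data, selector = selector_st_bip(m = 10),
                 n_pos_train = 15, n_neg_train = 15,
                 repetitions = 20, seed = 12)
  )
  expect_lt(abs(mean(res$auc) - 0.5), 0.1)
})

test_that("insufficient per-class samples are rejected", {
  sim <- generate_expression(synthetic_config(n = 10, m_features = 20,
                                              n_informative = 2, seed = 95))
  expect_error(
    holdout_eval(sim$data, selector = function(d, seed) 1:2,
                 n_pos_train = 5, n_neg_train = 5, repetitions = 2, seed = 1),
    class = "bipfs_validation_error"
  )
})
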