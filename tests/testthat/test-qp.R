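test_that("auto lambda follows the m^2/M * |sum c| / sum Q rule with a guarded fallback", {
  expect_equal(auto_lambda(c(-1, -1), matrix(1, 2, 2), m = 1), 0.25)
  expect_warning(lam <- auto_lambda(c(-1, -1), matrix(0, 2, 2), m = 1),
                 "falling back")
  expect_equal(lam, 1)
  # low-rank path agrees with the dense sum on an exact factor
  d <- standardize(random_dataset(20, 8, seed = 41))
  fac <- exact_factor(d)
  q <- pearson_similarity(d)
  expect_equal(auto_lambda(linear_term(d), fac, m = 3),
               auto_lambda(linear_term(d), q, m = 3), tolerance = 1e-6)
})

test_that("the dense-Q solver reproduces the identity-Q closed form", {
  s <- solve_full_qp(c(-2, -1, 0), diag(3), lambda = 4, m = 2)
  expect_equal(unname(s$w), c(7, 4, 1) / 6, tolerance = 1e-6)
  expect_equal(s$objective, qp_objective(c(-2, -1, 0), diag(3), 4, 2, s$w),
               tolerance = 1e-8)

  for (case in 1:25) {
    set.seed(900 + case)
    M <- sample(4:25, 1)
    cvec <- rnorm(M, sd = 2)
    lambda <- runif(1, 0.2, 5)
    m <- sample.int(M - 1, 1)
    oracle <- waterfill_identity_qp(cvec, lambda, m)
    for (method in c("ipm", "activeset")) {
      s <- solve_full_qp(cvec, diag(M), lambda = lambda, m = m, method = method)
      expect_equal(unname(s$w), oracle, tolerance = 1e-6)
      expect_true(all(s$w >= -1e-8))
      expect_lt(abs(sum(s$w) - m), 1e-6)
    }
  }
})

test_that("interior-point and active-set solvers agree on random PSD instances", {
  for (case in 1:10) {
    d <- random_dataset(40, sample(5:20, 1), n_informative = 2, delta = 1.5,
                        seed = 950 + case)
    ds <- standardize(d)
    q <- pearson_similarity(ds)
    cvec <- linear_term(ds)
    m <- sample.int(ncol(d$x) - 1, 1)
    lambda <- auto_lambda(cvec, q, m)
    s1 <- solve_full_qp(cvec, q, lambda, m, method = "ipm")
    s2 <- solve_full_qp(cvec, q, lambda, m, method = "activeset")
    expect_equal(unname(s1$w), unname(s2$w), tolerance = 1e-4)
  }
})

test_that("a very large ridge drives the solution to the uniform point", {
  s <- solve_full_qp(c(-2, -1, 0), diag(3), lambda = 1e6, m = 2)
  expect_equal(unname(s$w), rep(2 / 3, 3), tolerance = 1e-3)
})

test_that("exhaustive binary enumeration finds the optimal subset with lexicographic ties", {
  res <- enumerate_binary_optimum(c(-2, -1, 0), diag(3), lambda = 4, m = 2)
  expect_equal(res$indices, c(1L, 2L))
  expect_equal(res$objective, -1)

  # single feasible point
  res2 <- enumerate_binary_optimum(c(1, 2), matrix(c(1, .5, .5, 1), 2), 3, m = 2)
  expect_equal(res2$indices, 1:2)
  expect_equal(res2$objective, 3 + (3 / 4) * 3)

  # duplicated features with identical c resolve to the smallest index set
  q <- diag(4)
  res3 <- enumerate_binary_optimum(c(-1, -1, -1, 0), q, lambda = 1, m = 2)
  expect_equal(res3$indices, c(1L, 2L))

  expect_error(enumerate_binary_optimum(rnorm(40), diag(40), 1, 20),
               class = "bipfs_validation_error")
})

test_that("the relaxed optimum lower-bounds the binary optimum on enumerable instances", {
  for (case in 1:12) {
    set.seed(1000 + case)
    M <- sample(5:12, 1)
    d <- standardize(random_dataset(M + sample(3:10, 1), M,
                                    n_informative = 2, delta = 1.5,
                                    seed = 1100 + case))
    q <- pearson_similarity(d)
    cvec <- linear_term(d)
    m <- sample.int(M - 1, 1)
    lambda <- runif(1, 0.1, 3) * max(1, abs(sum(cvec)))
    binary <- enumerate_binary_optimum(cvec, q, lambda, m)
    full <- solve_full_qp(cvec, q, lambda, m)
    expect_lte(full$objective, binary$objective + 1e-6)
    # exact low-rank factor inherits the bound
    fac <- exact_factor(d)
    red <- solve_reduced_qp(cvec, fac, lambda, m)
    expect_lte(red$objective, binary$objective + 1e-4)
  }
})

test_that("reduced and full solvers agree when the factorization is exact", {
  for (case in 1:6) {
    M <- sample(10:50, 1)
    d <- standardize(random_dataset(M + 10, M, n_informative = 3, delta = 1.2,
                                    seed = 1200 + case))
    q <- pearson_similarity(d)
    cvec <- linear_term(d)
    m <- sample.int(M - 1, 1)
    lambda <- auto_lambda(cvec, q, m)
    fac <- lowrank_eigenpairs(nystrom_factor(d, kmeans_landmarks(d, M, seed = case)))
    full <- solve_full_qp(cvec, q, lambda, m, method = "activeset")
    red <- solve_reduced_qp(cvec, fac, lambda, m)
    expect_equal(unname(red$w), unname(full$w), tolerance = 1e-4)
    # reconstruction identity in the full-rank regime
    recon <- fac$U_k %*% (red$alpha / sqrt(fac$lambda_k))
    expect_lt(max(abs(drop(recon) - red$w)), 1e-6)
  }
})

test_that("ranking is stable with ascending-index tie-breaks", {
  expect_equal(rank_and_select(c(0.5, 2, 1), 2), c(2L, 3L))
  expect_equal(rank_and_select(rep(1, 5), 3), 1:3)
  expect_equal(rank_and_select(c(3, 1, 2), 3), c(1L, 3L, 2L))
  expect_error(rank_and_select(c(1, 2), 3), class = "bipfs_validation_error")
})

test_that("the end-to-end single-task fit is feasible, deterministic and self-consistent", {
  sim <- generate_expression(synthetic_config(n = 30, m_features = 120,
                                              n_informative = 5, seed = 77))
  f1 <- st_bip(sim$data, m = 15, seed = 42)
  f2 <- st_bip(sim$data, m = 15, seed = 42)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$w, f2$w)
  expect_true(all(f1$w >= -1e-8))
  expect_lt(abs(sum(f1$w) - 15), 1e-6)
  expect_equal(length(f1$selected), 15L)
  expect_s3_class(f1, "bip_fit")
  expect_named(coef(f1), sim$data$feature_ids)
  # objective reproduced independently from (w, c, Qhat, lambda)
  ds <- standardize(sim$data)
  fac <- lowrank_eigenpairs(nystrom_factor(ds, kmeans_landmarks(ds, f1$k_requested, seed = 42)))
  qhat <- fac$U_k %*% (fac$lambda_k * t(fac$U_k))
  expect_equal(f1$objective,
               qp_objective(linear_term(ds), qhat, f1$lambda, 15, f1$w),
               tolerance = 1e-8)
  expect_error(st_bip(sim$data, m = 1000), class = "bipfs_validation_error")

  s <- summary(f1)
  expect_s3_class(s, "summary.bip_fit")
  expect_equal(nrow(s$ranking), 120L)
  expect_output(print(f1), "Single-task")
})
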