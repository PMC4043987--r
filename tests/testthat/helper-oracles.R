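# Shared fixtures and independent oracles used across the suite.

# Random labeled dataset with a few informative columns.
random_dataset <- function(n, m, n_informative = 0L, delta = 0, seed = NULL) {
  gen <- function() {
    y <- rep(c(1, -1), length.out = n)
    x <- matrix(rnorm(n * m), n, m)
    if (n_informative > 0L) {
      x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
        outer(y, rep(delta / 2, n_informative))
    }
    expression_dataset(x, labels = y)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Fixture with one strong informative feature duplicated as identical
# columns, a few weaker independent informative features, and noise, all
# at random column positions so no metric can lean on position artifacts.
duplicated_feature_dataset <- function(seed, n = 60L, m = 100L,
                                       n_dup = 10L, n_weak = 5L,
                                       delta_strong = 2, delta_weak = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, -1), each = n / 2)
    x <- matrix(rnorm(n * m), n, m)
    slots <- sample.int(m, n_dup + n_weak)
    dup_group <- slots[seq_len(n_dup)]
    weak <- slots[(n_dup + 1):(n_dup + n_weak)]
    strong <- rnorm(n) + y * delta_strong / 2
    for (j in dup_group) x[, j] <- strong
    x[, weak] <- x[, weak] + outer(y, rep(delta_weak / 2, n_weak))
    list(data = expression_dataset(x, labels = y),
         dup_group = dup_group, weak = weak)
  })
}

# Number of distinct informative groups (the duplicate block counts once,
# each weak feature is its own group) covered by an index set.
distinct_groups_covered <- function(idx, dup_group, weak) {
  as.integer(any(idx %in% dup_group)) + sum(weak %in% idx)
}

# Closed-form water-filling solution of
#   min c'w + (lambda/m^2) ||w||^2  s.t. w >= 0, sum(w) = m
# KKT: w_i = max(0, (nu - c_i)) * m^2 / (2 lambda), with nu from sum(w) = m.
waterfill_identity_qp <- function(cvec, lambda, m) {
  gam <- lambda / m^2
  cs <- sort(cvec)
  M <- length(cvec)
  for (j in seq_len(M)) {
    nu <- (2 * gam * m + sum(cs[seq_len(j)])) / j
    upper <- if (j < M) cs[j + 1L] else Inf
    if (nu > cs[j] && nu <= upper) {
      return(pmax(0, (nu - cvec) / (2 * gam)))
    }
  }
  stop("water-filling oracle failed to bracket nu")
}

# Objective of the relaxed/binary program, evaluated independently.
qp_objective <- function(cvec, Q, lambda, m, w) {
  sum(cvec * w) + (lambda / m^2) * drop(crossprod(w, Q %*% w))
}

# Exact Nystrom factor using every feature as a landmark.
exact_factor <- function(data) {
  lowrank_eigenpairs(nystrom_factor(data, data$x))
}
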