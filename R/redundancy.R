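# Feature-redundancy term: Pearson similarity, k-means landmarks, Nystrom
# low-rank factorization and its eigenpairs.
#
# The full M x M Pearson matrix Q is only ever formed on small problems (it
# is the reference path and the test oracle). The working representation is
# a factor G with Q ~ GG', built from correlations against k landmark
# pseudo-features: G = E_Mk W_kk^(-1/2), where E_Mk holds feature-landmark
# correlations and W_kk landmark-landmark correlations. The top eigenpairs
# of GG' come from the small k x k matrix G'G, never from an M x M
# decomposition.

#' Full Pearson feature-similarity matrix (reference path)
#'
#' @param data An [expression_dataset()] (or numeric matrix) with at least
#'   two samples. Zero-variance columns get similarity 0 off-diagonal and 1
#'   on the diagonal.
#' @return Symmetric `M x M` correlation matrix with unit diagonal; positive
#'   semi-definite up to numerical tolerance.
#' @export
pearson_similarity <- function(data) {
  x <- if (inherits(data, "expr_dataset")) data$x else as.matrix(data)
  if (nrow(x) < 2L) stop_validation("Pearson similarity needs at least 2 samples")
  q <- suppressWarnings(stats::cor(x))
  q[!is.finite(q)] <- 0
  diag(q) <- 1
  q
}

#' Default low-rank dimension
#'
#' One tenth of the feature count (rounded up), capped at `M`.
#'
#' @param m_features Number of features `M`.
#' @return Integer rank.
#' @export
default_rank <- function(m_features) {
  as.integer(min(m_features, max(1, ceiling(0.1 * m_features))))
}

#' Select landmark pseudo-features by k-means
#'
#' Runs k-means on the `M` feature columns viewed as points in
#' `N`-dimensional sample space and returns the cluster centroids as
#' landmark pseudo-features. Deterministic given `seed`; uses 10 restarts.
#' With `k = M` the columns themselves are returned (saturated clustering).
#' Above `max_points` columns, clustering runs on a seeded random subsample
#' of the columns — centroid quality does not require every point, and this
#' keeps landmark selection (and with it the whole pipeline) linear in `M`.
#'
#' @param data An [expression_dataset()]; standardize first so squared
#'   Euclidean distance between feature columns aligns with correlation.
#' @param k Number of landmarks, `1 <= k <= M`.
#' @param seed Integer seed.
#' @param max_points Cap on the number of columns fed to k-means.
#' @return `N x k` matrix whose columns are landmark vectors.
#' @export
kmeans_landmarks <- function(data, k, seed = 1L, max_points = 5000L) {
  stopifnot(inherits(data, "expr_dataset"))
  m <- ncol(data$x)
  k <- as.integer(k)
  if (k < 1L || k > m) {
    stop_validation(sprintf("k must be in [1, %d], got %d", m, k))
  }
  if (k == m) {
    lm <- data$x
    colnames(lm) <- NULL
    return(lm)
  }
  with_seed(seed, {
    cap <- max(k, as.integer(max_points))
    cols <- if (m > cap) sort(sample.int(m, cap)) else seq_len(m)
    pts <- t(data$x[, cols, drop = FALSE])
    fit <- stats::kmeans(pts, centers = k, nstart = 10L, iter.max = 100L)
    t(fit$centers)
  })
}

#' Nystrom low-rank factor of the feature-similarity matrix
#'
#' Builds `G = E_Mk W_kk^(-1/2)` where `E_Mk[i, j]` is the Pearson
#' correlation between feature `i` and landmark `j` and `W_kk` the
#' landmark-landmark correlations. The inverse square root uses the
#' eigen-decomposition of `W_kk` with eigenvalues below `tau` times the
#' largest discarded (pseudo-inverse), so near-singular landmark sets are
#' handled; the retained rank is recorded as `k_effective`.
#'
#' @param data An [expression_dataset()], standardized.
#' @param landmarks `N x k` matrix of landmark vectors
#'   (see [kmeans_landmarks()]). Zero-variance landmarks are dropped with a
#'   warning.
#' @param tau Relative eigenvalue threshold for the pseudo-inverse.
#' @return An object of class `redundancy_factor` with elements `G`
#'   (`M x k_effective`), `landmarks`, `k_requested`, `k_effective`,
#'   `sum_q = ||G'1||^2` (low-rank estimate of `sum_ij Q_ij`), and slots
#'   `U_k` / `lambda_k` filled by [lowrank_eigenpairs()].
#' @export
nystrom_factor <- function(data, landmarks, tau = 1e-10) {
  stopifnot(inherits(data, "expr_dataset"))
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) < 1L) stop_validation("at least one landmark is required")
  if (nrow(landmarks) != nrow(data$x)) {
    stop_shape("landmarks must have one row per sample")
  }
  k_requested <- ncol(landmarks)
  sdv <- apply(landmarks, 2L, stats::sd)
  degenerate <- !(is.finite(sdv) & sdv > 0)
  if (all(degenerate)) stop_validation("all landmarks are constant vectors")
  if (any(degenerate)) {
    warning(sprintf("dropping %d zero-variance landmark(s)", sum(degenerate)))
    landmarks <- landmarks[, !degenerate, drop = FALSE]
  }
  e_mk <- suppressWarnings(stats::cor(data$x, landmarks))
  e_mk[!is.finite(e_mk)] <- 0
  w_kk <- suppressWarnings(stats::cor(landmarks))
  w_kk[!is.finite(w_kk)] <- 0
  diag(w_kk) <- 1
  ew <- eigen(w_kk, symmetric = TRUE)
  keep <- ew$values > tau * max(ew$values)
  if (!any(keep)) stop_validation("landmark correlation matrix is numerically zero")
  # M x k' factor; GG' = E W^+ E' with W^+ the eigenvalue-thresholded inverse
  g <- e_mk %*% sweep(ew$vectors[, keep, drop = FALSE], 2L, sqrt(ew$values[keep]), "/")
  structure(
    list(G = g, U_k = NULL, lambda_k = NULL, landmarks = landmarks,
         k_requested = k_requested, k_effective = ncol(g), tau = tau,
         sum_q = sum(colSums(g)^2)),
    class = "redundancy_factor"
  )
}

#' Top eigenpairs of the low-rank similarity matrix
#'
#' Eigen-decomposes the small `k' x k'` matrix `G'G` and maps back:
#' `lambda_k` are its eigenvalues and `U_k = G U_G diag(lambda_G^(-1/2))`,
#' which has orthonormal columns and satisfies
#' `U_k diag(lambda_k) U_k' = GG'`. Total cost `O(M k^2)`; no `M x M`
#' matrix is ever decomposed. Eigenvalues at or below `tau` times the
#' largest are dropped and `k_effective` updated.
#'
#' @param factor A [nystrom_factor()] result.
#' @param tau Relative eigenvalue threshold; defaults to the factor's.
#' @param max_rank Optional cap on the retained rank (used by the
#'   multi-task aggregation).
#' @return The factor with `U_k`, `lambda_k` (descending) populated.
#' @export
lowrank_eigenpairs <- function(factor, tau = factor$tau, max_rank = NULL) {
  stopifnot(inherits(factor, "redundancy_factor"))
  g <- factor$G
  eg <- eigen(crossprod(g), symmetric = TRUE)
  keep <- eg$values > tau * max(eg$values)
  if (!any(keep)) {
    stop_validation("degenerate redundancy structure: all eigenvalues below threshold")
  }
  if (!is.null(max_rank)) keep <- keep & (seq_along(eg$values) <= max_rank)
  vals <- eg$values[keep]
  factor$U_k <- g %*% sweep(eg$vectors[, keep, drop = FALSE], 2L, sqrt(vals), "/")
  factor$lambda_k <- vals
  factor$k_effective <- length(vals)
  factor
}

#' @export
print.redundancy_factor <- function(x, ...) {
  cat(sprintf(
    "Nystrom redundancy factor: %d features, %d landmark(s), effective rank %d\n",
    nrow(x$G), x$k_requested, x$k_effective
  ))
  if (!is.null(x$lambda_k)) {
    cat(sprintf("  eigenvalues: %.4g ... %.4g\n",
                max(x$lambda_k), min(x$lambda_k)))
  }
  invisible(x)
}
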