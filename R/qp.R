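# Convex QP core: the relaxed selection programs and the exhaustive binary
# oracle.
#
# All programs minimize  c'w + (lambda/m^2) w'Qw  over the relaxed set
# {w >= 0, sum(w) = m}. The reference path uses the dense Q; the working
# path replaces Q by its Nystrom approximation U_k diag(lambda_k) U_k',
# whose low-rank structure the interior-point solver exploits through
# Woodbury solves, keeping each iteration O(M k^2).

# ---- interior-point solver -------------------------------------------------

# Mehrotra predictor-corrector primal-dual interior point for
#   min c'w + 0.5 w'Hw   s.t.  w >= 0, 1'w = m
# with H given either dense (PSD) or as a low-rank factor V (H = VV').
# Deterministic; returns w, multipliers and KKT residuals.
#
# With `polish = TRUE` the converged iterate is refined by an exact KKT
# solve on the identified free set (verified, with fallback), which removes
# the interior-point smearing that matters when the curvature lambda/m^2 is
# tiny relative to the linear term. The polish is used by the dense
# reference solver only: the production ranking path deliberately keeps the
# interior-point limit, because on the flat directions of the objective
# (coordinates outside span(Q)) the strictly positive interior weights
# order features by their reduced costs, whereas the exact optimum sets
# them all to zero and carries no ranking information.
qp_ipm <- function(cvec, H = NULL, V = NULL, m, tol = 1e-10, max_iter = 300L,
                   polish = FALSE) {
  M <- length(cvec)
  lowrank <- is.null(H)
  if (lowrank && is.null(V)) V <- matrix(0, M, 0L)
  hmul <- if (lowrank) {
    if (ncol(V) == 0L) function(w) numeric(M) else function(w) drop(V %*% crossprod(V, w))
  } else {
    function(w) drop(H %*% w)
  }
  # Factory for solves with (H + diag(d)); low-rank path uses Woodbury.
  make_solver <- function(d) {
    if (lowrank) {
      di <- 1 / d
      if (ncol(V) == 0L) return(function(b) as.matrix(b) * di)
      VD <- V * di
      R <- chol(diag(ncol(V)) + crossprod(V, VD))
      function(b) {
        b <- as.matrix(b)
        db <- b * di
        db - VD %*% backsolve(R, backsolve(R, crossprod(V, db), transpose = TRUE))
      }
    } else {
      R <- chol(H + diag(d, M))
      function(b) backsolve(R, backsolve(R, as.matrix(b), transpose = TRUE))
    }
  }
  steplen <- function(x, dx) {
    neg <- dx < 0
    if (!any(neg)) 1 else min(1, min(-x[neg] / dx[neg]))
  }
  scale_c <- 1 + max(abs(cvec))
  w <- rep(m / M, M)
  mu <- rep(1, M)
  nu <- 0
  converged <- FALSE
  it <- 0L
  stall <- 0L
  best_crit <- Inf
  rd_inf <- rp_abs <- gap <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    rd <- hmul(w) + cvec - nu - mu
    rp <- sum(w) - m
    gap <- sum(w * mu) / M
    rd_inf <- max(abs(rd))
    rp_abs <- abs(rp)
    crit <- max(rd_inf / scale_c, rp_abs / (1 + m), gap / scale_c)
    if (crit < tol) {
      converged <- TRUE
      break
    }
    # stop once floating point blocks further progress; accept if close
    if (crit < 0.9 * best_crit) stall <- 0L else stall <- stall + 1L
    best_crit <- min(best_crit, crit)
    if (stall > 10L) {
      converged <- best_crit < 1e3 * tol
      break
    }
    d <- mu / w
    solv <- make_solver(d)
    sol1 <- solv(cbind(-rd - mu, rep(1, M)))
    x2 <- sol1[, 2L]
    s2 <- sum(x2)
    # affine (predictor) direction
    dnu_a <- (-rp - sum(sol1[, 1L])) / s2
    dw_a <- sol1[, 1L] + dnu_a * x2
    dmu_a <- -mu - d * dw_a
    ap <- steplen(w, dw_a)
    ad <- steplen(mu, dmu_a)
    gap_a <- sum((w + ap * dw_a) * (mu + ad * dmu_a)) / M
    sigma <- min(0.99, max(1e-8, (max(gap_a, 0) / gap)^3))
    # corrector with centering
    comp <- sigma * gap - dw_a * dmu_a
    x1 <- solv(-rd - mu + comp / w)
    dnu <- (-rp - sum(x1)) / s2
    dw <- drop(x1) + dnu * x2
    dmu <- comp / w - mu - d * dw
    ap <- 0.995 * steplen(w, dw)
    ad <- 0.995 * steplen(mu, dmu)
    w <- w + ap * dw
    mu <- mu + ad * dmu
    nu <- nu + ad * dnu
  }
  if (converged && polish) {
    pol <- qp_polish(cvec, H = H, V = V, m = m, w = w, hmul = hmul)
    if (!is.null(pol)) {
      w <- pol$w
      nu <- pol$nu
      mu <- pmax(0, hmul(w) + cvec - nu)
      rd_inf <- max(abs(hmul(w) + cvec - nu - mu))
      rp_abs <- abs(sum(w) - m)
      gap <- sum(w * mu) / M
    }
  }
  list(w = w, nu = nu, mu = mu, iterations = it, converged = converged,
       dual_residual = rd_inf, primal_residual = rp_abs, gap = gap)
}

# Active-set polish seeded by the interior-point support: repeatedly solve
#   [H_FF  -1; 1' 0] (w_F, nu) = (-c_F, m),  w = 0 off F,
# dropping coordinates that go negative and re-admitting dual violators,
# until the KKT conditions verify exactly. Returns NULL (keep the
# interior-point iterate) on any irregularity or when the free set is too
# large for dense solves.
qp_polish <- function(cvec, H, V, m, w, hmul, max_free = 1000L) {
  M <- length(cvec)
  free <- which(w > 1e-7 * m / sqrt(M))
  if (length(free) == 0L || length(free) > max_free) return(NULL)
  eps_p <- 1e-12 * max(m, 1)
  eps_d <- 1e-9 * (1 + max(abs(cvec)))
  h_sub <- function(idx) {
    if (is.null(H)) tcrossprod(V[idx, , drop = FALSE]) else H[idx, idx, drop = FALSE]
  }
  for (pass in 1:100) {
    nf <- length(free)
    if (nf == 0L || nf > max_free) return(NULL)
    kkt <- rbind(cbind(h_sub(free), -1), c(rep(1, nf), 0))
    sol <- tryCatch(solve(kkt, c(-cvec[free], m)), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) return(NULL)
    w_f <- sol[seq_len(nf)]
    nu <- sol[nf + 1L]
    if (any(w_f < -eps_p)) {
      free <- free[w_f > -eps_p]
      next
    }
    w_new <- numeric(M)
    w_new[free] <- pmax(w_f, 0)
    slack <- hmul(w_new) + cvec - nu
    viol <- setdiff(which(slack < -eps_d), free)
    if (length(viol) == 0L) return(list(w = w_new, nu = nu))
    free <- sort(c(free, viol[which.min(slack[viol])]))
  }
  NULL
}

# Shared constructor for solver outputs.
selection_solution <- function(w, alpha, lambda, m, objective, stats, method,
                               feature_ids = NULL) {
  below <- w < -1e-8
  if (any(below)) {
    warning(sprintf("clamping %d weight(s) below -1e-8 (min %.3g)", sum(below), min(w)))
  }
  w <- pmax(w, 0)
  if (!is.null(feature_ids)) names(w) <- feature_ids
  structure(
    list(w = w, alpha = alpha, lambda = lambda, m = m,
         objective = objective, selected = rank_and_select(w, m),
         solver = c(stats, list(method = method))),
    class = "bip_solution"
  )
}

#' Relevance/redundancy tradeoff weight
#'
#' The default balance `lambda = (m^2 / M) * |sum_i c_i| / sum_ij Q_ij`. In
#' the low-rank path `sum_ij Q_ij` is evaluated as `||G'1||^2 >= 0`. The
#' absolute value guards the sign: the separability term is negative for
#' discriminative data while the tradeoff weight must be nonnegative to keep
#' the program convex. A near-zero denominator falls back to `lambda = 1`
#' with a warning.
#'
#' @param cvec Linear separability term (see [linear_term()]).
#' @param redundancy Either a [nystrom_factor()] result or a dense
#'   similarity matrix.
#' @param m Number of features to select.
#' @param m_features Total feature count `M`; defaults to `length(cvec)`.
#' @return A nonnegative scalar.
#' @export
auto_lambda <- function(cvec, redundancy, m, m_features = length(cvec)) {
  if (m < 1L) stop_validation("m must be at least 1")
  sum_q <- if (inherits(redundancy, "redundancy_factor")) {
    redundancy$sum_q
  } else {
    sum(redundancy)
  }
  if (!is.finite(sum_q) || sum_q < 1e-12) {
    warning("sum of similarity entries is numerically zero; falling back to lambda = 1")
    return(1)
  }
  (m^2 / m_features) * abs(sum(cvec)) / sum_q
}

#' Solve the relaxed selection QP with a dense similarity matrix
#'
#' Reference path for small-to-moderate `M`: minimizes
#' `c'w + (lambda/m^2) w'Qw` subject to `w >= 0`, `sum(w) = m`.
#'
#' @param cvec Linear term of length `M`.
#' @param Q Symmetric positive semi-definite `M x M` similarity matrix.
#' @param lambda Nonnegative tradeoff weight.
#' @param m Number of features to select.
#' @param method `"ipm"` (interior point, handles singular `Q` exactly) or
#'   `"activeset"` (Goldfarb-Idnani via \pkg{quadprog}; a ridge of
#'   `1e-9 * max(diag)` is added when `Q` is not positive definite, since
#'   that method requires a PD Hessian).
#' @param tol Convergence tolerance on the scaled KKT residuals.
#' @return A `bip_solution` with elements `w`, `lambda`, `m`, `objective`,
#'   `selected` and `solver` diagnostics.
#' @export
solve_full_qp <- function(cvec, Q, lambda, m,
                          method = c("ipm", "activeset"), tol = 1e-9) {
  method <- match.arg(method)
  M <- length(cvec)
  if (lambda < 0) stop_validation("lambda must be nonnegative")
  if (m < 1L || m > M) stop_validation(sprintf("m must be in [1, %d]", M))
  if (!isTRUE(all.equal(dim(Q), c(M, M)))) stop_shape("Q must be M x M")
  gam <- lambda / m^2
  H <- 2 * gam * (Q + t(Q)) / 2
  if (method == "ipm") {
    res <- qp_ipm(cvec, H = H, m = m, tol = tol, polish = TRUE)
    if (!res$converged) {
      stop_solver(sprintf(
        "interior-point solver did not converge in %d iterations (dual %.2e, primal %.2e, gap %.2e)",
        res$iterations, res$dual_residual, res$primal_residual, res$gap
      ), stats = res[c("dual_residual", "primal_residual", "gap")])
    }
    w <- res$w
    stats <- res[c("iterations", "dual_residual", "primal_residual", "gap")]
  } else {
    Dmat <- H
    ok <- tryCatch({ chol(Dmat); TRUE }, error = function(e) FALSE)
    if (!ok) {
      ridge <- 1e-9 * max(diag(Dmat), 1e-12)
      Dmat <- Dmat + diag(ridge, M)
    }
    qp <- tryCatch(
      quadprog::solve.QP(Dmat = Dmat, dvec = -cvec,
                         Amat = cbind(rep(1, M), diag(M)),
                         bvec = c(m, rep(0, M)), meq = 1L),
      error = function(e) stop_solver(sprintf("active-set solver failed: %s",
                                              conditionMessage(e)))
    )
    w <- qp$solution
    stats <- list(iterations = qp$iterations[1L],
                  dual_residual = NA_real_,
                  primal_residual = abs(sum(w) - m),
                  gap = NA_real_)
  }
  stats$sum_w <- sum(w)
  obj <- sum(cvec * w) + gam * drop(crossprod(w, Q %*% w))
  selection_solution(w, alpha = NULL, lambda = lambda, m = m,
                     objective = obj, stats = stats, method = method,
                     feature_ids = names(cvec))
}

#' Solve the relaxed selection QP with the Nystrom low-rank quadratic term
#'
#' Working path for high-dimensional data: minimizes
#' `c'w + (lambda/m^2) w' (U_k diag(lambda_k) U_k') w` subject to
#' `w >= 0`, `sum(w) = m`, using the structured interior-point solver whose
#' per-iteration cost is `O(M k^2)`. When the factorization is exact
#' (`GG' = Q`) this coincides with [solve_full_qp()]. The reduced-space
#' coordinates `alpha = diag(lambda_k^(1/2)) U_k' w` are returned together
#' with the out-of-span residual `||w - U_k U_k' w||`; the two descriptions
#' agree exactly whenever the similarity matrix has full rank (see the
#' methods vignette for the rank-deficient case).
#'
#' The returned weights are the interior-point limit rather than an
#' exactly-sparse vertex: on coordinates where the objective is flat the
#' strictly positive weights decay with each feature's reduced cost, so the
#' induced ranking remains informative beyond the support of the exact
#' optimum — which is what a selection filter needs.
#'
#' @param cvec Linear term of length `M`.
#' @param factor A [nystrom_factor()] result with eigenpairs populated by
#'   [lowrank_eigenpairs()].
#' @param lambda Nonnegative tradeoff weight.
#' @param m Number of features to select.
#' @param tol Convergence tolerance on the scaled KKT residuals.
#' @return A `bip_solution`; `solver$span_residual` reports
#'   `max |w - U_k U_k' w|`.
#' @export
solve_reduced_qp <- function(cvec, factor, lambda, m, tol = 1e-9) {
  stopifnot(inherits(factor, "redundancy_factor"))
  if (is.null(factor$U_k)) {
    stop_validation("factor has no eigenpairs; call lowrank_eigenpairs() first")
  }
  M <- length(cvec)
  if (nrow(factor$U_k) != M) stop_shape("factor and linear term disagree on M")
  if (lambda < 0) stop_validation("lambda must be nonnegative")
  if (m < 1L || m > M) stop_validation(sprintf("m must be in [1, %d]", M))
  gam <- lambda / m^2
  V <- sweep(factor$U_k, 2L, sqrt(2 * gam * factor$lambda_k), "*")
  res <- qp_ipm(cvec, V = V, m = m, tol = tol)
  if (!res$converged) {
    stop_solver(sprintf(
      "interior-point solver did not converge in %d iterations (dual %.2e, primal %.2e, gap %.2e)",
      res$iterations, res$dual_residual, res$primal_residual, res$gap
    ), stats = res[c("dual_residual", "primal_residual", "gap")])
  }
  w <- res$w
  utw <- drop(crossprod(factor$U_k, w))
  alpha <- sqrt(factor$lambda_k) * utw
  stats <- res[c("iterations", "dual_residual", "primal_residual", "gap")]
  stats$sum_w <- sum(w)
  stats$span_residual <- max(abs(w - drop(factor$U_k %*% utw)))
  obj <- sum(cvec * w) + gam * sum(factor$lambda_k * utw^2)
  selection_solution(w, alpha = alpha, lambda = lambda, m = m,
                     objective = obj, stats = stats, method = "ipm_lowrank",
                     feature_ids = names(cvec))
}

#' Exhaustive binary optimum (test oracle)
#'
#' Enumerates every binary indicator with exactly `m` ones and returns the
#' subset minimizing `c'w + (lambda/m^2) w'Qw`. Ties resolve to the
#' lexicographically smallest index set. Refuses instances with more than
#' `10^6` subsets.
#'
#' @inheritParams solve_full_qp
#' @return List with `indices`, `objective` and the binary `w`.
#' @export
enumerate_binary_optimum <- function(cvec, Q, lambda, m) {
  M <- length(cvec)
  if (m < 1L || m > M) stop_validation(sprintf("m must be in [1, %d]", M))
  if (choose(M, m) > 1e6) {
    stop_validation(sprintf("C(%d, %d) exceeds the enumeration budget", M, m))
  }
  gam <- lambda / m^2
  subsets <- utils::combn(M, m)
  best <- NULL
  best_obj <- Inf
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    obj <- sum(cvec[s]) + gam * sum(Q[s, s])
    if (obj < best_obj - 0) {  # strict improvement keeps the first (lexicographic) tie
      best_obj <- obj
      best <- s
    }
  }
  w <- numeric(M)
  w[best] <- 1
  list(indices = best, objective = best_obj, w = w)
}

#' Rank features by weight and take the top m
#'
#' Stable descending sort; ties broken by ascending original column index.
#'
#' @param w Weight vector of length `M`.
#' @param m Number of features to select, `m <= M`.
#' @return Integer vector of `m` (1-based) indices.
#' @export
rank_and_select <- function(w, m) {
  if (m > length(w)) {
    stop_validation(sprintf("m = %d exceeds the number of features (%d)", m, length(w)))
  }
  order(-w, seq_along(w))[seq_len(m)]
}
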