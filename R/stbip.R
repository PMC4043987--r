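# Single-task pipeline: the main fitting function and its methods.

#' Single-task minimum-redundancy feature selection
#'
#' Runs the full filter pipeline on one labeled dataset: (1) compute the
#' class-separability term `c` from the agreement Laplacian; (2) pick `k`
#' landmark pseudo-features by k-means over the feature columns; (3) build
#' the Nystrom factor of the Pearson similarity matrix and (4) its top
#' eigenpairs; (5) set the tradeoff weight `lambda` from the data unless
#' supplied; (6) solve the relaxed convex QP
#' `min c'w + (lambda/m^2) w'Qw` over `w >= 0`, `sum(w) = m` with the
#' low-rank quadratic term; (7) rank features by the relaxed weights and
#' (8) flag the top `m`. Deterministic given `seed`.
#'
#' @param data An [expression_dataset()] with labels, or a numeric
#'   samples-by-features matrix (then `y` must be given).
#' @param m Number of features to select, `1 <= m <= M`.
#' @param k Number of k-means landmarks; defaults to [default_rank()]
#'   (`ceiling(0.1 * M)`, capped at `M`).
#' @param lambda Optional nonnegative relevance/redundancy tradeoff; when
#'   `NULL` (default) it is set by [auto_lambda()].
#' @param seed Integer seed driving the k-means restarts.
#' @param standardize Z-score the feature columns first (default `TRUE`;
#'   skipped when the dataset is already standardized). The separability
#'   term is scale-dependent while Pearson similarity is scale-free, so a
#'   shared scaling keeps the `lambda` balance meaningful.
#' @param y Labels, only used when `data` is a bare matrix.
#' @param tol Solver tolerance on the scaled KKT residuals.
#' @return An object of class `bip_fit`: relaxed weights `w` (named),
#'   reduced-space coordinates `alpha`, `selected` indices and
#'   `selected_ids`, `m`, `k_requested` / `k_effective`, `lambda` (and
#'   whether it was auto-set), `objective`, and `solver` diagnostics.
#' @seealso [mt_bip()] for the multi-task version, [write_selection()],
#'   [holdout_eval()].
#' @export
#' @examples
#' sim <- generate_expression(synthetic_config(n = 30, m_features = 60,
#'                                             n_informative = 5, seed = 4))
#' fit <- st_bip(sim$data, m = 10, seed = 4)
#' fit
#' head(coef(fit))
st_bip <- function(data, m, k = NULL, lambda = NULL, seed = 1L,
                   standardize = TRUE, y = NULL, tol = 1e-9) {
  if (is.matrix(data)) data <- expression_dataset(data, labels = y)
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(data$y)) stop_validation("st_bip needs a labeled dataset")
  M <- ncol(data$x)
  m <- as.integer(m)
  if (m < 1L || m > M) stop_validation(sprintf("m must be in [1, %d], got %d", M, m))
  if (standardize && !data$standardized) data <- standardize(data)
  k <- as.integer(k %||% default_rank(M))

  cvec <- with_stage("linear_term", linear_term(data))
  landmarks <- with_stage("kmeans_landmarks", kmeans_landmarks(data, k, seed = seed))
  factor <- with_stage("nystrom_factor", nystrom_factor(data, landmarks))
  factor <- with_stage("lowrank_eigenpairs", lowrank_eigenpairs(factor))
  lambda_auto <- is.null(lambda)
  if (lambda_auto) lambda <- auto_lambda(cvec, factor, m, M)
  if (lambda < 0) stop_validation("lambda must be nonnegative")
  sol <- with_stage("solve_reduced_qp", solve_reduced_qp(cvec, factor, lambda, m, tol = tol))

  structure(
    list(w = sol$w, alpha = sol$alpha, selected = sol$selected,
         selected_ids = data$feature_ids[sol$selected],
         feature_ids = data$feature_ids, m = m,
         k_requested = k, k_effective = factor$k_effective,
         lambda = lambda, lambda_auto = lambda_auto,
         objective = sol$objective, solver = sol$solver,
         c_term = cvec, n_samples = nrow(data$x), n_features = M,
         n_tasks = 1L, seed = seed, call = match.call()),
    class = "bip_fit"
  )
}

#' @export
print.bip_fit <- function(x, ...) {
  cat(sprintf("%s feature selection by relaxed binary integer programming\n",
              if (x$n_tasks > 1L) sprintf("Multi-task (%d tasks)", x$n_tasks) else "Single-task"))
  cat(sprintf("  features: %d, selected m = %d\n", x$n_features, x$m))
  cat(sprintf("  low-rank k: %d requested, %d effective\n", x$k_requested, x$k_effective))
  cat(sprintf("  lambda: %.6g%s\n", x$lambda, if (x$lambda_auto) " (auto)" else ""))
  cat(sprintf("  objective: %.6g  (solver: %s, %d iterations)\n",
              x$objective, x$solver$method, x$solver$iterations))
  preview <- utils::head(x$selected_ids, 8L)
  cat(sprintf("  top features: %s%s\n", paste(preview, collapse = ", "),
              if (x$m > 8L) ", ..." else ""))
  invisible(x)
}

#' @export
coef.bip_fit <- function(object, ...) object$w

#' @export
summary.bip_fit <- function(object, ...) {
  ord <- order(-object$w, seq_along(object$w))
  tab <- data.frame(
    rank = seq_along(object$w),
    feature_id = object$feature_ids[ord],
    weight = object$w[ord],
    separability = object$c_term[ord],
    selected = seq_along(object$w) <= object$m,
    row.names = NULL
  )
  structure(list(fit = object, ranking = tab,
                 weight_quartiles = stats::quantile(object$w),
                 weight_mass_selected = sum(object$w[object$selected]) / sum(object$w)),
            class = "summary.bip_fit")
}

#' @export
print.summary.bip_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weight mass on selected set: %.1f%%\n", 100 * x$weight_mass_selected))
  cat("  top of ranking:\n")
  print(utils::head(x$ranking, min(10L, nrow(x$ranking))), digits = 4)
  invisible(x)
}

#' Plot relaxed selection weights
#'
#' Weights in ranked order on a base-graphics plot, with the selected
#' features highlighted and a vertical line at the selection cutoff `m`.
#'
#' @param x A `bip_fit`.
#' @param max_features Cap on the number of ranked features drawn.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bip_fit <- function(x, max_features = 500L, ...) {
  ord <- order(-x$w, seq_along(x$w))
  n <- min(length(ord), max_features)
  w <- x$w[ord][seq_len(n)]
  sel <- seq_len(n) <= x$m
  graphics::plot(seq_len(n), w, type = "h",
                 col = ifelse(sel, "firebrick", "grey60"),
                 xlab = "rank", ylab = "relaxed weight",
                 main = sprintf("Selection weights (m = %d, lambda = %.3g)",
                                x$m, x$lambda), ...)
  graphics::abline(v = x$m + 0.5, lty = 2, col = "grey40")
  invisible(x)
}
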