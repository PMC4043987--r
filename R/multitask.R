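# Multi-task extension: aggregate per-task linear and quadratic terms and
# solve one shared-selection QP.
#
# With K related tasks the objective sums per-task terms under one shared
# indicator: min sum_j c_j'w + (lambda/m^2) w'(sum_j Q_j)w. The sum of
# per-task low-rank factors is represented exactly by column concatenation
# (G_total G_total' = sum_j G_j G_j') and then re-truncated to the
# configured rank by one extra eigenpair pass.

#' Bundle related tasks over one feature universe
#'
#' @param tasks List of labeled [expression_dataset()] objects whose
#'   `feature_ids` sequences are identical (same ids, same order).
#' @return An object of class `task_bundle`.
#' @export
task_bundle <- function(tasks) {
  if (inherits(tasks, "task_bundle")) return(tasks)
  if (inherits(tasks, "expr_dataset")) tasks <- list(tasks)
  if (length(tasks) < 1L) stop_validation("at least one task is required")
  lapply(tasks, function(t) stopifnot(inherits(t, "expr_dataset")))
  ref <- tasks[[1L]]$feature_ids
  for (t in seq_along(tasks)) {
    ids <- tasks[[t]]$feature_ids
    if (!identical(ids, ref)) {
      bad <- which(ids != ref)[1] %||% NA
      offending <- if (length(ids) != length(ref)) {
        sprintf("task %d has %d features, task 1 has %d", t, length(ids), length(ref))
      } else {
        sprintf("task %d: first mismatch at column %d ('%s' vs '%s')",
                t, bad, ids[bad], ref[bad])
      }
      bip_stop(sprintf("tasks do not share one feature universe: %s", offending),
               "bipfs_alignment_error")
    }
    if (is.null(tasks[[t]]$y)) {
      stop_validation(sprintf("task %d has no labels", t))
    }
  }
  structure(list(tasks = tasks, K = length(tasks), feature_ids = ref,
                 n_features = length(ref),
                 n_samples = vapply(tasks, function(t) nrow(t$x), 0L)),
            class = "task_bundle")
}

#' @export
print.task_bundle <- function(x, ...) {
  cat(sprintf("Task bundle: %d task(s) over %d shared features; N = %s\n",
              x$K, x$n_features, paste(x$n_samples, collapse = ", ")))
  invisible(x)
}

#' Read a multi-task manifest
#'
#' Plain-text list of tasks, one per line: an expression-matrix path and a
#' CLS label path separated by whitespace (or a tab). Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @param format Matrix format passed to [read_expression_matrix()].
#' @param orientation Matrix orientation, idem.
#' @return A [task_bundle()].
#' @export
read_task_manifest <- function(path, format = "tsv",
                               orientation = "samples_by_features") {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_format(sprintf("%s: manifest lists no tasks", path))
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  tasks <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[\t ]+")[[1L]]
    if (length(parts) != 2L) {
      stop_format(sprintf("%s: each manifest line needs '<matrix> <labels>', got '%s'", path, ln))
    }
    d <- read_expression_matrix(resolve(parts[1L]), format = format,
                                orientation = orientation)
    d$y <- encode_labels(read_cls_labels(resolve(parts[2L])), nrow(d$x))
    d
  })
  task_bundle(tasks)
}

#' Aggregate per-task terms for the shared-selection QP
#'
#' Computes `c_total = sum_j c_j` and a low-rank representation of
#' `sum_j Q_j`: the per-task Nystrom factors are column-concatenated
#' (exact for the sum) and re-truncated to the configured rank via one
#' eigenpair pass, keeping the `O(M (Kk)^2)` cost. All tasks reuse the same
#' landmark seed; their landmark sets still differ because the data differ.
#'
#' @param bundle A [task_bundle()].
#' @param k Landmarks per task; defaults to [default_rank()] of `M`.
#' @param seed Integer seed for the per-task k-means.
#' @param standardize Z-score each task's columns first (default `TRUE`).
#' @param tau Relative eigenvalue threshold.
#' @return List with `c_total`, `factor` (aggregated `redundancy_factor`
#'   with eigenpairs), `per_task_c`, `per_task_factor`, `k`.
#' @export
aggregate_tasks <- function(bundle, k = NULL, seed = 1L, standardize = TRUE,
                            tau = 1e-10) {
  bundle <- task_bundle(bundle)
  M <- bundle$n_features
  k <- as.integer(k %||% default_rank(M))
  per_task <- lapply(bundle$tasks, function(task) {
    if (standardize && !task$standardized) task <- standardize(task)
    cv <- linear_term(task)
    lm <- kmeans_landmarks(task, min(k, ncol(task$x)), seed = seed)
    fac <- nystrom_factor(task, lm, tau = tau)
    list(c = cv, factor = fac)
  })
  c_total <- Reduce(`+`, lapply(per_task, `[[`, "c"))
  g_total <- do.call(cbind, lapply(per_task, function(p) p$factor$G))
  agg <- structure(
    list(G = g_total, U_k = NULL, lambda_k = NULL, landmarks = NULL,
         k_requested = k, k_effective = ncol(g_total), tau = tau,
         sum_q = sum(vapply(per_task, function(p) p$factor$sum_q, 0))),
    class = "redundancy_factor"
  )
  agg <- lowrank_eigenpairs(agg, tau = tau, max_rank = k)
  list(c_total = c_total, factor = agg,
       per_task_c = lapply(per_task, `[[`, "c"),
       per_task_factor = lapply(per_task, `[[`, "factor"),
       k = k)
}

#' Multi-task minimum-redundancy feature selection
#'
#' Selects one shared subset of `m` features across `K` related labeled
#' datasets by solving the aggregated relaxed QP (see [aggregate_tasks()]).
#' With `K = 1` this reduces exactly to [st_bip()]. Tasks are not reweighted
#' by sample size by default (the aggregate is an unweighted sum);
#' `task_weights` overrides that.
#'
#' @param tasks A [task_bundle()] or list of labeled [expression_dataset()]s
#'   sharing one feature universe.
#' @inheritParams st_bip
#' @param task_weights Optional length-`K` nonnegative weights applied to
#'   each task's linear and quadratic term.
#' @return A `bip_fit` (with `n_tasks = K`).
#' @export
mt_bip <- function(tasks, m, k = NULL, lambda = NULL, seed = 1L,
                   standardize = TRUE, task_weights = NULL, tol = 1e-9) {
  bundle <- task_bundle(tasks)
  M <- bundle$n_features
  m <- as.integer(m)
  if (m < 1L || m > M) stop_validation(sprintf("m must be in [1, %d], got %d", M, m))
  k <- as.integer(k %||% default_rank(M))
  if (!is.null(task_weights)) {
    if (length(task_weights) != bundle$K || any(task_weights < 0)) {
      stop_validation("task_weights must be K nonnegative numbers")
    }
  }
  agg <- with_stage("aggregate_tasks", {
    a <- aggregate_tasks(bundle, k = k, seed = seed, standardize = standardize)
    if (!is.null(task_weights)) {
      a$c_total <- Reduce(`+`, Map(function(cv, wt) wt * cv, a$per_task_c, task_weights))
      g_total <- do.call(cbind, Map(function(p, wt) sqrt(wt) * p$G,
                                    a$per_task_factor, task_weights))
      fac <- structure(
        list(G = g_total, U_k = NULL, lambda_k = NULL, landmarks = NULL,
             k_requested = k, k_effective = ncol(g_total), tau = 1e-10,
             sum_q = sum(vapply(seq_along(task_weights), function(t) {
               task_weights[t] * a$per_task_factor[[t]]$sum_q
             }, 0))),
        class = "redundancy_factor"
      )
      a$factor <- lowrank_eigenpairs(fac, tau = 1e-10, max_rank = k)
    }
    a
  })
  lambda_auto <- is.null(lambda)
  if (lambda_auto) lambda <- auto_lambda(agg$c_total, agg$factor, m, M)
  if (lambda < 0) stop_validation("lambda must be nonnegative")
  # Solve the per-task average rather than the sum: the minimizer is
  # identical (the objective scales by K) but the solver then sees inputs
  # on the single-task scale, so K duplicated tasks reproduce the
  # single-task computation; the reported objective is scaled back.
  scale_k <- if (is.null(task_weights)) bundle$K else max(sum(task_weights), 1e-12)
  fac_norm <- agg$factor
  fac_norm$lambda_k <- fac_norm$lambda_k / scale_k
  sol <- with_stage("solve_reduced_qp",
                    solve_reduced_qp(agg$c_total / scale_k, fac_norm, lambda, m,
                                     tol = tol))
  sol$objective <- scale_k * sol$objective
  sol$alpha <- sqrt(scale_k) * sol$alpha
  structure(
    list(w = sol$w, alpha = sol$alpha, selected = sol$selected,
         selected_ids = bundle$feature_ids[sol$selected],
         feature_ids = bundle$feature_ids, m = m,
         k_requested = k, k_effective = agg$factor$k_effective,
         lambda = lambda, lambda_auto = lambda_auto,
         objective = sol$objective, solver = sol$solver,
         c_term = agg$c_total, n_samples = sum(bundle$n_samples),
         n_features = M, n_tasks = bundle$K, seed = seed,
         call = match.call()),
    class = "bip_fit"
  )
}
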