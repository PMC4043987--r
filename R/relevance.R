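# Class-agreement structure and the linear separability term.
#
# For labels y in {+1,-1}^N the agreement matrix is A = y y' (+1 for
# same-class pairs, -1 otherwise, +1 on the diagonal), D = diag(rowSums(A))
# and L = D - A its Laplacian. The signed sum of squared pairwise distances
# in the reweighted feature space collapses to a linear function of the
# selection indicator: the i-th feature contributes c_i = (X'LX)_ii.

#' Build the class-agreement matrix and its Laplacian
#'
#' @param labels Vector in `{+1, -1}`, one entry per sample.
#' @return An object of class `agreement` with elements `A` (agreement
#'   matrix), `D` (diagonal degree matrix, possibly negative), and
#'   `L = D - A`. Every row of `L` sums to zero.
#' @export
#' @examples
#' class_agreement(c(1, 1, -1))
class_agreement <- function(labels) {
  if (length(labels) == 0L) stop_validation("labels must be nonempty")
  if (!all(labels %in% c(-1, 1))) {
    stop_validation("labels must be encoded in {+1, -1}")
  }
  if (length(unique(labels)) == 1L) {
    warning("single-class labels: the objective reduces to intra-class tightness")
  }
  y <- as.numeric(labels)
  A <- tcrossprod(y)
  D <- diag(rowSums(A), nrow = length(y))
  structure(list(A = A, D = D, L = D - A, labels = y), class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Class-agreement structure over %d samples (%d / %d per class)\n",
              length(x$labels), sum(x$labels > 0), sum(x$labels < 0)))
  invisible(x)
}

#' Per-feature class-separability term
#'
#' Computes `c_i = (X'LX)_ii` for every feature, where `L` is the Laplacian
#' of the class-agreement matrix. Strongly discriminative features get large
#' negative values (inter-class distances dominate); constant features get 0.
#' The computation is a column-wise quadratic form, `O(N^2 M)`, and never
#' materializes per-pair distances.
#'
#' @param data An [expression_dataset()] (standardize first if downstream
#'   terms should share a scale).
#' @param agreement Optional [class_agreement()] built from the dataset's
#'   labels; derived from `data$y` when omitted.
#' @return Numeric vector of length `M`, named by feature id.
#' @export
linear_term <- function(data, agreement = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(agreement)) {
    if (is.null(data$y)) stop_validation("dataset has no labels and no agreement was given")
    agreement <- class_agreement(data$y)
  }
  if (nrow(agreement$L) != nrow(data$x)) {
    stop_validation(sprintf(
      "agreement built over %d samples but dataset has %d",
      nrow(agreement$L), nrow(data$x)
    ))
  }
  cvec <- colSums(data$x * (agreement$L %*% data$x))
  names(cvec) <- data$feature_ids
  cvec
}

#' Brute-force pairwise objective (test oracle)
#'
#' Evaluates the signed sum over all ordered sample pairs of the squared
#' Euclidean distance in the reweighted space,
#' `sum_{i,j} A_ij * ||x_i o w - x_j o w||^2`, by a direct double loop. For a
#' binary weight vector this equals `2 * c'w` (the ordered-pair sum double
#' counts each unordered pair, while `c` follows the single-count
#' convention). Intended as an independent check of [linear_term()]; cost is
#' quadratic in `N` and it should only be used on small instances.
#'
#' @param data An [expression_dataset()].
#' @param labels Labels in `{+1,-1}`; defaults to `data$y`.
#' @param w Nonnegative weight vector of length `M`.
#' @return A single number.
#' @export
pairwise_objective_oracle <- function(data, labels = data$y, w) {
  stopifnot(inherits(data, "expr_dataset"))
  if (any(w < 0)) stop_validation("w must be elementwise nonnegative")
  if (length(w) != ncol(data$x)) stop_shape("w must have one entry per feature")
  y <- as.numeric(labels)
  n <- nrow(data$x)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- if (y[i] == y[j]) 1 else -1
      d <- (data$x[i, ] - data$x[j, ]) * w
      total <- total + a * sum(d * d)
    }
  }
  total
}
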