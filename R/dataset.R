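# Canonical dataset container and file I/O (GCT / CLS / TSV / CSV).

#' Construct an expression dataset
#'
#' The canonical container used throughout the package: a numeric
#' samples-by-features matrix plus optional two-class labels encoded as
#' `{+1, -1}`. Missing values are rejected; imputation is out of scope.
#'
#' @param values Numeric matrix, `N` samples (rows) by `M` features (columns).
#' @param labels Optional vector of length `N` with exactly two distinct
#'   values. Numeric `{+1, -1}` labels are kept as-is; any other pair is
#'   encoded with the lexicographically first value mapped to `+1`.
#' @param feature_ids,sample_ids Optional identifier vectors; default to the
#'   matrix dimnames or generated `f<i>` / `s<i>` names. Feature ids must be
#'   unique.
#' @param standardized Logical flag recording whether columns have been
#'   z-scored (see [standardize()]).
#'
#' @return An object of class `expr_dataset` with elements `x`, `y`,
#'   `feature_ids`, `sample_ids`, `standardized`.
#' @seealso [read_expression_matrix()], [read_cls_labels()], [standardize()]
#' @export
#' @examples
#' d <- expression_dataset(matrix(rnorm(20), 4, 5), labels = c(1, 1, -1, -1))
#' d
expression_dataset <- function(values, labels = NULL, feature_ids = NULL,
                               sample_ids = NULL, standardized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_validation("expression values must be numeric")
  }
  if (anyNA(values)) {
    stop_validation("expression matrix contains missing values; imputation is not supported")
  }
  n <- nrow(values)
  m <- ncol(values)
  feature_ids <- as.character(feature_ids %||% colnames(values) %||% sprintf("f%d", seq_len(m)))
  sample_ids <- as.character(sample_ids %||% rownames(values) %||% sprintf("s%d", seq_len(n)))
  if (length(feature_ids) != m) {
    stop_shape(sprintf("feature_ids length (%d) != number of columns (%d)", length(feature_ids), m))
  }
  if (length(sample_ids) != n) {
    stop_shape(sprintf("sample_ids length (%d) != number of rows (%d)", length(sample_ids), n))
  }
  if (anyDuplicated(feature_ids)) {
    stop_validation(sprintf(
      "duplicate feature ids: %s",
      paste(unique(feature_ids[duplicated(feature_ids)])[1:min(5, m)], collapse = ", ")
    ))
  }
  y <- if (is.null(labels)) NULL else encode_labels(labels, n)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(x = values, y = y, feature_ids = feature_ids, sample_ids = sample_ids,
         standardized = isTRUE(standardized)),
    class = "expr_dataset"
  )
}

encode_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop_shape(sprintf("labels length (%d) != number of samples (%d)", length(labels), n))
  }
  if (anyNA(labels)) stop_validation("labels contain missing values")
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    y <- as.numeric(labels)
  } else {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) > 2L) {
      stop_validation(sprintf("expected 2 classes, found %d", length(lev)))
    }
    y <- ifelse(as.character(labels) == lev[1L], 1, -1)
  }
  if (length(unique(y)) == 1L) {
    warning("labels contain a single class; only intra-class tightness is measurable")
  }
  y
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "Expression dataset: %d samples x %d features%s\n",
    nrow(x$x), ncol(x$x), if (x$standardized) " (standardized)" else ""
  ))
  if (!is.null(x$y)) {
    cat(sprintf("  classes: %d positive / %d negative\n", sum(x$y > 0), sum(x$y < 0)))
  } else {
    cat("  labels: unset\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$x)

#' Read an expression matrix from TSV, CSV or GCT
#'
#' Plain TSV/CSV files carry a header row and an identifier first column; the
#' `orientation` argument states whether rows are samples (default) or
#' features. GCT v1.2 files are always genes-by-samples and are transposed on
#' read, so the returned dataset is always samples-by-features. Labels are
#' left unset; pair with [read_cls_labels()].
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`.
#' @param orientation `"samples_by_features"` (default) or
#'   `"features_by_samples"`; ignored for GCT (always features-by-samples).
#' @return An [expression_dataset()] with `y = NULL`.
#' @export
read_expression_matrix <- function(path,
                                   format = c("tsv", "csv", "gct"),
                                   orientation = c("samples_by_features",
                                                   "features_by_samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  if (format == "gct") {
    return(read_gct(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop_format(sprintf("%s: expected an id column plus data columns", path))
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop_format(sprintf(
      "%s: non-numeric value '%s' at data row %d, column '%s'",
      path, vals[bad[1L], bad[2L]], bad[1L], colnames(vals)[bad[2L]]
    ))
  }
  if (orientation == "features_by_samples") {
    expression_dataset(t(num), feature_ids = ids, sample_ids = colnames(vals))
  } else {
    expression_dataset(num, feature_ids = colnames(vals), sample_ids = ids)
  }
}

read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_format(sprintf("%s: GCT needs at least 3 lines", path))
  if (trimws(lines[1L]) != "#1.2") {
    stop_format(sprintf("%s: line 1 must be '#1.2', found '%s'", path, lines[1L]))
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(dims) != 2L || anyNA(dims)) {
    stop_format(sprintf("%s: line 2 must hold '<n_genes> <n_samples>'", path))
  }
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || tolower(header[1L]) != "name") {
    stop_format(sprintf("%s: line 3 must be a 'Name<TAB>Description<TAB>...' header", path))
  }
  sample_ids <- header[-(1:2)]
  if (length(sample_ids) != dims[2L]) {
    stop_shape(sprintf(
      "%s: dims line declares %d samples but header has %d",
      path, dims[2L], length(sample_ids)
    ))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1L]) {
    stop_shape(sprintf(
      "%s: dims line declares %d genes but %d data rows follow",
      path, dims[1L], length(body)
    ))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(header))) {
    stop_shape(sprintf(
      "%s: data row %d has %d fields, expected %d",
      path, which(nfield != length(header))[1L], nfield[nfield != length(header)][1L],
      length(header)
    ))
  }
  gene_ids <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-(1:2)]))
    v
  }, numeric(dims[2L]))
  if (anyNA(vals)) {
    stop_format(sprintf("%s: non-numeric expression value in data block", path))
  }
  # vals is samples x genes after vapply; exactly the internal orientation
  expression_dataset(matrix(vals, nrow = dims[2L]),
                     feature_ids = gene_ids, sample_ids = sample_ids)
}

#' Read two-class labels in CLS format
#'
#' CLS dialect: line 1 is `<N> <n_classes> 1`, line 2 is `# <name0> <name1>`,
#' line 3 holds `N` space-separated tokens (class names or 0/1 codes). The
#' first-listed class maps to `+1`, the second to `-1`.
#'
#' @param path File path.
#' @return Numeric vector of `N` labels in `{+1, -1}`.
#' @export
read_cls_labels <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_format(sprintf("%s: CLS needs 3 lines", path))
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2])) {
    stop_format(sprintf("%s: line 1 must be '<N> <n_classes> 1'", path))
  }
  if (hdr[2L] != 2L) {
    stop_validation(sprintf("%s: only two-class CLS is supported, found %d classes", path, hdr[2L]))
  }
  names_line <- strsplit(trimws(sub("^#", "", lines[2L])), "\\s+")[[1L]]
  tokens <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (length(tokens) != hdr[1L]) {
    stop_shape(sprintf(
      "%s: declared N = %d but found %d label tokens", path, hdr[1L], length(tokens)
    ))
  }
  if (length(names_line) >= 2L && all(tokens %in% names_line[1:2])) {
    y <- ifelse(tokens == names_line[1L], 1, -1)
  } else {
    codes <- suppressWarnings(as.integer(tokens))
    if (anyNA(codes) || !all(codes %in% c(0L, 1L))) {
      stop_format(sprintf("%s: label tokens must be the class names or 0/1 codes", path))
    }
    y <- ifelse(codes == 0L, 1, -1)
  }
  y
}

#' Z-score the feature columns of a dataset
#'
#' Each feature column is centered and divided by its sample standard
#' deviation (denominator `N - 1`). Constant columns become all-zero and are
#' reported with a warning. The centering/scaling vectors are stored on the
#' result so they can be re-applied to held-out data without leakage.
#'
#' @param data An [expression_dataset()] with at least 2 samples.
#' @return The dataset with standardized columns, `standardized = TRUE`, and
#'   `center` / `scale` elements.
#' @export
standardize <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  if (nrow(data$x) < 2L) stop_validation("standardization needs at least 2 samples")
  ctr <- colMeans(data$x)
  sdv <- apply(data$x, 2L, stats::sd)
  const <- sdv <= 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf(
      "%d constant feature column(s) set to zero: %s",
      sum(const), paste(utils::head(data$feature_ids[const], 5L), collapse = ", ")
    ))
    sdv[const] <- 1
  }
  data$x <- sweep(sweep(data$x, 2L, ctr), 2L, sdv, "/")
  data$center <- ctr
  data$scale <- sdv
  data$standardized <- TRUE
  data
}

# Apply a previously learned standardization (train statistics) to new data.
apply_standardization <- function(data, center, scale) {
  data$x <- sweep(sweep(data$x, 2L, center), 2L, scale, "/")
  data$standardized <- TRUE
  data
}

#' Write a ranked selection to a TSV file
#'
#' Writes one row per feature, sorted by weight (descending; ties broken by
#' ascending original column index), with columns `rank`, `feature_id`,
#' `weight` and `selected` (1 for the top `m` features, else 0).
#'
#' @param fit A [st_bip()] / [mt_bip()] fit, or any object with elements
#'   `w` and `m`.
#' @param path Output file path.
#' @param feature_ids Identifiers for the weights; defaults to the ones
#'   stored in the fit.
#' @return The ranking `data.frame`, invisibly.
#' @export
write_selection <- function(fit, path, feature_ids = NULL) {
  w <- fit$w
  m <- fit$m
  feature_ids <- feature_ids %||% fit$feature_ids %||% names(w) %||%
    sprintf("f%d", seq_along(w))
  if (length(feature_ids) != length(w)) {
    stop_shape("feature_ids length does not match the weight vector")
  }
  ord <- order(-w, seq_along(w))
  out <- data.frame(
    rank = seq_along(w),
    feature_id = feature_ids[ord],
    weight = w[ord],
    selected = as.integer(seq_along(w) <= m),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) bip_stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
                            "bipfs_io_error")
  invisible(out)
}

#' Write an expression dataset to TSV, CSV or GCT
#'
#' The TSV/CSV layout is the exact inverse of [read_expression_matrix()]
#' (id column `sample_id`, feature names in the header). GCT output is
#' genes-by-samples with a constant `na` description column.
#'
#' @param data An [expression_dataset()].
#' @param path Output file path.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(data, path, format = c("tsv", "csv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "expr_dataset"))
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#1.2", con)
    writeLines(sprintf("%d\t%d", ncol(data$x), nrow(data$x)), con)
    writeLines(paste(c("Name", "Description", data$sample_ids), collapse = "\t"), con)
    body <- apply(t(data$x), 1L, function(v) paste(format(v, digits = 17), collapse = "\t"))
    writeLines(paste(data$feature_ids, "na", body, sep = "\t"), con)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    out <- data.frame(sample_id = data$sample_ids, data$x,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write two-class labels in CLS format
#'
#' @param labels Vector of labels in `{+1, -1}`.
#' @param path Output file path.
#' @param class_names Length-2 names for the `+1` and `-1` classes.
#' @return `path`, invisibly.
#' @export
write_cls_labels <- function(labels, path, class_names = c("pos", "neg")) {
  y <- encode_labels(labels, length(labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d 2 1", length(y)), con)
  writeLines(sprintf("# %s %s", class_names[1L], class_names[2L]), con)
  writeLines(paste(ifelse(y > 0, 0L, 1L), collapse = " "), con)
  invisible(path)
}
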