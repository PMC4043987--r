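test_that("GCT files are parsed, validated and transposed to samples x features", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(
    "#1.2",
    "2\t3",
    "Name\tDescription\ts1\ts2\ts3",
    "geneA\tna\t1\t2\t3",
    "geneB\tna\t4\t5\t6"
  ), path)
  d <- read_expression_matrix(path, format = "gct")
  expect_s3_class(d, "expr_dataset")
  expect_equal(dim(d$x), c(3L, 2L))
  expect_equal(d$feature_ids, c("geneA", "geneB"))
  expect_equal(d$sample_ids, c("s1", "s2", "s3"))
  expect_equal(unname(d$x[, "geneA"]), c(1, 2, 3))

  bad_header <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t3", "Name\tDescription\ts1\ts2\ts3"), bad_header)
  expect_error(read_expression_matrix(bad_header, format = "gct"),
               class = "bipfs_format_error")

  short <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(
    "#1.2", "5\t3", "Name\tDescription\ts1\ts2\ts3",
    "g1\tna\t1\t2\t3", "g2\tna\t4\t5\t6", "g3\tna\t7\t8\t9", "g4\tna\t1\t1\t1"
  ), short)
  expect_error(read_expression_matrix(short, format = "gct"),
               class = "bipfs_shape_error")

  dup <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(
    "#1.2", "2\t2", "Name\tDescription\ts1\ts2",
    "g1\tna\t1\t2", "g1\tna\t3\t4"
  ), dup)
  expect_error(read_expression_matrix(dup, format = "gct"),
               class = "bipfs_validation_error")
})

test_that("TSV write/read round trip preserves values and identifiers", {
  d <- random_dataset(4, 6, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(d, path, format = "tsv")
  d2 <- read_expression_matrix(path, format = "tsv")
  expect_equal(d2$feature_ids, d$feature_ids)
  expect_equal(d2$sample_ids, d$sample_ids)
  expect_lt(max(abs(d2$x - d$x)), 1e-12)

  gct <- withr::local_tempfile(fileext = ".gct")
  write_expression_matrix(d, gct, format = "gct")
  d3 <- read_expression_matrix(gct, format = "gct")
  expect_equal(d3$feature_ids, d$feature_ids)
  expect_lt(max(abs(d3$x - d$x)), 1e-12)

  # features-by-samples orientation flips back on read
  tpath <- withr::local_tempfile(fileext = ".tsv")
  flipped <- expression_dataset(t(d$x), feature_ids = d$sample_ids,
                                sample_ids = d$feature_ids)
  write_expression_matrix(flipped, tpath, format = "tsv")
  d4 <- read_expression_matrix(tpath, format = "tsv",
                               orientation = "features_by_samples")
  expect_equal(d4$x, d$x, ignore_attr = TRUE)
})

test_that("non-numeric cells and missing values are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t1.5\toops", "s2\t2\t3"), path)
  expect_error(read_expression_matrix(path, format = "tsv"),
               class = "bipfs_format_error")
  expect_error(expression_dataset(matrix(c(1, NA, 3, 4), 2, 2)),
               class = "bipfs_validation_error")
})

test_that("CLS labels parse with first-listed class mapped to +1", {
  path <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# pos neg", "0 0 1 1"), path)
  expect_equal(read_cls_labels(path), c(1, 1, -1, -1))

  named <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# tumor normal", "tumor normal normal tumor"), named)
  expect_equal(read_cls_labels(named), c(1, -1, -1, 1))

  three <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("2 3 1", "# a b c", "0 1"), three)
  expect_error(read_cls_labels(three), class = "bipfs_validation_error")

  short <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# pos neg", "0 0 1"), short)
  expect_error(read_cls_labels(short), class = "bipfs_shape_error")

  # writer round trip
  out <- withr::local_tempfile(fileext = ".cls")
  write_cls_labels(c(1, -1, -1, 1), out)
  expect_equal(read_cls_labels(out), c(1, -1, -1, 1))
})

test_that("standardization z-scores columns, zeroes constants, and is idempotent", {
  d <- expression_dataset(cbind(a = c(1, 3), b = c(2, 2)))
  expect_warning(s <- standardize(d), "constant")
  expect_equal(unname(s$x[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(s$x[, "b"]), c(0, 0))
  expect_true(s$standardized)

  d2 <- random_dataset(10, 5, seed = 2)
  s1 <- standardize(d2)
  expect_equal(colMeans(s1$x), rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(s1$x, 2, sd), rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
  s2 <- standardize(s1)
  expect_lt(max(abs(s2$x - s1$x)), 1e-12)
  expect_equal(s1$feature_ids, d2$feature_ids)
  expect_equal(nrow(s1$x), nrow(d2$x))
})

test_that("selection rankings are written sorted with deterministic tie-breaks", {
  fit <- list(w = c(0.5, 2, 1), m = 2L, feature_ids = c("f1", "f2", "f3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_selection(fit, path)
  expect_equal(out$feature_id, c("f2", "f3", "f1"))
  expect_equal(out$selected, c(1L, 1L, 0L))
  reread <- read.delim(path)
  expect_equal(reread$feature_id, c("f2", "f3", "f1"))
  expect_equal(reread$rank, 1:3)

  # all-equal weights keep original column order
  ties <- list(w = rep(1, 4), m = 3L, feature_ids = paste0("g", 1:4))
  out2 <- write_selection(ties, withr::local_tempfile(fileext = ".tsv"))
  expect_equal(out2$feature_id, paste0("g", 1:4))

  # m = M flags every row
  all_sel <- list(w = c(3, 1, 2), m = 3L, feature_ids = c("a", "b", "c"))
  out3 <- write_selection(all_sel, withr::local_tempfile(fileext = ".tsv"))
  expect_true(all(out3$selected == 1L))
})
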