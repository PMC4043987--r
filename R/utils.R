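# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to causes.
bip_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bipfs_error"), call = call))
}

stop_validation <- function(msg) bip_stop(msg, "bipfs_validation_error")
stop_format <- function(msg) bip_stop(msg, "bipfs_format_error")
stop_shape <- function(msg) bip_stop(msg, "bipfs_shape_error")
stop_solver <- function(msg, stats = NULL) {
  cond <- errorCondition(msg, class = c("bipfs_solver_error", "bipfs_error"))
  cond$stats <- stats
  stop(cond)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Prefix condition messages with the pipeline stage that raised them.
with_stage <- function(stage, expr) {
  tryCatch(expr, bipfs_error = function(e) {
    e$message <- sprintf("%s: %s", stage, conditionMessage(e))
    stop(e)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
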