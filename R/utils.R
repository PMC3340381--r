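#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded helpers do not
#' perturb the global random stream. A `NULL` seed evaluates the expression
#' under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps results < 2^31 so they remain valid R integer seeds.
child_seed <- function(seed, label) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_simplex <- function(x, what, tol = 1e-12) {
  if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) ||
      abs(sum(x) - 1) > tol) {
    stop_config(
      "%s must be a non-negative (a2, c2, e2) triple summing to 1; got (%s)",
      what, paste(signif(x, 6), collapse = ", ")
    )
  }
  invisible(x)
}
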