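# Classed conditions so callers (and the CLI) can distinguish bad input
# (exit 2) from numerical failure (exit 3).
stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tlpca_validation_error", "tlpca_error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tlpca_numerical_error", "tlpca_error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Full-precision decimal formatting for text round-trips.
format_full <- function(x) sprintf("%.17g", x)

is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}
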