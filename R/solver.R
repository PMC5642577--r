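as_tensor_array <- function(x) {
  if (inherits(x, "fragment_tensor")) return(x$X)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_validation("expected a fragment_tensor or a 3-D array")
}

#' Collapse a tensor onto the property axis
#'
#' Contracts the descriptor tensor against fragment coefficients:
#' `F[i, k] = sum_l b[l] * X[i, l, k]`, yielding the N x K property matrix
#' used in the A-step of the alternating fit.
#'
#' @param x a [fragment_tensor()] or N x L x K array.
#' @param b numeric fragment coefficient vector of length L.
#' @return An N x K numeric matrix with sample/property dimnames.
#' @export
collapse_to_property_matrix <- function(x, b) {
  X <- as_tensor_array(x)
  d <- dim(X)
  if (length(b) != d[2])
    stop_validation("'b' has length ", length(b), " but the tensor has ",
                    d[2], " fragments")
  F <- matrix(0, d[1], d[3], dimnames = dimnames(X)[c(1, 3)])
  for (k in seq_len(d[3]))
    F[, k] <- matrix(X[, , k], d[1], d[2]) %*% b
  F
}

#' Collapse a tensor onto the fragment axis
#'
#' Contracts the descriptor tensor against property coefficients:
#' `H[i, l] = sum_k a[k] * X[i, l, k]`. Row i, column l is the contribution
#' of fragment l to the activity of sample i (before fragment weighting).
#'
#' @param x a [fragment_tensor()] or N x L x K array.
#' @param a numeric property coefficient vector of length K.
#' @return An N x L numeric matrix with sample/fragment dimnames.
#' @export
collapse_to_fragment_matrix <- function(x, a) {
  X <- as_tensor_array(x)
  d <- dim(X)
  if (length(a) != d[3])
    stop_validation("'a' has length ", length(a), " but the tensor has ",
                    d[3], " properties")
  H <- matrix(0, d[1], d[2], dimnames = dimnames(X)[c(1, 2)])
  for (l in seq_len(d[2]))
    H[, l] <- matrix(X[, l, ], d[1], d[3]) %*% a
  H
}

#' Solve a symmetric normal system through its eigendecomposition
#'
#' Solves `M z = rhs` for symmetric positive semi-definite `M` by
#' assembling the pseudo-inverse from the eigenpairs of `M`:
#' `z = Phi diag(1/beta) Phi' rhs`, keeping only eigenvalues above
#' `inversion_rtol` times the largest. If `principal_energy` is set, the
#' retained set is further truncated to the leading components whose
#' normalized eigenvalues cumulatively reach that fraction — the
#' principal-component regularized inverse.
#'
#' @param M symmetric p x p numeric matrix.
#' @param rhs numeric right-hand side of length p.
#' @param inversion_rtol relative eigenvalue cutoff (default `1e-10`).
#' @param principal_energy optional fraction in (0, 1]; cumulative
#'   normalized-eigenvalue truncation. Default `NULL` keeps every component
#'   above `inversion_rtol`.
#' @return Numeric solution vector of length p.
#' @export
solve_normal_system <- function(M, rhs, inversion_rtol = 1e-10,
                                principal_energy = NULL) {
  if (!is_symmetric_tol(M))
    stop_validation("'M' is not symmetric within tolerance")
  if (length(rhs) != nrow(M))
    stop_validation("'rhs' length ", length(rhs), " does not match order ",
                    nrow(M))
  e <- eigen(M, symmetric = TRUE)  # eigenvalues already descending
  keep <- e$values > inversion_rtol * max(e$values, 0)
  if (!any(keep))
    stop_numerical("all eigenvalues below the inversion cutoff; ",
                   "the normal system is singular")
  if (!is.null(principal_energy)) {
    if (!(principal_energy > 0 && principal_energy <= 1))
      stop_validation("'principal_energy' must lie in (0, 1]")
    shares <- e$values / sum(e$values)
    m <- which(cumsum(shares) >= principal_energy - 1e-12)[1]
    keep <- keep & seq_along(e$values) <= m
  }
  phi <- e$vectors[, keep, drop = FALSE]
  drop(phi %*% (crossprod(phi, rhs) / e$values[keep]))
}

#' Pearson correlation between predicted and experimental activities
#'
#' @param pred,expt numeric vectors of equal length (>= 3), neither
#'   constant.
#' @return The Pearson product-moment correlation.
#' @export
pearson_r <- function(pred, expt) {
  if (length(pred) != length(expt))
    stop_validation("'pred' and 'expt' differ in length")
  if (length(pred) < 3L)
    stop_validation("need at least 3 observations for a correlation")
  if (sd(pred) == 0 || sd(expt) == 0)
    stop_numerical("correlation undefined for a constant vector")
  cor(pred, expt)
}

#' Root-mean-square residue between predicted and experimental activities
#'
#' `Q = sqrt(mean((expt - pred)^2))`, the convergence quantity of the
#' alternating fit.
#'
#' @param pred,expt numeric vectors of equal length.
#' @return The RMS residue (>= 0).
#' @export
q_residue <- function(pred, expt) {
  if (length(pred) != length(expt))
    stop_validation("'pred' and 'expt' differ in length")
  sqrt(mean((expt - pred)^2))
}

#' Solver settings for the alternating two-level fit
#'
#' @param epsilon convergence threshold on `|Q(n+1) - Q(n)|` between
#'   successive full cycles (default `1e-6` pIC50 units).
#' @param max_iterations iteration cap (default 500).
#' @param init_b starting fragment coefficients: a scalar recycled over L
#'   or a length-L vector. Default 1 — all fragments initially equally
#'   important.
#' @param inversion_rtol relative eigenvalue cutoff for the pseudo-inverse.
#' @param principal_energy optional cumulative-eigenvalue truncation used
#'   inside the half-step solves; default `NULL` (off).
#' @param seed integer recorded for provenance; the fit itself is
#'   deterministic.
#' @return A list of class `tlpca_config`.
#' @export
tlpca_config <- function(epsilon = 1e-6, max_iterations = 500L, init_b = 1,
                         inversion_rtol = 1e-10, principal_energy = NULL,
                         seed = NULL) {
  if (!(is.numeric(epsilon) && epsilon > 0))
    stop_validation("'epsilon' must be > 0")
  if (max_iterations < 1L) stop_validation("'max_iterations' must be >= 1")
  if (!is.null(principal_energy) &&
      !(principal_energy > 0 && principal_energy <= 1))
    stop_validation("'principal_energy' must lie in (0, 1]")
  structure(list(epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 init_b = init_b, inversion_rtol = inversion_rtol,
                 principal_energy = principal_energy, seed = seed),
            class = "tlpca_config")
}

new_tlpca <- function(A, B, property_names, fragment_labels,
                      config = tlpca_config(), trace = NULL,
                      n_iterations = NA_integer_, converged = NA,
                      fitted.values = NULL, residuals = NULL,
                      activities = NULL, property_table = NULL,
                      call = NULL) {
  names(A) <- property_names
  names(B) <- fragment_labels
  structure(list(coefficients = list(property = A, fragment = B),
                 property_names = property_names,
                 fragment_labels = fragment_labels,
                 n_iterations = n_iterations, converged = converged,
                 trace = trace, fitted.values = fitted.values,
                 residuals = residuals, activities = activities,
                 config = config, property_table = property_table,
                 call = call),
            class = "tlpca")
}

#' Fit the two-level bilinear activity model
#'
#' Fits `w_i = sum_l b_l sum_k a_k x_{i,l,k}` — one coefficient per
#' physicochemical property (shared across fragments) and one per fragment
#' position (shared across properties) — by alternating least squares.
#' Starting from `B = init_b`, each cycle (i) collapses the tensor against
#' the current `B` into the property matrix `F` and solves the normal
#' system `(F'F) A = F'W` for new property coefficients, then (ii)
#' collapses against the new `A` into the fragment matrix `H` and solves
#' `(H'H) B = H'W` for new fragment coefficients. Both solves go through
#' the truncated eigendecomposition pseudo-inverse
#' ([solve_normal_system()]). After each half-step the Pearson correlation
#' R and RMS residue Q between fitted and experimental activities are
#' recorded; iteration stops when the B-step Q changes by at most
#' `epsilon` between cycles, or at `max_iterations` (then with a warning
#' and `converged = FALSE`).
#'
#' The model has no intercept, and the bilinear form leaves the joint
#' scale of `A` and `B` indeterminate (`(c A, B / c)` predicts
#' identically); coefficients are reported as the iteration leaves them —
#' see [rescale_coefficients()] for a normalized view.
#'
#' @param x a [fragment_tensor()] carrying activities, or a 3-D array with
#'   dimnames (then `activity` must be given).
#' @param activity optional activity vector overriding `x$W`.
#' @param config a [tlpca_config()]; individual settings may instead be
#'   passed through `...`.
#' @param ... settings forwarded to [tlpca_config()] when `config` is not
#'   supplied.
#' @return An object of class `tlpca` with components `coefficients`
#'   (named property and fragment vectors), `trace` (per-iteration
#'   `iteration, R_a, Q_a, R_b, Q_b`), `n_iterations`, `converged`,
#'   `fitted.values`, `residuals` and the configuration used. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' bench <- hla_benchmark()
#' x <- encode_peptides(bench$train, bench$property_table)
#' fit <- tlpca(x)
#' fit
#' pearson_r(fitted(fit), x$W)
#' @export
tlpca <- function(x, activity = NULL, config = NULL, ...) {
  if (is.null(config)) config <- tlpca_config(...)
  if (is.array(x) && !inherits(x, "fragment_tensor"))
    x <- fragment_tensor(x, W = activity)
  if (!inherits(x, "fragment_tensor"))
    stop_validation("'x' must be a fragment_tensor")
  W <- if (!is.null(activity)) as.numeric(activity) else x$W
  if (is.null(W))
    stop_validation("activities are required to fit the model")
  d <- dim(x$X)
  if (length(W) != d[1])
    stop_validation("activity length ", length(W), " does not match ",
                    d[1], " samples")
  N <- d[1]; L <- d[2]; K <- d[3]
  if (N <= max(K, L))
    warning("only ", N, " samples for ", L, " fragment and ", K,
            " property coefficients; the fit may be under-determined",
            call. = FALSE)
  B <- rep_len(as.numeric(config$init_b), L)
  trace <- matrix(NA_real_, config$max_iterations, 5L,
                  dimnames = list(NULL,
                                  c("iteration", "R_a", "Q_a", "R_b", "Q_b")))
  q_prev <- Inf
  converged <- FALSE
  n <- 0L
  A <- wb <- NULL
  for (n in seq_len(config$max_iterations)) {
    F <- collapse_to_property_matrix(x, B)
    A <- tryCatch(
      solve_normal_system(crossprod(F), drop(crossprod(F, W)),
                          config$inversion_rtol, config$principal_energy),
      tlpca_numerical_error = function(e)
        stop_numerical("A-step (property coefficients), iteration ", n, ": ",
                       conditionMessage(e)))
    wa <- drop(F %*% A)
    H <- collapse_to_fragment_matrix(x, A)
    B <- tryCatch(
      solve_normal_system(crossprod(H), drop(crossprod(H, W)),
                          config$inversion_rtol, config$principal_energy),
      tlpca_numerical_error = function(e)
        stop_numerical("B-step (fragment coefficients), iteration ", n, ": ",
                       conditionMessage(e)))
    wb <- drop(H %*% B)
    qb <- q_residue(wb, W)
    trace[n, ] <- c(n, pearson_r(wa, W), q_residue(wa, W),
                    pearson_r(wb, W), qb)
    if (abs(q_prev - qb) <= config$epsilon) {
      converged <- TRUE
      break
    }
    q_prev <- qb
  }
  if (!converged)
    warning("alternating fit did not converge within ",
            config$max_iterations, " iterations (|dQ| = ",
            signif(abs(q_prev - qb), 3), " > epsilon = ", config$epsilon,
            ")", call. = FALSE)
  trace <- as.data.frame(trace[seq_len(n), , drop = FALSE])
  fit <- new_tlpca(A, B, property_names(x), fragment_labels(x),
                   config = config, trace = trace, n_iterations = n,
                   converged = converged, fitted.values = wb,
                   residuals = W - wb, activities = W,
                   property_table = x$property_table,
                   call = match.call())
  fit
}

#' Predict activities with a fitted two-level model
#'
#' Evaluates `w_i = sum_l b_l sum_k a_k x_{i,l,k}` for new samples. The
#' model carries no intercept, so an all-zero tensor predicts zero.
#'
#' @param object a fitted `tlpca` model.
#' @param newdata a [fragment_tensor()] whose fragment and property axes
#'   match the model's labels (checked in order), or a character vector /
#'   peptide data frame when the model carries the encoding property
#'   table.
#' @param ... unused.
#' @return Named numeric vector of predicted activities.
#' @export
predict.tlpca <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (is.character(newdata) ||
      (is.data.frame(newdata) && "sequence" %in% names(newdata))) {
    if (is.null(object$property_table))
      stop_validation("model carries no property table; encode sequences ",
                      "with encode_peptides() first")
    newdata <- encode_peptides(newdata, object$property_table)
  }
  if (!inherits(newdata, "fragment_tensor"))
    stop_validation("'newdata' must be a fragment_tensor, sequences, or a ",
                    "peptide data frame")
  if (!identical(fragment_labels(newdata), object$fragment_labels))
    stop_validation("fragment labels differ from the model's: tensor has [",
                    paste(fragment_labels(newdata), collapse = ", "),
                    "], model has [",
                    paste(object$fragment_labels, collapse = ", "), "]")
  if (!identical(property_names(newdata), object$property_names))
    stop_validation("property names differ from the model's: tensor has [",
                    paste(property_names(newdata), collapse = ", "),
                    "], model has [",
                    paste(object$property_names, collapse = ", "), "]")
  H <- collapse_to_fragment_matrix(newdata, object$coefficients$property)
  drop(H %*% object$coefficients$fragment)
}

#' Rescale fitted coefficients to a reporting convention
#'
#' The bilinear model is invariant under `(A, B) -> (c A, B / c)`, so the
#' individual coefficient scales are a convention. This fixes
#' `||B||_2 = sqrt(L)` (an average fragment weight of one) and rescales
#' `A` inversely; predictions are unchanged. Intended for reporting only —
#' the unnormalized coefficients are what the alternating iteration
#' produces.
#'
#' @param object a fitted `tlpca` model.
#' @return The model with rescaled coefficient vectors.
#' @export
rescale_coefficients <- function(object) {
  stopifnot(inherits(object, "tlpca"))
  B <- object$coefficients$fragment
  c0 <- sqrt(length(B)) / sqrt(sum(B^2))
  object$coefficients$fragment <- B * c0
  object$coefficients$property <- object$coefficients$property / c0
  object
}

#' @export
coef.tlpca <- function(object, side = c("both", "property", "fragment"),
                       ...) {
  side <- match.arg(side)
  switch(side,
         both = object$coefficients,
         property = object$coefficients$property,
         fragment = object$coefficients$fragment)
}

#' @export
fitted.tlpca <- function(object, ...) object$fitted.values

#' @export
residuals.tlpca <- function(object, ...) object$residuals

#' @export
print.tlpca <- function(x, digits = 5, ...) {
  cat("Two-level bilinear activity model (", length(x$property_names),
      " properties x ", length(x$fragment_labels), " fragments)\n", sep = "")
  if (!is.na(x$n_iterations))
    cat("Alternating fit: ", x$n_iterations, " iterations, ",
        if (isTRUE(x$converged)) "converged" else "NOT converged", "\n",
        sep = "")
  cat("\nProperty coefficients {a_k}:\n")
  print(round(x$coefficients$property, digits))
  cat("\nFragment coefficients {b_l}:\n")
  print(round(x$coefficients$fragment, digits))
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat("\nTraining R = ", round(last$R_b, 4), ", Q (RMS residue) = ",
        round(last$Q_b, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tlpca <- function(object, ...) {
  tr <- object$trace
  ans <- list(model = object,
              first_R_a = if (!is.null(tr)) tr$R_a[1] else NA_real_,
              final_R = if (!is.null(tr)) tr$R_b[nrow(tr)] else NA_real_,
              final_Q = if (!is.null(tr)) tr$Q_b[nrow(tr)] else NA_real_,
              n_iterations = object$n_iterations,
              converged = object$converged,
              residual_summary = if (!is.null(object$residuals))
                summary(object$residuals))
  class(ans) <- "summary.tlpca"
  ans
}

#' @export
print.summary.tlpca <- function(x, ...) {
  print(x$model)
  if (!is.na(x$first_R_a))
    cat("\nFirst A-step R = ", round(x$first_R_a, 4),
        "; converged R = ", round(x$final_R, 4),
        "; Q = ", round(x$final_Q, 4), "\n", sep = "")
  if (!is.null(x$residual_summary)) {
    cat("\nResiduals:\n")
    print(x$residual_summary)
  }
  invisible(x)
}

#' Plot the convergence trace of an alternating fit
#'
#' Draws the per-iteration Pearson correlation R (A-step and B-step) and,
#' on a second panel, the RMS residue Q.
#'
#' @param x a fitted `tlpca` model with a trace.
#' @param which `"R"`, `"Q"` or `"both"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tlpca <- function(x, which = c("both", "R", "Q"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (is.null(tr) || !nrow(tr))
    stop_validation("model has no iteration trace to plot")
  panels <- if (which == "both") c("R", "Q") else which
  if (length(panels) == 2L) {
    op <- par(mfrow = c(1, 2))
    on.exit(par(op))
  }
  for (p in panels) {
    ya <- tr[[paste0(p, "_a")]]
    yb <- tr[[paste0(p, "_b")]]
    plot(tr$iteration, ya, type = "l", lty = 2, col = "grey40",
         xlab = "iteration", ylab = p, ylim = range(ya, yb), ...)
    lines(tr$iteration, yb, col = "black")
    legend(if (p == "R") "bottomright" else "topright",
           legend = c(paste0(p, "_a (property step)"),
                      paste0(p, "_b (fragment step)")),
           lty = c(2, 1), col = c("grey40", "black"), bty = "n")
  }
  invisible(x)
}

#' Simulate response vectors from a fitted model
#'
#' Draws new activity vectors `w = fitted + N(0, sigma^2)` with `sigma`
#' equal to the training RMS residue, one column per simulation.
#'
#' @param object a fitted `tlpca` model with fitted values.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed (restored afterwards).
#' @param ... unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.tlpca <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted.values))
    stop_validation("model carries no fitted values")
  mu <- object$fitted.values
  sigma <- sqrt(mean(object$residuals^2))
  with_seed(seed, {
    out <- replicate(nsim, mu + rnorm(length(mu), 0, sigma))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}
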