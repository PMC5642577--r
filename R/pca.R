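#' Eigen-decomposition report for a property or fragment square matrix
#'
#' Decomposes the symmetric PSD matrix `M` (typically `F'F` on the
#' property side or `H'H` on the fragment side of a converged fit) into
#' eigenpairs sorted by descending eigenvalue. Eigenvalues are reported
#' both raw and normalized to sum to one; the principal count is the
#' smallest number of leading components whose normalized eigenvalues
#' cumulatively reach `energy_threshold`. Each eigenvector's sign is fixed
#' so its largest-magnitude entry is positive, making reports reproducible
#' across platforms.
#'
#' @param M symmetric positive semi-definite p x p matrix.
#' @param energy_threshold cumulative normalized-eigenvalue fraction for
#'   the principal-component count (default 0.95).
#' @param side optional `"property"` or `"fragment"` tag carried into the
#'   report.
#' @return An object of class `eigen_report`: list with `side`, `labels`,
#'   `values_raw`, `values_normalized`, `vectors` (orthonormal columns),
#'   `principal_count` and `energy_threshold`.
#' @examples
#' eigen_report(diag(c(3, 1)), energy_threshold = 0.7)$principal_count  # 1
#' @export
eigen_report <- function(M, energy_threshold = 0.95, side = NULL) {
  if (!is_symmetric_tol(M))
    stop_validation("'M' is not symmetric within tolerance")
  if (!(energy_threshold > 0 && energy_threshold <= 1))
    stop_validation("'energy_threshold' must lie in (0, 1]")
  e <- eigen(M, symmetric = TRUE)
  mx <- max(abs(e$values), 0)
  if (any(e$values < -1e-8 * max(1, mx)))
    stop_validation("'M' has a significantly negative eigenvalue; ",
                    "expected a positive semi-definite matrix")
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  labels <- rownames(M)
  if (!is.null(labels)) rownames(vecs) <- labels
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  shares <- vals / sum(vals)
  structure(list(side = side, labels = labels,
                 values_raw = vals, values_normalized = shares,
                 vectors = vecs,
                 principal_count =
                   which(cumsum(shares) >= energy_threshold - 1e-12)[1],
                 energy_threshold = energy_threshold),
            class = "eigen_report")
}

#' @export
print.eigen_report <- function(x, ...) {
  cat("Eigen report", if (!is.null(x$side)) paste0(" (", x$side, " side)"),
      ": ", length(x$values_raw), " components, ", x$principal_count,
      " principal at threshold ", x$energy_threshold, "\n", sep = "")
  cat("Normalized eigenvalues:", signif(x$values_normalized, 4), "\n")
  invisible(x)
}

contributions_from_report <- function(report) {
  keep <- seq_len(report$principal_count)
  out <- drop(report$vectors[, keep, drop = FALSE]^2 %*%
                report$values_normalized[keep])
  names(out) <- report$labels
  out
}

#' Per-property contributions to the modeled activity
#'
#' `gamma_j = sum_{k <= K'} beta_k phi_{j,k}^2`: the normalized
#' eigenvalue-weighted squared loadings of property j over the retained
#' principal components of the property square matrix. Their sum equals
#' the retained normalized energy.
#'
#' @param report an [eigen_report()] computed on the property side.
#' @return Named numeric vector of contributions, one per property.
#' @export
property_contributions <- function(report) {
  stopifnot(inherits(report, "eigen_report"))
  if (!is.null(report$side) && report$side != "property")
    stop_validation("report is tagged '", report$side,
                    "', expected the property side")
  contributions_from_report(report)
}

#' Per-fragment contributions to the modeled activity
#'
#' `lambda_j = sum_{l <= L'} alpha_l psi_{j,l}^2` with normalized
#' eigenvalues of the fragment square matrix; the fragment-side analogue
#' of [property_contributions()].
#'
#' @param report an [eigen_report()] computed on the fragment side.
#' @return Named numeric vector of contributions, one per fragment.
#' @export
fragment_contributions <- function(report) {
  stopifnot(inherits(report, "eigen_report"))
  if (!is.null(report$side) && report$side != "fragment")
    stop_validation("report is tagged '", report$side,
                    "', expected the fragment side")
  contributions_from_report(report)
}

#' Project samples onto an eigenbasis
#'
#' Cosine projections of each row of the collapsed matrix (`F` on the
#' property side, `H` on the fragment side) onto each eigenvector:
#' `J[i, k] = (f_i . phi_k) / (||f_i|| ||phi_k||)`. Because the basis is
#' orthonormal, each row of projections has unit Euclidean norm.
#'
#' @param rows N x p numeric matrix of collapsed sample rows.
#' @param report the matching [eigen_report()].
#' @return N x p matrix of cosines in `[-1, 1]`.
#' @export
sample_projections <- function(rows, report) {
  stopifnot(inherits(report, "eigen_report"))
  rows <- as.matrix(rows)
  p <- ncol(report$vectors)
  if (ncol(rows) != p)
    stop_validation("rows have ", ncol(rows), " columns but the eigenbasis ",
                    "has dimension ", p)
  nrm <- sqrt(rowSums(rows^2))
  if (any(nrm == 0)) {
    i <- which(nrm == 0)[1]
    id <- rownames(rows)[i]
    stop_validation("zero-norm sample row ",
                    if (is.null(id)) i else paste0("'", id, "'"),
                    "; its projection is undefined")
  }
  vnrm <- sqrt(colSums(report$vectors^2))  # = 1; kept literal
  J <- (rows %*% report$vectors) / outer(nrm, vnrm)
  colnames(J) <- colnames(report$vectors)
  J
}

#' Per-sample contributions of each property or fragment
#'
#' Combines sample projections with eigenvalue-weighted squared loadings:
#' `xi[i, r] = sum_{k <= K'} beta_k J[i, k] phi_{r,k}^2` on the property
#' side (and the analogous `sigma[i, r]` with `alpha`, `I`, `psi` on the
#' fragment side), giving the contribution of property/fragment r to
#' sample i through the retained principal components.
#'
#' @param projections N x p matrix from [sample_projections()].
#' @param report the matching [eigen_report()].
#' @return N x p matrix of per-sample contributions.
#' @export
sample_contributions <- function(projections, report) {
  stopifnot(inherits(report, "eigen_report"))
  projections <- as.matrix(projections)
  p <- ncol(report$vectors)
  if (ncol(projections) != p)
    stop_validation("projection and eigenbasis dimensions differ")
  keep <- seq_len(report$principal_count)
  wsq <- sweep(report$vectors[, keep, drop = FALSE]^2, 2,
               report$values_normalized[keep], `*`)  # p x K' of beta phi^2
  out <- projections[, keep, drop = FALSE] %*% t(wsq)
  colnames(out) <- report$labels
  out
}

#' Principal-component contribution analysis of a fitted model
#'
#' At the fitted coefficients, collapses the training tensor into the
#' property matrix `F` and fragment matrix `H`, eigen-decomposes `F'F`
#' and `H'H`, and assembles the full decomposition: normalized eigen
#' spectra on both sides, per-property contributions `gamma`,
#' per-fragment contributions `lambda`, per-sample cosine projections and
#' per-sample contributions. All of these are invariant under the
#' `(c A, B / c)` rescaling of the coefficients.
#'
#' @param object a fitted `tlpca` model.
#' @param x the [fragment_tensor()] to analyze (typically the training
#'   tensor).
#' @param energy_threshold cumulative normalized-eigenvalue fraction
#'   selecting the principal components (default 0.95).
#' @return An object of class `tlpca_analysis`: list with `property` and
#'   `fragment` sublists, each holding `report` ([eigen_report()]),
#'   `contributions`, `projections` and `sample_contributions`.
#' @examples
#' bench <- hla_benchmark()
#' x <- encode_peptides(bench$train, bench$property_table)
#' fit <- tlpca(x)
#' an <- contribution_analysis(fit, x)
#' round(an$property$contributions, 4)
#' @export
contribution_analysis <- function(object, x, energy_threshold = 0.95) {
  stopifnot(inherits(object, "tlpca"))
  if (!inherits(x, "fragment_tensor"))
    stop_validation("'x' must be a fragment_tensor")
  if (!identical(fragment_labels(x), object$fragment_labels) ||
      !identical(property_names(x), object$property_names))
    stop_validation("tensor axes do not match the model's labels")
  F <- collapse_to_property_matrix(x, object$coefficients$fragment)
  H <- collapse_to_fragment_matrix(x, object$coefficients$property)
  rep_v <- eigen_report(crossprod(F), energy_threshold, side = "property")
  rep_u <- eigen_report(crossprod(H), energy_threshold, side = "fragment")
  rep_v$labels <- object$property_names
  rep_u$labels <- object$fragment_labels
  J <- sample_projections(F, rep_v)
  I <- sample_projections(H, rep_u)
  structure(list(
    property = list(report = rep_v,
                    contributions = property_contributions(rep_v),
                    projections = J,
                    sample_contributions = sample_contributions(J, rep_v)),
    fragment = list(report = rep_u,
                    contributions = fragment_contributions(rep_u),
                    projections = I,
                    sample_contributions = sample_contributions(I, rep_u)),
    energy_threshold = energy_threshold),
    class = "tlpca_analysis")
}

analysis_table <- function(side) {
  data.frame(index = seq_along(side$report$values_normalized),
             eigenvalue_normalized = side$report$values_normalized,
             label = side$report$labels,
             contribution = unname(side$contributions),
             stringsAsFactors = FALSE)
}

#' @export
print.tlpca_analysis <- function(x, digits = 5, ...) {
  cat("Two-level PCA contribution analysis (energy threshold ",
      x$energy_threshold, ")\n\n", sep = "")
  cat("Property side: ", x$property$report$principal_count,
      " principal component(s), leading share ",
      round(x$property$report$values_normalized[1], 5), "\n", sep = "")
  print(round(sort(x$property$contributions, decreasing = TRUE), digits))
  cat("\nFragment side: ", x$fragment$report$principal_count,
      " principal component(s), leading share ",
      round(x$fragment$report$values_normalized[1], 5), "\n", sep = "")
  print(round(x$fragment$contributions, digits))
  invisible(x)
}

#' Export contribution-analysis tables as delimited text
#'
#' Writes one file per side (`property_eigen.csv`, `fragment_eigen.csv`)
#' with columns `index,eigenvalue_normalized,label,contribution`, plus
#' per-sample contribution tables keyed by sample id.
#'
#' @param analysis a [contribution_analysis()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "tlpca_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("property", "fragment")) {
    write.csv(analysis_table(analysis[[side]]),
              file.path(dir, paste0(side, "_eigen.csv")), row.names = FALSE)
    sc <- analysis[[side]]$sample_contributions
    df <- data.frame(sample_id = rownames(sc), sc, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, file.path(dir, paste0(side, "_sample_contributions.csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
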