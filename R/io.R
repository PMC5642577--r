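MODEL_SCHEMA_VERSION <- "1.0"

#' Write a fitted model to JSON
#'
#' Serializes coefficient vectors, axis labels, configuration, convergence
#' state and the iteration trace. Numbers are written at full double
#' precision so a write/read round trip is bit-stable.
#'
#' @param object a `tlpca` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_tlpca()]
#' @export
write_tlpca <- function(object, path) {
  stopifnot(inherits(object, "tlpca"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    property_names = object$property_names,
    fragment_labels = object$fragment_labels,
    A = unname(object$coefficients$property),
    B = unname(object$coefficients$fragment),
    n_iterations = object$n_iterations,
    converged = object$converged,
    config = object$config[c("epsilon", "max_iterations", "init_b",
                             "inversion_rtol", "principal_energy", "seed")],
    trace = object$trace)
  # digits = I(17): significant-digit mode, enough for bit-exact doubles
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_tlpca()].
#' @return A `tlpca` model (without fitted values or residuals, which
#'   belong to the training tensor).
#' @export
read_tlpca <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("property_names", "fragment_labels", "A", "B")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop_validation("model file missing field(s): ",
                    paste(miss, collapse = ", "))
  cfg <- tlpca_config()
  for (f in names(p$config))
    if (!is.null(p$config[[f]])) cfg[[f]] <- p$config[[f]]
  trace <- if (!is.null(p$trace) && length(p$trace))
    as.data.frame(p$trace) else NULL
  new_tlpca(as.numeric(p$A), as.numeric(p$B),
            property_names = p$property_names,
            fragment_labels = p$fragment_labels,
            config = cfg, trace = trace,
            n_iterations = if (is.null(p$n_iterations)) NA_integer_
                           else as.integer(p$n_iterations),
            converged = if (is.null(p$converged)) NA else p$converged)
}

#' Write an iteration trace as delimited text
#'
#' Columns `iteration,R_a,Q_a,R_b,Q_b`, one row per completed iteration.
#'
#' @param object a fitted `tlpca` model with a trace.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(object, path) {
  stopifnot(inherits(object, "tlpca"))
  if (is.null(object$trace))
    stop_validation("model carries no iteration trace")
  write.csv(object$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
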