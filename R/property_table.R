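#' Amino-acid (building-block) property tables
#'
#' A property table holds K named physicochemical scales for a set of
#' residues (or, more generally, building blocks), one row per residue.
#' It is the lookup used by [encode_peptides()] to turn fixed-length
#' sequences into fragment-by-property descriptor tensors. The bundled
#' default (see [hla_benchmark()]) carries eight scales for the 20 natural
#' amino-acid side chains: lipophilicity and hydrophilicity indices
#' (unitless), lipophilic and hydrophilic surface areas (A^2),
#' alpha-helix, beta-sheet and coil secondary-structure potencies
#' (unitless), and side-chain volume (A^3).
#'
#' @param values numeric matrix, one row per residue, one column per
#'   property; rownames are 1-letter residue codes, colnames are unique
#'   property names.
#' @return An object of class `property_table`: the validated numeric
#'   matrix with residue rownames and property colnames.
#' @examples
#' pt <- property_table(matrix(c(1, 2), 2, 1,
#'   dimnames = list(c("A", "G"), "scale")))
#' pt["G", "scale"]
#' @seealso [read_property_table()], [encode_peptides()]
#' @export
property_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  res <- rownames(values)
  props <- colnames(values)
  if (is.null(res) || is.null(props))
    stop_validation("property table needs residue rownames and property colnames")
  dup <- unique(res[duplicated(res)])
  if (length(dup))
    stop_validation("duplicate residue row(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(props))
    stop_validation("property names must be unique")
  if (ncol(values) < 1L)
    stop_validation("at least one property column is required")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop_validation("non-finite value at residue '", res[bad[1, 1]],
                    "', property '", props[bad[1, 2]], "'")
  structure(values, class = c("property_table", "matrix", "array"))
}

#' Read a property table from delimited text
#'
#' Expects a header `residue,<prop1>,...,<propK>`; one row per residue.
#' Column order is preserved. Duplicate residues and non-numeric cells are
#' reported as errors naming the offending row/column.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @return A [property_table()].
#' @export
read_property_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L)
    stop_validation("expected a residue column plus >= 1 property column")
  res <- df[[1]]
  dup <- unique(res[duplicated(res)])
  if (length(dup))
    stop_validation("duplicate residue row(s): ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(res, names(df)[-1]))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop_validation("non-numeric value '", df[[j + 1L]][i], "' at row ", i,
                      " (residue '", res[i], "'), column '",
                      names(df)[j + 1L], "'")
    }
    vals[, j] <- v
  }
  property_table(vals)
}

#' Write a property table as delimited text
#'
#' Values are written in full decimal precision (17 significant digits) so
#' that a write/read round trip is value-exact.
#'
#' @param x a [property_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(x, path) {
  stopifnot(inherits(x, "property_table"))
  df <- data.frame(residue = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (p in colnames(x)) df[[p]] <- format_full(x[, p])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.property_table <- function(x, ...) {
  cat("Property table: ", nrow(x), " residues x ", ncol(x), " properties (",
      paste(colnames(x), collapse = ", "), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
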