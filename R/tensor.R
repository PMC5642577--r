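#' Fragment-by-property descriptor tensors
#'
#' The data object of the two-level model: an N x L x K array `X` holding
#' physicochemical property k of fragment l in sample i, with an optional
#' activity vector `W` (pIC50 for the bundled benchmark). For peptides the
#' fragments are the residue side chains at each sequence position; for
#' general molecules any fragmentation scheme with per-fragment descriptors
#' can be supplied through [read_fragment_tensor()].
#'
#' @param X numeric 3-D array, samples x fragments x properties, with full
#'   dimnames (sample ids, fragment labels, property names), all finite.
#' @param W optional numeric activity vector of length `dim(X)[1]`.
#' @param property_table optional [property_table()] recording how `X` was
#'   encoded; carried along so fitted models can encode new sequences.
#' @return An object of class `fragment_tensor`: a list with elements `X`
#'   and `W` (possibly `NULL`).
#' @seealso [encode_peptides()], [read_fragment_tensor()]
#' @export
fragment_tensor <- function(X, W = NULL, property_table = NULL) {
  if (!is.array(X) || length(dim(X)) != 3L || !is.numeric(X))
    stop_validation("'X' must be a numeric 3-D array (samples x fragments x properties)")
  dn <- dimnames(X)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop_validation("'X' needs complete dimnames: sample ids, fragment labels, property names")
  for (axis in seq_along(dn)) {
    if (anyDuplicated(dn[[axis]]))
      stop_validation("duplicate labels on the ",
                      c("sample", "fragment", "property")[axis], " axis")
  }
  if (any(dim(X) < 1L)) stop_validation("all tensor dimensions must be >= 1")
  if (!all(is.finite(X)))
    stop_validation("tensor contains non-finite entries")
  if (!is.null(W)) {
    if (!is.numeric(W) || length(W) != dim(X)[1])
      stop_validation("'W' must be numeric with one activity per sample (",
                      dim(X)[1], ")")
    if (!all(is.finite(W))) stop_validation("'W' contains non-finite entries")
    W <- as.numeric(W)
    names(W) <- dn[[1]]
  }
  structure(list(X = X, W = W, property_table = property_table),
            class = "fragment_tensor")
}

#' @export
print.fragment_tensor <- function(x, ...) {
  d <- dim(x$X)
  cat("Fragment tensor: ", d[1], " samples x ", d[2], " fragments x ",
      d[3], " properties; activities ",
      if (is.null(x$W)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
dim.fragment_tensor <- function(x) dim(x$X)

sample_ids      <- function(x) dimnames(x$X)[[1]]
fragment_labels <- function(x) dimnames(x$X)[[2]]
property_names  <- function(x) dimnames(x$X)[[3]]

#' Encode fixed-length peptides into a descriptor tensor
#'
#' Each residue position is one fragment: `X[i, l, k]` is property `k` of
#' the residue at position `l` of sequence `i`. Fragment labels run
#' N-terminus to C-terminus as `"Residue-1" ... "Residue-L"`. When every
#' record carries an activity, it becomes the tensor's `W`; otherwise the
#' tensor is prediction-only.
#'
#' @param records a data frame with columns `id`, `sequence` and optionally
#'   `activity`, or a character vector of sequences (names used as ids).
#' @param table a [property_table()] covering every residue letter used.
#' @param case_fold if `TRUE`, lowercase sequence letters are folded to
#'   upper case before lookup. Off by default: silent folding hides data
#'   errors.
#' @return A [fragment_tensor()] with the encoding `table` attached.
#' @examples
#' pt <- hla_benchmark()$property_table
#' x <- encode_peptides(c(p1 = "VALVGLFVL"), pt)
#' x$X[1, 1, ]  # the Val property row
#' @export
encode_peptides <- function(records, table, case_fold = FALSE) {
  if (!inherits(table, "property_table"))
    stop_validation("'table' must be a property_table")
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(records))
    records <- data.frame(id = ids, sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records)))
    stop_validation("'records' must have columns 'id' and 'sequence'")
  ids <- as.character(records$id)
  seqs <- as.character(records$sequence)
  if (anyDuplicated(ids))
    stop_validation("duplicate peptide id(s): ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (case_fold) seqs <- toupper(seqs)
  n <- length(seqs)
  if (n < 1L) stop_validation("no peptide records supplied")
  lens <- nchar(seqs)
  L <- lens[1]
  if (any(lens != L))
    stop_validation("sequences of mixed length; expected ", L,
                    " for all, offending id(s): ",
                    paste(ids[lens != L], collapse = ", "))
  K <- ncol(table)
  X <- array(NA_real_, c(n, L, K),
             dimnames = list(ids, paste0("Residue-", seq_len(L)),
                             colnames(table)))
  known <- rownames(table)
  for (i in seq_len(n)) {
    aa <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!aa %in% known)
    if (length(bad))
      stop_validation("unknown residue '", aa[bad[1]], "' at position ",
                      bad[1], " of '", ids[i], "'")
    X[i, , ] <- table[aa, , drop = FALSE]
  }
  W <- NULL
  if ("activity" %in% names(records)) {
    act <- suppressWarnings(as.numeric(records$activity))
    if (all(is.finite(act))) W <- act
  }
  fragment_tensor(X, W, property_table = table)
}

#' Read a peptide dataset from delimited text or FASTA
#'
#' Delimited input must have columns `id,sequence[,activity]` (the activity
#' column may be empty for prediction-only data). FASTA input (extension
#' `.fa`/`.fasta`/`.faa`, or `format = "fasta"`) takes ids from the headers
#' and carries no activities; reading FASTA uses the Biostrings package.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"` or `"fasta"`.
#' @param sep field separator for delimited input.
#' @return A data frame with columns `id`, `sequence` and, when present,
#'   `activity`.
#' @export
read_peptides <- function(path, format = c("auto", "csv", "fasta"), sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop_validation("reading FASTA requires the Biostrings package")
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) < 1L) stop_validation("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(ss))
    return(data.frame(id = ids, sequence = as.character(ss),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  df <- read.csv(path, sep = sep, colClasses = "character",
                 strip.white = TRUE, check.names = FALSE)
  if (!all(c("id", "sequence") %in% names(df)))
    stop_validation("peptide file needs columns 'id' and 'sequence'")
  out <- data.frame(id = df$id, sequence = df$sequence,
                    stringsAsFactors = FALSE)
  if ("activity" %in% names(df)) {
    act <- df$activity
    if (any(nzchar(act))) {
      num <- suppressWarnings(as.numeric(act))
      bad <- nzchar(act) & is.na(num)
      if (any(bad))
        stop_validation("non-numeric activity for id(s): ",
                        paste(df$id[bad], collapse = ", "))
      out$activity <- num
    }
  }
  out
}

#' Read a descriptor tensor from long-format delimited text
#'
#' Expects columns `sample_id,fragment,property,value` and optionally a
#' per-sample `activity` column. Every (sample, fragment, property)
#' combination must appear exactly once; axis orders follow first
#' appearance in the file.
#'
#' @param path input file.
#' @param sep field separator.
#' @return A [fragment_tensor()].
#' @export
read_fragment_tensor <- function(path, sep = ",") {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 strip.white = TRUE, check.names = FALSE)
  need <- c("sample_id", "fragment", "property", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("tensor file missing column(s): ",
                    paste(miss, collapse = ", "))
  ids <- unique(df$sample_id)
  frs <- unique(df$fragment)
  prs <- unique(df$property)
  key <- paste(df$sample_id, df$fragment, df$property, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop_validation("duplicate combination (", d$sample_id, ", ", d$fragment,
                    ", ", d$property, ")")
  }
  if (nrow(df) != length(ids) * length(frs) * length(prs)) {
    full <- expand.grid(p = prs, f = frs, s = ids, stringsAsFactors = FALSE)
    fk <- paste(full$s, full$f, full$p, sep = "\r")
    m <- full[!fk %in% key, , drop = FALSE][1, ]
    stop_validation("missing combination (", m$s, ", ", m$f, ", ", m$p, ")")
  }
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    i <- which(is.na(val))[1]
    stop_validation("non-numeric value '", df$value[i], "' at row ", i)
  }
  X <- array(NA_real_, c(length(ids), length(frs), length(prs)),
             dimnames = list(ids, frs, prs))
  X[cbind(match(df$sample_id, ids), match(df$fragment, frs),
          match(df$property, prs))] <- val
  W <- NULL
  if ("activity" %in% names(df) && any(nzchar(df$activity))) {
    act <- suppressWarnings(as.numeric(df$activity))
    bad <- nzchar(df$activity) & is.na(act)
    if (any(bad))
      stop_validation("non-numeric activity at row ", which(bad)[1])
    per <- tapply(act, df$sample_id, function(v) unique(v[is.finite(v)]))
    if (any(lengths(per) > 1L))
      stop_validation("inconsistent activity within sample '",
                      names(per)[lengths(per) > 1L][1], "'")
    w <- vapply(ids, function(s) {
      v <- per[[s]]
      if (length(v)) v else NA_real_
    }, numeric(1))
    if (all(is.finite(w))) W <- w
  }
  fragment_tensor(X, W)
}

#' Write a descriptor tensor as long-format delimited text
#'
#' One row per (sample, fragment, property) cell, values at 17 significant
#' digits so a write/read round trip reproduces the tensor exactly in
#' decimal text. When activities are present an `activity` column is added
#' (repeated across a sample's rows).
#'
#' @param x a [fragment_tensor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_tensor <- function(x, path) {
  stopifnot(inherits(x, "fragment_tensor"))
  d <- dim(x$X)
  grid <- expand.grid(property = property_names(x),
                      fragment = fragment_labels(x),
                      sample_id = sample_ids(x),
                      stringsAsFactors = FALSE)[, 3:1]
  idx <- cbind(match(grid$sample_id, sample_ids(x)),
               match(grid$fragment, fragment_labels(x)),
               match(grid$property, property_names(x)))
  grid$value <- format_full(x$X[idx])
  if (!is.null(x$W)) grid$activity <- format_full(x$W[idx[, 1]])
  write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
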