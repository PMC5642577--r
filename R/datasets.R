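extdata <- function(file) {
  path <- system.file("extdata", file, package = "tlpca")
  if (!nzchar(path)) stop("bundled file not found: ", file)
  path
}

#' The bundled HLA-A*0201 nonamer binding benchmark
#'
#' Returns the packaged benchmark for 9-mer epitope peptides binding the
#' human MHC class I allele HLA-A*0201: an 8-property table over the 20
#' natural amino-acid side chains, 90 training and 40 independent test
#' peptides with experimental pIC50 (plus the reference study's own
#' predicted values and differences, kept verbatim for comparison), the
#' reference converged coefficient sets as a ready-made `tlpca` model, and
#' the reference eigenvalue/contribution table.
#'
#' @return A list with elements `property_table` ([property_table()]),
#'   `train` and `test` (data frames `id, sequence, activity,
#'   reference_prediction, reference_difference`), `reference_model` (a
#'   `tlpca` object holding the published coefficient vectors; no trace),
#'   and `reference_eigen` (data frame of published normalized eigenvalues
#'   and contributions per side).
#' @examples
#' bench <- hla_benchmark()
#' nrow(bench$train)  # 90
#' predict(bench$reference_model, "VALVGLFVL")
#' @export
hla_benchmark <- function() {
  pt <- read_property_table(extdata("aa_properties.csv"))
  read_set <- function(file) {
    df <- read.csv(extdata(file), colClasses = c(sequence = "character"))
    data.frame(id = as.character(df$id), sequence = df$sequence,
               activity = df$expt_pic50,
               reference_prediction = df$pred_pic50,
               reference_difference = df$diff,
               stringsAsFactors = FALSE)
  }
  co <- read.csv(extdata("reference_coefficients.csv"),
                 stringsAsFactors = FALSE)
  prop <- co[co$side == "property", ]
  frag <- co[co$side == "fragment", ]
  ref <- new_tlpca(prop$coefficient, frag$coefficient,
                   property_names = prop$label,
                   fragment_labels = frag$label,
                   converged = TRUE, property_table = pt)
  list(property_table = pt,
       train = read_set("hla_a0201_train.csv"),
       test = read_set("hla_a0201_test.csv"),
       reference_model = ref,
       reference_eigen = read.csv(extdata("reference_eigen.csv"),
                                  stringsAsFactors = FALSE))
}

#' Generate a synthetic descriptor tensor with planted coefficients
#'
#' Draws a tensor whose activities have the exact bilinear two-level
#' structure `w_i = sum_l b*_l sum_k a*_k x_{i,l,k} + N(0, noise_sd^2)`,
#' for property-based testing and coefficient-recovery experiments.
#' Defaults mirror the bundled benchmark's geometry (90 samples, 9
#' fragments, 8 properties) and its heterogeneous descriptor magnitudes:
#' per-property scale multipliers span unit-scale indices up to
#' surface-area/volume scales two orders larger. Descriptor entries are
#' uniform on `[0, scale_k]`; planted coefficients are uniform over the
#' given ranges, which bracket the magnitudes seen in the benchmark fit.
#'
#' @param n_samples,n_fragments,n_properties tensor dimensions.
#' @param coef_range_a range for planted property coefficients `a*`.
#' @param coef_range_b range for planted fragment coefficients `b*`.
#' @param property_scales length-`n_properties` positive multipliers; the
#'   default recycles `c(1, 1, 100, 20, 1, 1, 1, 150)`-style heterogeneity
#'   to `n_properties` values.
#' @param noise_sd standard deviation of additive Gaussian activity noise
#'   (same units as the activity; 0 = noise-free).
#' @param seed integer seed; identical seeds give identical output. The
#'   caller's RNG state is left untouched.
#' @return A list with `tensor` (a [fragment_tensor()] with `W`),
#'   `a_true`, `b_true` and the generating settings (`spec`).
#' @examples
#' sim <- simulate_tensor(n_samples = 40, noise_sd = 0, seed = 1)
#' fit <- tlpca(sim$tensor)
#' pearson_r(fitted(fit), sim$tensor$W)  # 1 up to round-off
#' @export
simulate_tensor <- function(n_samples = 90, n_fragments = 9,
                            n_properties = 8,
                            coef_range_a = c(-0.25, 0.25),
                            coef_range_b = c(-5, 9),
                            property_scales = NULL,
                            noise_sd = 0, seed = NULL) {
  if (min(n_samples, n_fragments, n_properties) < 1L)
    stop_validation("tensor dimensions must all be >= 1")
  if (noise_sd < 0) stop_validation("'noise_sd' must be >= 0")
  if (is.null(property_scales))
    property_scales <- rep_len(c(1, 1, 100, 20, 1, 1, 1, 150), n_properties)
  if (length(property_scales) != n_properties || any(property_scales <= 0))
    stop_validation("'property_scales' must be ", n_properties,
                    " positive values")
  with_seed(seed, {
    a_true <- runif(n_properties, coef_range_a[1], coef_range_a[2])
    b_true <- runif(n_fragments, coef_range_b[1], coef_range_b[2])
    X <- array(runif(n_samples * n_fragments * n_properties),
               c(n_samples, n_fragments, n_properties),
               dimnames = list(paste0("sample_", seq_len(n_samples)),
                               paste0("Residue-", seq_len(n_fragments)),
                               paste0("prop_", seq_len(n_properties))))
    for (k in seq_len(n_properties)) X[, , k] <- X[, , k] * property_scales[k]
    H <- collapse_to_fragment_matrix(X, a_true)
    W <- drop(H %*% b_true) + rnorm(n_samples, 0, noise_sd)
    list(tensor = fragment_tensor(X, W),
         a_true = a_true, b_true = b_true,
         spec = list(n_samples = n_samples, n_fragments = n_fragments,
                     n_properties = n_properties,
                     coef_range_a = coef_range_a,
                     coef_range_b = coef_range_b,
                     property_scales = property_scales,
                     noise_sd = noise_sd, seed = seed))
  })
}

#' Copy the bundled benchmark fixtures to a directory
#'
#' Writes the packaged property-table, training, testing, reference
#' coefficient and reference eigen tables (verbatim delimited text) into
#' `dir`.
#'
#' @param dir destination directory (created if needed).
#' @return Character vector of the copied paths, invisibly.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("aa_properties.csv", "hla_a0201_train.csv",
             "hla_a0201_test.csv", "reference_coefficients.csv",
             "reference_eigen.csv")
  out <- file.path(dir, files)
  for (i in seq_along(files)) file.copy(extdata(files[i]), out[i],
                                        overwrite = TRUE)
  invisible(out)
}
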