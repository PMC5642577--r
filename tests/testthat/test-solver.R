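test_that("tensor collapses match brute-force loop summation", {
  x <- random_tensor(3, 2, 2, seed = 42)
  b <- c(1, -1)
  F <- collapse_to_property_matrix(x, b)
  for (i in 1:3) for (k in 1:2)
    expect_equal(F[i, k], sum(b * x$X[i, , k]))

  a <- c(0.5, 2)
  H <- collapse_to_fragment_matrix(x, a)
  for (i in 1:3) for (l in 1:2)
    expect_equal(H[i, l], sum(a * x$X[i, l, ]))

  # degenerate coefficient choices
  expect_equal(unname(collapse_to_property_matrix(x, c(1, 1))),
               unname(apply(x$X, c(1, 3), sum)))
  expect_true(all(collapse_to_property_matrix(x, c(0, 0)) == 0))
  expect_equal(unname(collapse_to_fragment_matrix(x, c(0, 1))),
               unname(x$X[, , 2]))
  expect_error(collapse_to_property_matrix(x, 1:3), "fragments",
               class = "tlpca_validation_error")
  expect_error(collapse_to_fragment_matrix(x, 1:5), "properties",
               class = "tlpca_validation_error")
})

test_that("fragment activity contribution of Leu matches a hand dot product", {
  bench <- hla_benchmark()
  a <- coef(bench$reference_model, "property")
  leu <- bench$property_table["L", ]
  # independent accumulation, term by term
  acc <- 0
  for (k in seq_along(a)) acc <- acc + a[[k]] * leu[[k]]
  x <- encode_peptides("LLLLLLLLL", bench$property_table)
  H <- collapse_to_fragment_matrix(x, a)
  expect_equal(unname(H[1, 1]), acc, tolerance = 1e-12)
  expect_equal(acc, 0.8214, tolerance = 1e-3)
})

test_that("eigen-based normal solve reproduces a dense direct solve", {
  expect_equal(solve_normal_system(diag(4), c(3, 1, 4, 1)), c(3, 1, 4, 1))
  for (seed in 1:5) {
    M <- random_psd(4, seed)
    rhs <- rnorm(4)
    z <- solve_normal_system(M, rhs)
    z_direct <- solve(M, rhs)  # independent dense oracle
    expect_lt(max(abs(z - z_direct)) / max(abs(z_direct)), 1e-8)
  }
})

test_that("tiny eigenvalues are truncated, singular systems are errors", {
  z <- solve_normal_system(diag(c(1, 1e-30)), c(1, 1))
  expect_equal(z, c(1, 0))
  expect_error(solve_normal_system(matrix(0, 2, 2), c(1, 1)),
               "singular", class = "tlpca_numerical_error")
  expect_error(solve_normal_system(matrix(1:4, 2, 2), c(1, 1)),
               "not symmetric", class = "tlpca_validation_error")
})

test_that("principal-energy truncation keeps only leading components", {
  M <- diag(c(8, 1, 1))
  rhs <- c(8, 1, 1)
  # 8/10 of the energy in the first component: threshold 0.8 keeps it alone
  expect_equal(solve_normal_system(M, rhs, principal_energy = 0.8),
               c(1, 0, 0))
  expect_equal(solve_normal_system(M, rhs, principal_energy = 1),
               c(1, 1, 1))
})

test_that("pearson_r and q_residue implement their formulas", {
  v <- c(1, 3, 2, 5)
  expect_equal(pearson_r(v, v), 1)
  expect_equal(pearson_r(-v, v), -1)
  expect_error(pearson_r(rep(1, 4), v), "constant",
               class = "tlpca_numerical_error")
  expect_error(pearson_r(1:3, 1:4), "length",
               class = "tlpca_validation_error")

  expect_equal(q_residue(v, v), 0)
  expect_equal(q_residue(v, v + 2), 2)
  expect_error(q_residue(1:3, 1:4), "length",
               class = "tlpca_validation_error")

  # printed test-set columns against a from-scratch formula evaluation
  te <- hla_benchmark()$test
  p <- te$reference_prediction; e <- te$activity; n <- length(p)
  r_hand <- (sum(p * e) - n * mean(p) * mean(e)) /
    sqrt((sum(p^2) - n * mean(p)^2) * (sum(e^2) - n * mean(e)^2))
  expect_equal(pearson_r(p, e), r_hand, tolerance = 1e-12)

  # RMS of the printed training differences
  tr <- hla_benchmark()$train
  expect_equal(q_residue(tr$reference_prediction, tr$activity),
               sqrt(mean(tr$reference_difference^2)), tolerance = 1e-3)
})

test_that("noise-free planted bilinear data is fitted exactly", {
  sim <- simulate_tensor(n_samples = 60, n_fragments = 5, n_properties = 4,
                         noise_sd = 0, seed = 7)
  fit <- tlpca(sim$tensor)
  expect_true(fit$converged)
  expect_equal(pearson_r(fitted(fit), sim$tensor$W), 1, tolerance = 1e-6)
  expect_lt(q_residue(fitted(fit), sim$tensor$W), 1e-6)
})

test_that("planted coefficients are recovered up to the bilinear scale", {
  # near the zero-noise limit; at appreciable noise the near-collinear
  # collapsed matrices leave individual coefficients weakly identified
  # even while predictions stay accurate
  clean <- simulate_tensor(n_samples = 200, n_fragments = 9,
                           n_properties = 8, noise_sd = 0, seed = 19)
  sim <- simulate_tensor(n_samples = 200, n_fragments = 9, n_properties = 8,
                         noise_sd = 0.001 * sd(clean$tensor$W), seed = 19)
  fit <- tlpca(sim$tensor)
  outer_fit <- coef(fit, "fragment") %o% coef(fit, "property")
  outer_true <- sim$b_true %o% sim$a_true
  cosine <- sum(outer_fit * outer_true) /
    sqrt(sum(outer_fit^2) * sum(outer_true^2))
  expect_gte(abs(cosine), 0.999)
})

test_that("predictions are invariant under the (cA, B/c) rescaling", {
  run <- benchmark_fit()
  fit <- run$fit
  x <- run$x
  base <- predict(fit, x)
  for (c0 in c(0.02, -3, 117)) {
    scaled <- fit
    scaled$coefficients$property <- fit$coefficients$property * c0
    scaled$coefficients$fragment <- fit$coefficients$fragment / c0
    expect_lt(max(abs(predict(scaled, x) - base)) / max(abs(base)), 1e-10)
  }
  norm <- rescale_coefficients(fit)
  expect_equal(sqrt(sum(coef(norm, "fragment")^2)), 3)  # sqrt(L) = 3
  expect_equal(predict(norm, x), base, tolerance = 1e-12)
})

test_that("training error is non-increasing across full-rank half-steps", {
  sim <- simulate_tensor(n_samples = 80, n_fragments = 6, n_properties = 5,
                         noise_sd = 0.3, seed = 3)
  fit <- tlpca(sim$tensor)
  q_seq <- as.vector(t(fit$trace[, c("Q_a", "Q_b")]))
  expect_true(all(diff(q_seq) <= 1e-10))
  expect_true(all(fit$trace$R_a >= -1 & fit$trace$R_a <= 1))
  expect_true(all(fit$trace$R_b >= -1 & fit$trace$R_b <= 1))
  expect_true(all(fit$trace$Q_a >= 0 & fit$trace$Q_b >= 0))
})

test_that("fitting warns on under-determined sample sizes", {
  sim <- simulate_tensor(n_samples = 5, n_fragments = 6, n_properties = 3,
                         noise_sd = 0, seed = 5)
  expect_warning(tlpca(sim$tensor), "under-determined")
})

test_that("prediction checks axis compatibility and has no intercept", {
  run <- benchmark_fit()
  fit <- run$fit
  zero <- fragment_tensor(
    array(0, c(2, 9, 8),
          dimnames = list(c("z1", "z2"), fit$fragment_labels,
                          fit$property_names)))
  expect_equal(unname(predict(fit, zero)), c(0, 0))

  wrong <- random_tensor(2, 9, 8, seed = 1)
  expect_error(predict(fit, wrong), "fragment labels differ",
               class = "tlpca_validation_error")
  expect_error(predict(fit, array(0, c(1, 2, 3))), "fragment_tensor",
               class = "tlpca_validation_error")
})

test_that("a fitted model survives the JSON round trip bit-stably", {
  run <- benchmark_fit()
  path <- tempfile(fileext = ".json")
  write_tlpca(run$fit, path)
  back <- read_tlpca(path)
  expect_identical(coef(back, "property"), coef(run$fit, "property"))
  expect_identical(coef(back, "fragment"), coef(run$fit, "fragment"))
  expect_identical(back$n_iterations, run$fit$n_iterations)
  expect_equal(back$trace, run$fit$trace)
  expect_equal(predict(back, run$x), predict(run$fit, run$x))
})

test_that("model methods expose fit diagnostics", {
  run <- benchmark_fit()
  fit <- run$fit
  expect_equal(fitted(fit) + residuals(fit), unname(run$x$W),
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.tlpca")
  expect_equal(s$final_R, fit$trace$R_b[nrow(fit$trace)])
  expect_output(print(fit), "Two-level bilinear activity model")
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(90L, 3L))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
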