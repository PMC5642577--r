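# Small builders shared across test files.

tiny_property_table <- function(k = 2) {
  vals <- matrix(seq_len(4 * k), nrow = 4,
                 dimnames = list(c("A", "C", "G", "V"),
                                 paste0("p", seq_len(k))))
  property_table(vals * 1.0)
}

random_tensor <- function(n, l, k, seed, with_w = FALSE) {
  set.seed(seed)
  X <- array(rnorm(n * l * k), c(n, l, k),
             dimnames = list(paste0("s", seq_len(n)),
                             paste0("f", seq_len(l)),
                             paste0("p", seq_len(k))))
  fragment_tensor(X, W = if (with_w) rnorm(n) else NULL)
}

random_psd <- function(p, seed) {
  set.seed(seed)
  G <- matrix(rnorm((p + 3) * p), p + 3, p)
  M <- crossprod(G)
  dimnames(M) <- list(paste0("v", seq_len(p)), paste0("v", seq_len(p)))
  M
}

benchmark_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- hla_benchmark()
      x <- encode_peptides(bench$train, bench$property_table)
      cache <<- list(bench = bench, x = x, fit = tlpca(x))
    }
    cache
  }
})
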