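# Shared fixture builders; all data are generated in code.

make_tab <- function(values, chrom = NULL, pos = NULL, ...) {
  if (is.null(dim(values))) values <- cbind(s1 = values)
  p <- nrow(values)
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p)
  cn_table(chrom, pos, values, ...)
}

# Random test instance for the oracle comparisons: short sequences drawn
# from Gaussian, two-level mixture, or small integer values.
random_instance <- function(p, flavour = c("gauss", "mixture", "integer")) {
  flavour <- match.arg(flavour)
  switch(flavour,
         gauss = rnorm(p),
         mixture = rnorm(p, mean = sample(c(0, 2), p, replace = TRUE)),
         integer = as.numeric(sample(-3:3, p, replace = TRUE)))
}

# Naive O(p^2) double-loop reference for the single-sample dynamic program;
# independent of the vectorized recursion under test.
naive_dp_reference <- function(y, gamma) {
  p <- length(y)
  e <- numeric(p + 1)
  tk <- integer(p)
  for (k in seq_len(p)) {
    best <- Inf
    arg <- NA_integer_
    for (j in seq_len(k)) {
      seg <- y[j:k]
      v <- e[j] - sum(seg)^2 / length(seg) + gamma
      if (v < best) {
        best <- v
        arg <- j
      }
    }
    e[k + 1] <- best
    tk[k] <- arg
  }
  list(e = e, t = tk)
}

# Cost must always agree; start indices are compared only when requested
# (ties are possible for discrete-valued instances, where several
# segmentations attain the optimum).
expect_same_segmentation <- function(fit, oracle, tol = 1e-9,
                                     check_indices = TRUE) {
  expect_equal(fit$cost_prime, oracle$cost_prime, tolerance = tol)
  if (check_indices) {
    expect_identical(as.integer(fit$start_indices),
                     as.integer(oracle$start_indices))
  }
}
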