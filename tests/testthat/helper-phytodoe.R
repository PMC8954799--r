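# shared fixtures and independent oracles

# brute-force normal-equation OLS, independent of fit_rsm's QR path
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# a small non-factorial but full-rank coded design for toy fits
toy_coded <- function(n = 12, n_f = 3, seed = 99) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n_f, -1, 1), n, n_f)
  colnames(m) <- paste0("x", seq_len(n_f))
  m
}

# one-row "design" at arbitrary coded coordinates for the study factors
coded_design <- function(coded, factors = c("Cd", "Pb", "Cr")) {
  coded <- matrix(coded, ncol = length(factors))
  d <- tibble::tibble(run_id = seq_len(nrow(coded)),
                      replicate = 1L)
  for (i in seq_along(factors)) {
    d[[paste0("coded_", factors[i])]] <- coded[, i]
  }
  attr(d, "factors") <- factors
  class(d) <- c("doe_design", class(d))
  d
}

# fit of the study design against noise-free reference surfaces
reference_fit <- function(metal = "Cd", replicates = 3) {
  design <- replicate_design(full_factorial(aviculare_factors()), replicates)
  X <- build_model_matrix(design)
  y <- drop(X %*% aviculare_coefficients()[[metal]])
  fit_rsm(X, y, response_name = metal)
}
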