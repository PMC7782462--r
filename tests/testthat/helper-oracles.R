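# Shared fixtures and independent oracles.  Everything heavy is memoized so
# test files can share one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Closed-form GBLUP with known variances (GLS intercept), the independent
## mixed-model oracle the Gibbs sampler is checked against.
closed_form_gblup <- function(y, G, sigma_g2, sigma_e2) {
  n <- length(y)
  V <- sigma_g2 * G + diag(sigma_e2, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  list(mu = mu, g = as.vector(sigma_g2 * G %*% Vi %*% (y - mu)))
}

## Conditional-mean prediction for unphenotyped lines given phenotyped ones
## (joint multivariate normal), independent of the sampler.
closed_form_prediction <- function(y_obs, G, obs_idx, new_idx,
                                   sigma_g2, sigma_e2) {
  Goo <- G[obs_idx, obs_idx]
  Gno <- G[new_idx, obs_idx, drop = FALSE]
  V <- sigma_g2 * Goo + diag(sigma_e2, length(obs_idx))
  Vi <- solve(V)
  mu <- sum(Vi %*% y_obs) / sum(Vi)
  as.vector(sigma_g2 * Gno %*% Vi %*% (y_obs - mu))
}

## Random binary marker panel + GRM for model-level tests.
toy_panel <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * p, 1, rep(runif(p, 0.15, 0.85), each = n)), n,
              dimnames = list(sprintf("L%03d", seq_len(n)),
                              sprintf("M%04d", seq_len(p))))
  M <- maf_filter(M)
  grm(standardize_markers(M))
}

## Draw a genetic-value vector with covariance sigma_g2 * G.
draw_gblup_truth <- function(G, sigma_g2 = 1) {
  n <- nrow(G)
  ch <- chol(sigma_g2 * G + diag(1e-8, n))
  setNames(as.vector(t(ch) %*% rnorm(n)), rownames(G))
}

## Small multi-year reference program at test scale, shared across files.
test_program <- function(seed = 11, ...) {
  cached(paste0("prog_", seed, "_", paste(c(...), collapse = "_")), {
    cfg <- sim_config("reference", seed = seed,
                      n_populations_per_year = 10L,
                      lines_per_population = list(min = 2L, max = 20L, mean = 8),
                      n_markers = 400L, n_qtl = 80L, ...)
    simulate_program(cfg)
  })
}
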