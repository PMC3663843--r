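# Shared fixtures: small synthetic cohorts and short MCMC configurations.
# Everything is generated in code; no stored data.

quick_cohort <- function(n_cases = 120L, n_controls = 180L, mode = "causal",
                         seed = 1L, ...) {
  simulate_cohort(generator_config(n_cases = n_cases, n_controls = n_controls,
                                   mode = mode, seed = seed, ...))
}

quick_data <- function(sim, genotypes = "dosages", ...) {
  preprocess_cohort(sim$cohort, genotypes = genotypes, ...)
}

# Analysis priors whose precisions match the generator's default truth.
matched_priors <- function(gam1 = 0.025, gam2 = gam1, ...) {
  prior_settings(gam1 = gam1, gam2 = gam2, precx = 2, precxt = 4, precy = 4,
                 ...)
}

quick_config <- function(n_iterations = 800L, burn_in = 300L, thin = 2L,
                         n_chains = 1L, seed = 1L) {
  mcmc_config(n_iterations, burn_in, thin, n_chains = n_chains, seed = seed)
}

# Minimal spiv_data built directly from matrices (bypasses the cohort CSV
# dialect) for focused sampler tests.
toy_data <- function(g, xt, y) {
  structure(list(g = g, xt = xt, y = as.integer(y)), class = "spiv_data")
}

# Random parameter state consistent with a structure, for log-density tests.
random_state <- function(structure, n, p, seed) {
  set.seed(seed)
  act <- sparseiv:::active_coefficients(structure)
  st <- parameter_state(
    u = if ("u" %in% act) rnorm(p, 0, 0.5) else numeric(p),
    w = if ("w" %in% act) rnorm(1, 0, 0.5) else 0,
    wr = if ("wr" %in% act) rnorm(1, 0, 0.5) else 0,
    wg = if ("wg" %in% act) rnorm(p, 0, 0.5) else numeric(p),
    v = if ("v" %in% act) rnorm(1, 0, 0.5) else 0,
    wz = if ("wz" %in% act) rnorm(1, 0, 0.5) else 0,
    b_x = rnorm(1, 0, 0.3), b_0 = rnorm(1, 0, 0.3),
    z = if (structure$include_confounder) rnorm(n) else numeric(n),
    x = rnorm(n), e = rnorm(n, 0, 0.5))
  st
}
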