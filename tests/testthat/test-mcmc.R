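# Sampler correctness: determinism, conjugate oracle, prior sampling,
# summaries and convergence diagnostics.

test_that("identical seeds give bit-identical traces", {
  sim <- quick_cohort(seed = 51)
  dat <- quick_data(sim)
  a <- run_chain(dat, model_structure("M7"), matched_priors(),
                 quick_config(seed = 5))
  b <- run_chain(dat, model_structure("M7"), matched_priors(),
                 quick_config(seed = 5))
  expect_identical(a$samples, b$samples)
  expect_identical(a$deviance, b$deviance)
  c <- run_chain(dat, model_structure("M7"), matched_priors(),
                 quick_config(seed = 6))
  expect_false(identical(a$samples, c$samples))
})

test_that("posterior means match the closed-form conjugate solution", {
  set.seed(52)
  n <- 200; p <- 3
  G <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  u_true <- c(0.8, -0.4, 0.2)
  xobs <- 1 + drop(G %*% u_true) + rnorm(n, 0, 1 / sqrt(4))
  dat <- toy_data(G, xobs, rbinom(n, 1, 0.4))
  # Gaussian-only sub-model: no confounder, Gaussian coefficient priors,
  # fixed precisions, and a measurement layer so tight that the latent
  # biomarker is pinned to its observation.
  st <- model_structure(direction = "none", include_confounder = FALSE,
                        include_pleiotropy = TRUE)
  pr <- prior_settings(precx = 4, precxt = 1e8, precy = 1,
                       coef_prior = "gaussian", gaussian_sd = 2,
                       intercept_sd = 10)
  tr <- run_chain(dat, st, pr, mcmc_config(5000, 1000, 1, n_chains = 1,
                                           seed = 9))
  X <- cbind(1, G)
  P0 <- diag(c(1 / 100, rep(1 / 4, p)))
  mu <- solve(4 * crossprod(X) + P0, 4 * crossprod(X, xobs))
  sm <- posterior_summary(tr)
  pars <- c("b_x", paste0("u.g", 1:p))
  idx <- match(pars, sm$parameter)
  ess <- vapply(pars, function(pp)
    sparseiv:::ess_geyer(tr$samples[, pp]), 0)
  mcse <- sm$sd[idx] / sqrt(ess)
  expect_true(all(abs(sm$mean[idx] - drop(mu)) < 3 * mcse))
})

test_that("with the likelihood disabled the chain samples the Laplace prior", {
  set.seed(53)
  n <- 60; p <- 2
  dat <- toy_data(matrix(rnorm(n * p), n, p,
                         dimnames = list(NULL, c("a", "b"))),
                  rnorm(n), rbinom(n, 1, 0.5))
  gam1 <- 1.5
  pr <- matched_priors(gam1 = gam1)
  tr <- run_chain(dat, model_structure("M7"), pr,
                  mcmc_config(26000, 1000, 5, n_chains = 1, seed = 11),
                  prior_only = TRUE)
  w <- tr$samples[, "w"]
  plaplace <- function(q) ifelse(q < 0, 0.5 * exp(gam1 * q),
                                 1 - 0.5 * exp(-gam1 * q))
  expect_gt(ks.test(w, plaplace)$p.value, 0.01)
})

test_that("posterior summaries reduce to manual statistics on toy traces", {
  mk_trace <- function(sm) {
    structure(list(samples = sm, deviance = rep(1, nrow(sm)),
                   latent_mean = list(), accept_rate = 0.4,
                   structure = model_structure("M4"),
                   priors = matched_priors(), config = quick_config(),
                   chain_id = 1L, seed = 1L),
              class = "spiv_trace")
  }
  sym <- mk_trace(cbind(w = c(-2, 2, -2, 2)))
  expect_equal(posterior_summary(sym)$mean, 0)
  toy <- mk_trace(cbind(a = 1:10 / 10, b = rep(3, 10)))
  s <- posterior_summary(toy)
  expect_equal(s$mean, c(mean(1:10 / 10), 3))
  expect_equal(s$sd[2], 0)
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
  empty <- mk_trace(cbind(w = numeric(0)))
  expect_error(posterior_summary(empty), "empty")
})

test_that("diagnostics behave on constructed chains", {
  base <- list(deviance = rnorm(500, 100), latent_mean = list(),
               accept_rate = 0.4, structure = model_structure("M4"),
               priors = matched_priors(), config = quick_config(),
               chain_id = 1L, seed = 1L)
  mk <- function(v) structure(c(list(samples = cbind(w = v)), base),
                              class = "spiv_trace")
  set.seed(54)
  v <- rnorm(1000)
  # two identical chains: the scale-reduction statistic is exactly one
  d <- diagnose(list(mk(v), mk(v)))
  expect_identical(d$parameters$rhat, 1)
  # iid draws: effective size close to the nominal size
  v2 <- rnorm(4000)
  ess <- sparseiv:::ess_geyer(v2)
  expect_gt(ess, 0.85 * 4000)
  expect_lt(ess, 1.15 * 4000)
  # a strongly trending chain is flagged
  trend <- mk(seq(0, 3, length.out = 1000) + rnorm(1000, 0, 0.1))
  d2 <- diagnose(list(trend, mk(v)))
  expect_gt(d2$parameters$rhat, 1.1)
  expect_true(any(grepl("scale reduction", d2$warnings)))
  # single short chain: a report with warnings, not a failure
  d3 <- diagnose(mk(rnorm(50)))
  expect_s3_class(d3, "spiv_diagnostics")
  expect_true(length(d3$warnings) >= 1)
})

test_that("effective sample size agrees with an established implementation", {
  set.seed(55)
  ar <- as.numeric(arima.sim(list(ar = 0.6), 3000))
  ours <- sparseiv:::ess_geyer(ar)
  ref <- unname(coda::effectiveSize(coda::mcmc(ar)))
  expect_lt(abs(ours - ref) / ref, 0.25)
})

test_that("swapping two individuals leaves pooled summaries unchanged", {
  sim <- quick_cohort(n_cases = 60, n_controls = 90, seed = 56)
  dat <- quick_data(sim)
  swap <- dat
  idx <- c(2L, 1L, 3:length(dat$y))
  swap$g <- dat$g[idx, ]; swap$xt <- dat$xt[idx]; swap$y <- dat$y[idx]
  cfg <- mcmc_config(2500, 800, 2, n_chains = 2, seed = 12)
  f1 <- fit_model(dat, model_structure("M2"), matched_priors(1), cfg)
  f2 <- fit_model(swap, model_structure("M2"), matched_priors(1), cfg)
  s1 <- posterior_summary(f1); s2 <- posterior_summary(f2)
  for (pp in c("w", "b_0", "b_x")) {
    i <- match(pp, s1$parameter)
    mcse <- s1$sd[i] / sqrt(max(sparseiv:::ess_geyer(
      do.call(rbind, lapply(f1$traces, `[[`, "samples"))[, pp]), 10))
    expect_lt(abs(s1$mean[i] - s2$mean[i]), 4 * mcse)
  }
})

test_that("stronger sparsity shrinks the biomarker-outcome coefficient", {
  sim <- quick_cohort(n_cases = 150, n_controls = 200, seed = 57)
  dat <- quick_data(sim)
  mean_abs_w <- sapply(c(0.025, 1, 10), function(g1) {
    mean(sapply(1:2, function(s) {
      tr <- run_chain(dat, model_structure("M7"), matched_priors(g1),
                      mcmc_config(2000, 800, 2, n_chains = 1,
                                  seed = 60 + s))
      mean(abs(tr$samples[, "w"]))
    }))
  })
  expect_true(all(diff(mean_abs_w) < 0))
})

test_that("traces persist to disk with their configuration sidecar", {
  sim <- quick_cohort(seed = 58)
  dat <- quick_data(sim)
  tr <- run_chain(dat, model_structure("M6"), matched_priors(),
                  quick_config(seed = 3))
  base <- file.path(tempfile(), "tr")
  dir.create(dirname(base), recursive = TRUE)
  write_trace(tr, base)
  back <- read.csv(paste0(base, ".csv"))
  expect_equal(nrow(back), nrow(tr$samples))
  expect_equal(back$deviance, tr$deviance, tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, tr$seed)
  expect_equal(meta$structure$label, "M6")
})
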