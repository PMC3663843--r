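# Model family: structure algebra, priors, log joint and deviance.

# Independent naive implementations of the log joint data terms and the
# deviance, written directly from the generative equations (scalar loops,
# no shared code with the package internals).
naive_log_joint_data <- function(st, dat, struct, precx, precxt, precy) {
  n <- length(dat$y)
  total <- 0
  for (i in seq_len(n)) {
    gi <- dat$g[i, ]
    xmean <- st$b_x + sum(st$u * gi) + st$v * st$z[i]
    if (struct$direction == "reverse") xmean <- xmean + st$wr * dat$y[i]
    eta <- st$b_0 + sum(st$wg * gi) + st$wz * st$z[i]
    if (struct$direction == "causal") eta <- eta + st$w * st$x[i]
    li <- eta + st$e[i]
    pr <- 1 / (1 + exp(-li))
    total <- total +
      dnorm(st$x[i], xmean, 1 / sqrt(precx), log = TRUE) +
      dnorm(dat$xt[i], st$x[i], 1 / sqrt(precxt), log = TRUE) +
      dnorm(st$e[i], 0, 1 / sqrt(precy), log = TRUE) +
      log(ifelse(dat$y[i] == 1, pr, 1 - pr))
    if (struct$include_confounder)
      total <- total + dnorm(st$z[i], 0, 1, log = TRUE)
  }
  total
}

naive_deviance <- function(st, dat, struct, precxt) {
  n <- length(dat$y)
  total <- 0
  for (i in seq_len(n)) {
    gi <- dat$g[i, ]
    eta <- st$b_0 + sum(st$wg * gi) + st$wz * st$z[i]
    if (struct$direction == "causal") eta <- eta + st$w * st$x[i]
    li <- eta + st$e[i]
    pr <- 1 / (1 + exp(-li))
    total <- total +
      dnorm(dat$xt[i], st$x[i], 1 / sqrt(precxt), log = TRUE) +
      log(ifelse(dat$y[i] == 1, pr, 1 - pr))
  }
  -2 * total
}

test_that("the eight named structures map to their defining flags", {
  flags <- function(lab) {
    s <- model_structure(lab)
    c(s$direction, s$include_confounder, s$include_pleiotropy)
  }
  expect_equal(flags("M1"), c("causal", "TRUE", "TRUE"))
  expect_equal(flags("M2"), c("causal", "FALSE", "TRUE"))
  expect_equal(flags("M3"), c("reverse", "FALSE", "TRUE"))
  expect_equal(flags("M4"), c("causal", "FALSE", "FALSE"))
  expect_equal(flags("M5"), c("reverse", "FALSE", "FALSE"))
  expect_equal(flags("M6"), c("none", "TRUE", "TRUE"))
  expect_equal(flags("M7"), c("causal", "TRUE", "TRUE"))
  expect_equal(flags("M8"), c("reverse", "TRUE", "TRUE"))
  expect_equal(model_structure(direction = "causal")$label, "M1/M7")
  expect_error(model_structure("M99"), "M1")
  # no pathway at all is rejected
  expect_error(model_structure(direction = "none",
                               include_confounder = FALSE,
                               include_pleiotropy = FALSE), "pathway")
})

test_that("states inconsistent with the structure are rejected", {
  n <- 4; p <- 2
  dat <- toy_data(matrix(rnorm(n * p), n, p), rnorm(n), rbinom(n, 1, 0.5))
  pr <- prior_settings(precx = 1, precxt = 1, precy = 1)
  st <- random_state(model_structure("M6"), n, p, seed = 1)
  st$w <- 0.3  # M6 has no causal link
  expect_error(log_joint(st, dat, model_structure("M6"), pr), "causal")
  st2 <- random_state(model_structure("M4"), n, p, seed = 2)
  st2$wg <- rep(0.2, p)  # no pleiotropy in M4
  expect_error(log_joint(st2, dat, model_structure("M4"), pr), "pleiotropy")
})

test_that("laplace log density is correct and normalized", {
  expect_equal(laplace_log_density(0, 2), 0)
  expect_equal(laplace_log_density(0, 0.025), log(0.0125))
  expect_error(laplace_log_density(1, 0), "gam")
  for (g in c(0.025, 1, 10)) {
    mass <- integrate(function(t) exp(laplace_log_density(t, g)),
                      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # larger gam concentrates mass at zero
  expect_gt(laplace_log_density(0, 10), laplace_log_density(0, 0.025))
  expect_lt(laplace_log_density(2, 10), laplace_log_density(2, 0.025))
})

test_that("log joint data terms match the hand-computable single-subject case", {
  dat <- toy_data(matrix(0, 1, 2), xt = 0, y = 1)
  struct <- model_structure("M2")
  pr <- prior_settings(precx = 1, precxt = 1, precy = 1)
  st <- parameter_state(u = c(0, 0), w = 0, wg = c(0, 0),
                        z = 0, x = 0, e = 0)
  lj <- log_joint(st, dat, struct, pr, include_priors = FALSE)
  expect_equal(lj, 3 * dnorm(0, log = TRUE) + log(0.5), tolerance = 1e-12)
})

test_that("log joint and deviance match a naive reimplementation", {
  set.seed(41)
  n <- 20; p <- 3
  dat <- toy_data(matrix(rnorm(n * p), n, p), rnorm(n), rbinom(n, 1, 0.5))
  pr <- prior_settings(precx = 2, precxt = 4, precy = 4)
  for (lab in c("M7", "M8", "M6", "M4", "M5", "M2")) {
    struct <- model_structure(lab)
    for (k in 1:9) {
      st <- random_state(struct, n, p, seed = 100 * k + match(lab, paste0("M", 1:8)))
      expect_equal(log_joint(st, dat, struct, pr, include_priors = FALSE),
                   naive_log_joint_data(st, dat, struct, 2, 4, 4),
                   tolerance = 1e-10)
      expect_equal(compute_deviance(st, dat, struct, pr),
                   naive_deviance(st, dat, struct, 4),
                   tolerance = 1e-10)
    }
  }
})

test_that("log joint adds coefficient priors on top of the data terms", {
  set.seed(42)
  n <- 10; p <- 2
  dat <- toy_data(matrix(rnorm(n * p), n, p), rnorm(n), rbinom(n, 1, 0.5))
  pr <- prior_settings(gam1 = 0.5, gam2 = 3, precx = 1, precxt = 1, precy = 1)
  struct <- model_structure("M7")
  st <- random_state(struct, n, p, seed = 7)
  expected_prior <- sum(laplace_log_density(st$u, 0.5)) +
    laplace_log_density(st$w, 0.5) +
    sum(laplace_log_density(st$wg, 0.5)) +
    laplace_log_density(st$v, 3) + laplace_log_density(st$wz, 3) +
    dnorm(st$b_x, 0, 10, log = TRUE) + dnorm(st$b_0, 0, 10, log = TRUE)
  expect_equal(log_joint(st, dat, struct, pr) -
                 log_joint(st, dat, struct, pr, include_priors = FALSE),
               expected_prior, tolerance = 1e-10)
})

test_that("log joint decreases as a measurement residual grows", {
  set.seed(43)
  n <- 12; p <- 2
  dat <- toy_data(matrix(rnorm(n * p), n, p), rnorm(n), rbinom(n, 1, 0.5))
  dat$xt[5] <- 0
  # structure without a causal x -> y link, so only the two Gaussian terms
  # of subject 5 move; their mean is anchored at the measurement
  struct <- model_structure("M6")
  pr <- prior_settings(precx = 1, precxt = 1, precy = 1)
  st <- random_state(struct, n, p, seed = 3)
  st$u <- numeric(p); st$v <- 0; st$b_x <- 0
  st$x <- dat$xt
  lls <- sapply(c(0, 0.5, 1.5, 4), function(d) {
    s2 <- st; s2$x[5] <- dat$xt[5] + d
    log_joint(s2, dat, struct, pr, include_priors = FALSE)
  })
  expect_true(all(diff(lls) < 0))
})

test_that("deviance limits behave as the Gaussian and Bernoulli extremes", {
  n <- 30; p <- 2
  set.seed(44)
  dat <- toy_data(matrix(rnorm(n * p), n, p), rnorm(n), rbinom(n, 1, 0.5))
  struct <- model_structure("M2")
  pr <- prior_settings(precx = 1, precxt = 1e6, precy = 1)
  st <- random_state(struct, n, p, seed = 4)
  st$x <- dat$xt
  # perfectly classified outcomes: liability huge with the correct sign
  st$e <- (2 * dat$y - 1) * 50 -
    (st$b_0 + drop(dat$g %*% st$wg) + st$w * st$x)
  dev <- compute_deviance(st, dat, struct, pr)
  gauss_part <- -2 * n * log(sqrt(1e6 / (2 * pi)))
  expect_equal(dev, gauss_part, tolerance = 1e-6)
  expect_lt(gauss_part, 0)  # high-precision fits give negative deviance
})

test_that("precision presets resolve to the published values", {
  s1 <- prior_preset("Setting1")
  expect_equal(c(s1$precxt, s1$precx, s1$precy), c(200, 200, 100))
  expect_equal(s1$gam1, 0.025)
  expect_equal(s1$precz, 1)
  s2 <- prior_preset("Setting2")
  expect_equal(c(s2$precxt, s2$precx, s2$precy), c(1000, 1000, 0.1))
  for (nm in paste0("S", 1:5)) {
    p <- prior_preset(nm)
    expect_equal(p$preset, nm)
  }
  expect_equal(with(prior_preset("S5"), c(precx, precxt, precy)),
               c(20, 20, 200))
  expect_error(prior_preset("S9"), "available")
  # gam2 defaults to gam1
  p <- prior_settings(gam1 = 0.4)
  expect_equal(p$gam2, 0.4)
})

test_that("structures and priors survive a JSON round trip", {
  dir <- tempfile(); dir.create(dir)
  s <- model_structure("M8")
  write_model_json(s, file.path(dir, "s.json"))
  s2 <- read_model_json(file.path(dir, "s.json"), "structure")
  expect_equal(s2$label, "M8")
  p <- prior_settings(gam1 = 0.1, gam2 = 5, precx = 30, precxt = 40,
                      precy = 50)
  write_model_json(p, file.path(dir, "p.json"))
  p2 <- read_model_json(file.path(dir, "p.json"), "priors")
  expect_equal(p2[c("gam1", "gam2", "precx", "precxt", "precy")],
               p[c("gam1", "gam2", "precx", "precxt", "precy")])
})
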