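# Synthetic case-control cohort generator.
#
# Emulates the observational structure the causal-direction analysis assumes:
# a latent standard-normal confounder z, a true biomarker level x built
# linearly from standardized predictors (environmental covariates + genotype
# dosages) and z, a noisy seasonally oscillating measurement xt, and a binary
# outcome y from a logistic liability with Gaussian noise. Case-control
# ascertainment is emulated by oversampling a source population and
# subsampling to fixed case/control counts.

#' Names of the environmental covariates in a cohort table
#'
#' @return Character vector of the 13 covariate column names.
#' @export
covariate_names <- function() {
  c("age", "sex", "bmi", "physact", "famhist", "nsaids", "deprivation",
    "energy", "alcohol", "smoking", "redmeat", "dietvitd", "vitdsupp")
}

#' Default minor-allele frequencies for the 20 emulated loci
#'
#' Sixteen loci emulate common colorectal-cancer GWAS variants and four
#' emulate 25-hydroxyvitamin D variants (columns `snp17`..`snp20`). Values
#' are plausible common-variant MAFs; no linkage disequilibrium is modelled.
#'
#' @return Named numeric vector of length 20.
#' @export
default_snp_mafs <- function() {
  mafs <- c(0.36, 0.20, 0.24, 0.09, 0.37, 0.33, 0.29, 0.35, 0.26, 0.46,
            0.19, 0.29, 0.48, 0.10, 0.36, 0.31, 0.28, 0.24, 0.40, 0.22)
  names(mafs) <- sprintf("snp%02d", seq_along(mafs))
  mafs
}

#' Default distributional specification of the environmental covariates
#'
#' Marginal distributions follow the published description of the SOCCS
#' case-control cohort (age, sex, BMI, physical activity, family history of
#' CRC, NSAID use, Carstairs deprivation index, energy intake, alcohol,
#' smoking, red meat, dietary vitamin D, supplement use). Continuous
#' right-skewed intakes use log-normal marginals matched to the reported
#' median and interquartile range; ordered categories use the reported
#' frequencies with integer codes.
#'
#' @return A named list; each element has fields `family` (one of
#'   `"normal"`, `"bernoulli"`, `"lognormal"`, `"categorical"`) and `params`.
#' @export
default_covariate_spec <- function() {
  lognorm <- function(median, q1, q3) {
    list(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
  }
  list(
    age         = list(family = "normal",      params = list(mean = 62.8, sd = 10.3)),
    sex         = list(family = "bernoulli",   params = list(prob = 0.42)),
    bmi         = list(family = "normal",      params = list(mean = 26.69, sd = 4.50)),
    physact     = list(family = "categorical", params = list(probs = c(0.5561, 0.2554, 0.1168, 0.0677))),
    famhist     = list(family = "categorical", params = list(probs = c(0.9342, 0.0597, 0.0061))),
    nsaids      = list(family = "bernoulli",   params = list(prob = 0.3403)),
    deprivation = list(family = "categorical", params = list(probs = c(0.0964, 0.2189, 0.2760, 0.2329, 0.0968, 0.0556, 0.0234))),
    energy      = list(family = "normal",      params = list(mean = 2575, sd = 982)),
    alcohol     = list(family = "lognormal",   params = lognorm(7.9, 1.8, 18.8)),
    smoking     = list(family = "categorical", params = list(probs = c(0.4367, 0.4015, 0.1618))),
    redmeat     = list(family = "lognormal",   params = lognorm(1.24, 0.80, 1.72)),
    dietvitd    = list(family = "lognormal",   params = lognorm(4.27, 3.16, 5.79)),
    vitdsupp    = list(family = "categorical", params = list(probs = c(0.8117, 0.1312, 0.0571)))
  )
}

predictor_names <- function(spec = default_covariate_spec(),
                            mafs = default_snp_mafs()) {
  c(names(spec), names(mafs))
}

# Sparse default effects of the standardized predictors on the biomarker:
# the four 25-OHD loci plus lifestyle determinants of vitamin D status.
default_true_u <- function() {
  u <- stats::setNames(numeric(33), predictor_names())
  u[c("snp17", "snp18", "snp19", "snp20")] <- 0.25
  u["dietvitd"] <- 0.25
  u["vitdsupp"] <- 0.25
  u["physact"]  <- 0.15
  u["bmi"]      <- -0.15
  u["age"]      <- -0.10
  u
}

# Sparse default direct (pleiotropic) effects on the outcome liability.
default_true_wg <- function() {
  wg <- stats::setNames(numeric(33), predictor_names())
  wg[sprintf("snp%02d", 1:8)] <- 0.12
  wg["famhist"] <- 0.60
  wg["nsaids"]  <- -0.25
  wg["smoking"] <- 0.10
  wg
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the generative structure (causal, reverse-causal, confounder-only
#' or null), the true coefficient values, noise precisions and seasonal
#' oscillation under which a case-control cohort is simulated. The default
#' counts (1057 cases, 1588 controls) match the cohort size the analysis is
#' designed for. `mode = "null"` forces `true_w`, `true_wr`, `true_v` and
#' `true_wz` to zero; `mode = "confounder_only"` forces `true_w` and
#' `true_wr` to zero.
#'
#' @param n_cases,n_controls Positive integers; target ascertained counts.
#' @param mode One of `"causal"`, `"reverse"`, `"confounder_only"`, `"null"`.
#' @param snp_mafs Numeric vector of minor-allele frequencies in (0, 1).
#' @param covariate_spec Covariate specification, see
#'   [default_covariate_spec()].
#' @param true_u Named numeric vector: effects of the standardized predictors
#'   on the true biomarker level.
#' @param true_w Biomarker-to-outcome liability effect (causal mode only).
#' @param true_wr Outcome-to-biomarker shift (reverse mode only; y coded 0/1).
#' @param true_wg Named numeric vector: direct predictor-to-outcome effects.
#' @param true_v,true_wz Confounder effects on biomarker and liability.
#' @param true_precx,true_precxt,true_precy Positive precisions (inverse
#'   variances) of the biomarker residual, the measurement noise and the
#'   liability noise.
#' @param seasonal_amplitude Non-negative cosine amplitude added to the
#'   measured biomarker.
#' @param seasonal_phase_month Integer 1-12; month at which the seasonal term
#'   peaks.
#' @param intercept_x,intercept_y Intercepts of the biomarker and liability
#'   equations. The default `intercept_y` puts the source-population case
#'   fraction near the ascertained study fraction (about 40 percent), so the
#'   default cohort's joint distribution matches the generative model; lower
#'   the intercept to emulate strong case-control selection.
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the configuration.
#' @param max_oversample Bound on the source-population size, as a multiple
#'   of `n_cases + n_controls`.
#' @return An object of class `spiv_generator_config`.
#' @export
generator_config <- function(n_cases = 1057L, n_controls = 1588L,
                             mode = c("causal", "reverse", "confounder_only", "null"),
                             snp_mafs = default_snp_mafs(),
                             covariate_spec = default_covariate_spec(),
                             true_u = default_true_u(),
                             true_w = -0.5, true_wr = -0.5,
                             true_wg = default_true_wg(),
                             true_v = 0.5, true_wz = 0.5,
                             true_precx = 2, true_precxt = 4, true_precy = 4,
                             seasonal_amplitude = 1.5,
                             seasonal_phase_month = 7L,
                             intercept_x = 0, intercept_y = -0.45,
                             seed = 1L, max_oversample = 50) {
  mode <- match.arg(mode)
  if (n_cases < 1 || n_controls < 1)
    stop_invalid("n_cases and n_controls must be positive (got %s, %s)",
                 n_cases, n_controls)
  if (any(snp_mafs <= 0 | snp_mafs >= 1))
    stop_invalid("snp_mafs must lie strictly in (0, 1)")
  if (any(c(true_precx, true_precxt, true_precy) <= 0))
    stop_invalid("precisions must be strictly positive")
  if (seasonal_amplitude < 0)
    stop_invalid("seasonal_amplitude must be >= 0")
  if (!seasonal_phase_month %in% 1:12)
    stop_invalid("seasonal_phase_month must be an integer in 1..12")
  p <- length(covariate_spec) + length(snp_mafs)
  if (length(true_u) != p || length(true_wg) != p)
    stop_invalid("true_u and true_wg must have one entry per predictor (%d)", p)

  if (mode == "null") true_w <- true_wr <- true_v <- true_wz <- 0
  if (mode == "confounder_only") true_w <- true_wr <- 0
  if (mode != "causal") true_w <- 0
  if (mode != "reverse") true_wr <- 0

  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    mode = mode, snp_mafs = snp_mafs, covariate_spec = covariate_spec,
    true_u = true_u, true_w = true_w, true_wr = true_wr, true_wg = true_wg,
    true_v = true_v, true_wz = true_wz,
    true_precx = true_precx, true_precxt = true_precxt, true_precy = true_precy,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_phase_month = as.integer(seasonal_phase_month),
    intercept_x = intercept_x, intercept_y = intercept_y,
    seed = as.integer(seed), max_oversample = max_oversample
  ), class = "spiv_generator_config")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Entry (i, j) is drawn as Binomial(2, `mafs[j]`); loci are independent.
#'
#' @param n Number of individuals.
#' @param mafs Vector of allele frequencies in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return Integer matrix of dosages in \{0, 1, 2\}, `n` rows, one column
#'   per locus (named after `mafs` when it has names).
#' @export
simulate_genotypes <- function(n, mafs, seed = 1L) {
  if (n < 1) stop_invalid("n must be >= 1")
  if (any(mafs < 0 | mafs > 1)) stop_invalid("mafs must lie in [0, 1]")
  with_seed(seed, draw_genotypes(n, mafs))
}

draw_genotypes <- function(n, mafs) {
  g <- vapply(mafs, function(m) stats::rbinom(n, 2L, m), integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(mafs)))
  g
}

#' Add a cosine seasonal oscillation
#'
#' Adds `amplitude * cos(2 * pi * (month - phase_month) / 12)` to each value,
#' so the term peaks in `phase_month` and averages to zero over a full year.
#'
#' @param x_values Numeric vector.
#' @param months Integer vector in 1..12, same length as `x_values`.
#' @param amplitude Non-negative amplitude.
#' @param phase_month Integer 1-12.
#' @return Numeric vector of the same length.
#' @export
inject_seasonality <- function(x_values, months, amplitude, phase_month) {
  if (any(!months %in% 1:12)) stop_invalid("months must be integers in 1..12")
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (!phase_month %in% 1:12) stop_invalid("phase_month must be in 1..12")
  x_values + amplitude * cos(2 * pi * (months - phase_month) / 12)
}

# Draw raw covariates for m individuals following the covariate specification.
draw_covariates <- function(m, spec) {
  out <- lapply(spec, function(cv) {
    p <- cv$params
    switch(cv$family,
      normal      = stats::rnorm(m, p$mean, p$sd),
      bernoulli   = stats::rbinom(m, 1L, p$prob),
      lognormal   = stats::rlnorm(m, p$meanlog, p$sdlog),
      categorical = {
        pr <- p$probs / sum(p$probs)
        sample.int(length(pr), m, replace = TRUE, prob = pr)
      },
      stop_invalid("unknown covariate family '%s'", cv$family)
    )
  })
  as.data.frame(out)
}

# Theoretical mean/sd of each covariate family, used to standardize the
# predictors entering the generative linear predictors (batch-independent).
covariate_moments <- function(spec) {
  mom <- vapply(spec, function(cv) {
    p <- cv$params
    switch(cv$family,
      normal      = c(p$mean, p$sd),
      bernoulli   = c(p$prob, sqrt(p$prob * (1 - p$prob))),
      lognormal   = {
        m <- exp(p$meanlog + p$sdlog^2 / 2)
        s <- m * sqrt(exp(p$sdlog^2) - 1)
        c(m, s)
      },
      categorical = {
        pr <- p$probs / sum(p$probs)
        k <- seq_along(pr)
        mu <- sum(pr * k)
        c(mu, sqrt(sum(pr * (k - mu)^2)))
      }
    )
  }, numeric(2))
  list(mean = mom[1, ], sd = mom[2, ])
}

standardize_predictors <- function(covariates, genotypes, spec, mafs) {
  cm <- covariate_moments(spec)
  gs_cov <- sweep(sweep(as.matrix(covariates), 2, cm$mean), 2, cm$sd, "/")
  gmean <- 2 * mafs
  gsd <- sqrt(2 * mafs * (1 - mafs))
  gs_snp <- sweep(sweep(genotypes, 2, gmean), 2, gsd, "/")
  cbind(gs_cov, gs_snp)
}

#' Simulate a case-control cohort with known ground truth
#'
#' Generates a source population under the configured graphical structure --
#' latent confounder `z ~ N(0, 1)`, true biomarker
#' `x = b_x + u'g + v z (+ wr y in reverse mode) + N(0, 1/precx)`, seasonal
#' noisy measurement `xt_raw = x + seasonal + N(0, 1/precxt)`, liability
#' noise `e ~ N(0, 1/precy)` and outcome
#' `y ~ Bernoulli(sigmoid(b_0 + w x + wg'g + wz z + e))` -- then subsamples
#' without replacement to exactly `n_cases` cases and `n_controls` controls.
#' In reverse mode the outcome is generated first (without the `w x` term)
#' and the biomarker receives the `wr * y` shift.
#'
#' @param config A [generator_config()].
#' @param keep_latents If `TRUE`, also return the generating per-subject
#'   latents (confounder `z`, true biomarker `x`, liability noise `e`) of
#'   the ascertained rows, for validation studies.
#' @return A list with elements `cohort` (a `spiv_cohort` data frame:
#'   `id`, `y`, `xt_raw`, `month`, 13 covariates, `snp01`..`snp20`) and
#'   `truth` (a `spiv_truth` holding every generating coefficient plus the
#'   configuration, sufficient to regenerate the cohort bit-exactly);
#'   plus `latents` when requested.
#' @export
simulate_cohort <- function(config, keep_latents = FALSE) {
  stopifnot(inherits(config, "spiv_generator_config"))
  cfg <- config
  target <- cfg$n_cases + cfg$n_controls
  with_seed(cfg$seed, {
    pieces <- list()
    n_done <- 0L
    batch <- 4L * target
    repeat {
      pieces[[length(pieces) + 1L]] <- draw_population_batch(batch, cfg)
      n_done <- n_done + batch
      ycum <- unlist(lapply(pieces, function(p) p$y))
      if (sum(ycum == 1L) >= cfg$n_cases && sum(ycum == 0L) >= cfg$n_controls)
        break
      if (n_done >= cfg$max_oversample * target)
        stop_invalid(paste0(
          "could not ascertain %d cases / %d controls within an oversampling ",
          "factor of %g (achieved case fraction %.4f over %d individuals)"),
          cfg$n_cases, cfg$n_controls, cfg$max_oversample,
          mean(ycum == 1L), n_done)
      batch <- n_done  # double the population each round
    }
    pop <- do.call(rbind, lapply(pieces, function(p) p$table))
    lat <- do.call(rbind, lapply(pieces, function(p) p$latents))
    keep <- sort(c(sample(which(pop$y == 1L), cfg$n_cases),
                   sample(which(pop$y == 0L), cfg$n_controls)))
    cohort <- pop[keep, , drop = FALSE]
    lat <- lat[keep, , drop = FALSE]
    cohort$id <- seq_len(nrow(cohort))
    rownames(cohort) <- rownames(lat) <- NULL
    cohort <- cohort[, c("id", setdiff(names(cohort), "id"))]
    class(cohort) <- c("spiv_cohort", "data.frame")
    truth <- structure(list(
      mode = cfg$mode, seed = cfg$seed,
      coefficients = list(
        u = cfg$true_u, w = cfg$true_w, wr = cfg$true_wr, wg = cfg$true_wg,
        v = cfg$true_v, wz = cfg$true_wz,
        b_x = cfg$intercept_x, b_0 = cfg$intercept_y),
      precisions = c(precx = cfg$true_precx, precxt = cfg$true_precxt,
                     precy = cfg$true_precy),
      seasonal = c(amplitude = cfg$seasonal_amplitude,
                   phase_month = cfg$seasonal_phase_month),
      config = cfg
    ), class = "spiv_truth")
    out <- list(cohort = cohort, truth = truth)
    if (keep_latents) out$latents <- lat
    out
  })
}

# One batch of the (pre-ascertainment) source population.
draw_population_batch <- function(m, cfg) {
  covs <- draw_covariates(m, cfg$covariate_spec)
  geno <- draw_genotypes(m, cfg$snp_mafs)
  gs <- standardize_predictors(covs, geno, cfg$covariate_spec, cfg$snp_mafs)
  z <- stats::rnorm(m)
  e <- stats::rnorm(m, 0, 1 / sqrt(cfg$true_precy))
  gu <- drop(gs %*% cfg$true_u)
  gwg <- drop(gs %*% cfg$true_wg)
  if (cfg$mode == "reverse") {
    eta <- cfg$intercept_y + gwg + cfg$true_wz * z + e
    y <- stats::rbinom(m, 1L, sigmoid(eta))
    x <- cfg$intercept_x + gu + cfg$true_v * z + cfg$true_wr * y +
      stats::rnorm(m, 0, 1 / sqrt(cfg$true_precx))
  } else {
    x <- cfg$intercept_x + gu + cfg$true_v * z +
      stats::rnorm(m, 0, 1 / sqrt(cfg$true_precx))
    eta <- cfg$intercept_y + cfg$true_w * x + gwg + cfg$true_wz * z + e
    y <- stats::rbinom(m, 1L, sigmoid(eta))
  }
  month <- sample.int(12L, m, replace = TRUE)
  xt_raw <- inject_seasonality(x, month, cfg$seasonal_amplitude,
                               cfg$seasonal_phase_month) +
    stats::rnorm(m, 0, 1 / sqrt(cfg$true_precxt))
  tab <- cbind(data.frame(y = y, xt_raw = xt_raw, month = month),
               covs, as.data.frame(geno))
  list(table = tab, y = y, latents = data.frame(z = z, x = x, e = e))
}

#' @export
print.spiv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic case-control cohort: %d individuals (%d cases, %d controls)\n",
              nrow(x), sum(x$y == 1), sum(x$y == 0)))
  cat(sprintf("Columns: %s ...\n", paste(utils::head(names(x), 8), collapse = ", ")))
  invisible(x)
}

#' @export
print.spiv_truth <- function(x, ...) {
  cat(sprintf("Ground truth (mode = %s, seed = %d)\n", x$mode, x$seed))
  co <- x$coefficients
  cat(sprintf("  w = %g, wr = %g, v = %g, wz = %g\n", co$w, co$wr, co$v, co$wz))
  cat(sprintf("  nonzero u: %d, nonzero wg: %d\n",
              sum(co$u != 0), sum(co$wg != 0)))
  invisible(x)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `spiv_cohort`.
#' @param path Output file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write the generating ground truth to JSON
#'
#' The file holds every generating coefficient and the full configuration,
#' so the cohort can be regenerated bit-exactly.
#'
#' @param truth A `spiv_truth`.
#' @param path Output file path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- unclass(truth)
  out$config <- unclass(out$config)
  # named atomic vectors serialize as JSON objects only as lists
  for (f in c("snp_mafs", "true_u", "true_wg"))
    out$config[[f]] <- as.list(out$config[[f]])
  out$coefficients$u <- as.list(out$coefficients$u)
  out$coefficients$wg <- as.list(out$coefficients$wg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
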