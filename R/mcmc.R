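# Blocked Gibbs / Metropolis sampler for the sparse instrumental-variable
# model family.
#
# All linear-Gaussian blocks (x-equation coefficients, liability-equation
# coefficients, latent true biomarker x, latent confounder z) have Gaussian
# full conditionals and are updated by exact conjugate draws; the Laplace
# priors are handled through their exponential scale-mixture representation
# (Park & Casella style), which keeps the coefficient blocks conjugate. The
# logistic outcome layer is linked through a per-subject liability
# l_i = eta_i + e_i with Gaussian noise of precision precy; the liabilities
# have log-concave univariate conditionals (Bernoulli x Gaussian) and are
# updated by a vectorized random-walk Metropolis step whose global proposal
# scale is adapted during burn-in only. Noise precisions get conjugate Gamma
# updates when requested. The latent-confounder reflection
# (v, wz, z) -> (-v, -wz, -z) leaves the posterior invariant; a
# deterministic involution move enforces v >= 0 so that traces are
# sign-aligned.

#' MCMC run configuration
#'
#' @param n_iterations Total iterations per chain (default 20000).
#' @param burn_in Iterations discarded (default 10000; must be smaller than
#'   `n_iterations`).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param n_chains Number of independent chains (default 2).
#' @param seed Integer seed; chain `i` uses `seed + 7919 * (i - 1)`.
#' @param proposal_scale Initial random-walk scale for the liability layer;
#'   defaults to `2.4 / sqrt(precy + 0.25)`.
#' @param adapt Adapt the proposal scale during burn-in only (default TRUE),
#'   preserving detailed balance of the retained samples.
#' @return Object of class `spiv_mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 20000L, burn_in = 10000L, thin = 5L,
                        n_chains = 2L, seed = 1L, proposal_scale = NULL,
                        adapt = TRUE) {
  if (burn_in >= n_iterations) stop_invalid("burn_in must be < n_iterations")
  if (thin < 1L) stop_invalid("thin must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 proposal_scale = proposal_scale, adapt = isTRUE(adapt)),
            class = "spiv_mcmc_config")
}

#' Run one MCMC chain
#'
#' Fits a model structure to preprocessed data and returns a reproducible
#' trace: retained coefficient samples, the per-sample deviance series,
#' running posterior means of the per-subject latents (x, z and the
#' liability), and the liability-layer acceptance rate. Identical seed and
#' configuration give a bit-identical trace.
#'
#' @param data A `spiv_data` (fields `g`, `xt`, `y`).
#' @param structure A `spiv_structure`.
#' @param priors A `spiv_priors`.
#' @param config A `spiv_mcmc_config`.
#' @param chain_id Chain index (offsets the seed).
#' @param prior_only If `TRUE`, data terms are dropped and the chain samples
#'   from the prior (useful for validating the prior implementation).
#' @return Object of class `spiv_trace`.
#' @export
run_chain <- function(data, structure, priors, config = mcmc_config(),
                      chain_id = 1L, prior_only = FALSE) {
  structure <- validate_structure(structure)
  seed <- config$seed + 7919L * (as.integer(chain_id) - 1L)
  with_seed(seed, run_chain_impl(data, structure, priors, config,
                                 chain_id, seed, prior_only))
}

run_chain_impl <- function(data, struct, priors, config, chain_id, seed,
                           prior_only) {
  g <- data$g; xt <- data$xt; y <- as.numeric(data$y)
  n <- length(y); p <- ncol(g)
  conf <- struct$include_confounder
  causal <- struct$direction == "causal"
  reverse <- struct$direction == "reverse"
  act <- active_coefficients(struct)
  gauss <- priors$coef_prior == "gaussian"

  # --- design layout -------------------------------------------------------
  # x-equation: response x; fixed columns [1 | g (u) | y (wr)]; dynamic: z (v)
  Fx <- cbind(b_x = rep(1, n))
  ax_names <- "b_x"; ax_gam <- NA_real_
  if ("u" %in% act) {
    Fx <- cbind(Fx, g)
    ax_names <- c(ax_names, paste0("u.", colnames(g)))
    ax_gam <- c(ax_gam, rep(priors$gam1, p))
  }
  if (reverse) {
    Fx <- cbind(Fx, wr = y)
    ax_names <- c(ax_names, "wr"); ax_gam <- c(ax_gam, priors$gam1)
  }
  if (conf) { ax_names <- c(ax_names, "v"); ax_gam <- c(ax_gam, priors$gam2) }
  kx <- length(ax_names)

  # liability equation: response l; fixed [1 | g (wg)]; dynamic: x (w), z (wz)
  Fy <- cbind(b_0 = rep(1, n))
  ay_names <- "b_0"; ay_gam <- NA_real_
  if ("wg" %in% act) {
    Fy <- cbind(Fy, g)
    ay_names <- c(ay_names, paste0("wg.", colnames(g)))
    ay_gam <- c(ay_gam, rep(priors$gam1, p))
  }
  if (causal) { ay_names <- c(ay_names, "w"); ay_gam <- c(ay_gam, priors$gam1) }
  if (conf) { ay_names <- c(ay_names, "wz"); ay_gam <- c(ay_gam, priors$gam2) }
  ky <- length(ay_names)

  # --- initial state -------------------------------------------------------
  precx <- priors$precx; precxt <- priors$precxt; precy <- priors$precy
  precz <- priors$precz
  init_coef <- function(k, gam) {
    th <- numeric(k)
    for (j in seq_len(k)) {
      if (is.na(gam[j])) th[j] <- stats::rnorm(1)           # intercept
      else if (gauss) th[j] <- stats::rnorm(1, 0, priors$gaussian_sd)
      else {                                                 # Laplace draw,
        sc <- min(1 / gam[j], 1)                             # unit-capped scale
        th[j] <- sample(c(-1, 1), 1) * stats::rexp(1, 1 / sc)
      }
    }
    th
  }
  alpha <- init_coef(kx, ax_gam)
  beta <- init_coef(ky, ay_gam)
  z <- if (conf) stats::rnorm(n) else numeric(n)
  x <- xt
  l <- (2 * y - 1) * abs(stats::rnorm(n, 1, 0.5))
  tau2x <- rep(1, kx); tau2y <- rep(1, ky)  # scale-mixture variances
  prior_prec_x <- function() {
    pp <- ifelse(is.na(ax_gam), 1 / priors$intercept_sd^2,
                 if (gauss) 1 / priors$gaussian_sd^2 else 1 / tau2x)
    pp
  }
  prior_prec_y <- function() {
    ifelse(is.na(ay_gam), 1 / priors$intercept_sd^2,
           if (gauss) 1 / priors$gaussian_sd^2 else 1 / tau2y)
  }

  s_prop <- config$proposal_scale %||% (2.4 / sqrt(precy + 0.25))
  log_s <- log(s_prop)
  # Collapsed-block adaptive Metropolis state: proposals use the running
  # empirical covariance of (v, dir, wz) scaled by 2.38^2/d (Haario-style),
  # with a global log-scale tuned to ~0.3 acceptance. Adaptation stops at
  # the end of burn-in.
  log_sc <- log(1); log_sc2 <- log(1)
  d_blk <- 2L + as.integer(causal || reverse)
  blk_mean <- numeric(3); blk_m2 <- matrix(0, 3, 3); blk_n <- 0L
  blk_chol <- diag(c(0.1, 0.3, 0.3))
  n_collapsed <- 4L

  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  if (n_keep < 1L)
    stop_invalid("no retained draws: increase n_iterations or reduce thin")
  samples <- matrix(NA_real_, n_keep, kx + ky + 3L,
                    dimnames = list(NULL, c(ax_names, ay_names,
                                            "precx", "precxt", "precy")))
  dev <- numeric(n_keep)
  sum_x <- sum_z <- sum_l <- numeric(n)
  kept <- 0L
  acc_post <- 0; acc_post_n <- 0L

  iv <- function(nm, names) match(nm, names)  # column index helper
  i_v <- if (conf) iv("v", ax_names) else NA_integer_
  i_wz <- if (conf) iv("wz", ay_names) else NA_integer_
  i_w <- if (causal) iv("w", ay_names) else NA_integer_
  i_wr <- if (reverse) iv("wr", ax_names) else NA_integer_
  nfx <- kx - as.integer(conf)   # fixed columns of the x design
  nfy <- ky - as.integer(causal) - as.integer(conf)

  gshape <- priors$gamma_shape
  grate <- if (priors$precision_mode == "gamma") gamma_rates(priors)

  # Conjugate Gaussian draw for [F | D] beta = resp, assembling the normal
  # equations from the precomputed fixed-block cross-product plus thin
  # strips for the dynamic (latent) columns.
  FtFx <- crossprod(Fx); FtFy <- crossprod(Fy)
  draw_block <- function(FtF, F, D, resp, prec_noise, p0) {
    if (is.null(D)) {
      XtX <- FtF
      Xty <- crossprod(F, resp)
    } else {
      FtD <- crossprod(F, D)
      XtX <- rbind(cbind(FtF, FtD), cbind(t(FtD), crossprod(D)))
      Xty <- rbind(crossprod(F, resp), crossprod(D, resp))
    }
    Q <- prec_noise * XtX + diag(p0, nrow(XtX))
    ch <- chol(Q)
    mu <- backsolve(ch, forwardsolve(t(ch), prec_noise * Xty))
    drop(mu + backsolve(ch, stats::rnorm(nrow(XtX))))
  }

  # Collapsed log posterior of the confounder block theta = (v, dir, wz),
  # with the latent confounder integrated out analytically. dir is the
  # direct-link coefficient (w in causal, wr in reverse, absent otherwise).
  # The direct effect w (or wr) and the confounder path v*wz explain the
  # same biomarker-outcome covariance, so their joint conditional is a long
  # ridge along which single-site Gibbs mixes poorly; a random-walk move on
  # this marginal, followed by an exact conditional redraw of z, traverses
  # the ridge. Priors enter through the current scale-mixture variances, so
  # the move leaves the augmented posterior invariant.
  sigz2 <- 1 / priors$precz
  collapsed_logpost <- function(v_, dir_, wz_, fxw, lbase, x_, l_,
                                precx_, precy_, t2_v, t2_dir, t2_wz) {
    mx <- fxw + (if (reverse) dir_ * y else 0)
    sx2 <- v_^2 * sigz2 + 1 / precx_
    mu_zx <- sigz2 * v_ * (x_ - mx) / sx2
    v_zx <- sigz2 * (1 - sigz2 * v_^2 / sx2)
    lmean <- lbase + (if (causal) dir_ * x_ else 0) + wz_ * mu_zx
    sl2 <- wz_^2 * v_zx + 1 / precy_
    lp <- sum(stats::dnorm(x_, mx, sqrt(sx2), log = TRUE)) +
      sum(stats::dnorm(l_, lmean, sqrt(sl2), log = TRUE)) +
      stats::dnorm(v_, 0, sqrt(t2_v), log = TRUE) +
      stats::dnorm(wz_, 0, sqrt(t2_wz), log = TRUE)
    if (causal || reverse)
      lp <- lp + stats::dnorm(dir_, 0, sqrt(t2_dir), log = TRUE)
    lp
  }

  for (it in seq_len(config$n_iterations)) {
    alpha_f <- alpha[seq_len(nfx)]
    beta_f <- beta[seq_len(nfy)]
    v <- if (conf) alpha[i_v] else 0
    wz <- if (conf) beta[i_wz] else 0
    w <- if (causal) beta[i_w] else 0

    fy_lin <- drop(Fy %*% beta_f)            # b_0 + wg'g
    fx_lin <- drop(Fx %*% alpha_f)           # b_x + u'g (+ wr y)
    eta <- fy_lin + wz * z + (if (causal) w * x else 0)

    # -- liability layer ----------------------------------------------------
    if (prior_only) {
      l <- eta + stats::rnorm(n, 0, 1 / sqrt(precy))
    } else {
      s <- exp(log_s)
      prop <- l + s * stats::rnorm(n)
      logr <- log_bernoulli_logit(y, prop) - log_bernoulli_logit(y, l) -
        0.5 * precy * ((prop - eta)^2 - (l - eta)^2)
      acc <- log(stats::runif(n)) < logr
      l[acc] <- prop[acc]
      rate <- mean(acc)
      if (config$adapt && it <= config$burn_in)
        log_s <- log_s + (rate - 0.44) * min(0.1, 5 / sqrt(it))
      if (it > config$burn_in) { acc_post <- acc_post + rate; acc_post_n <- acc_post_n + 1L }
    }

    # -- liability-equation coefficients ------------------------------------
    Dy <- if (causal && conf) cbind(x, z) else if (causal) cbind(x)
          else if (conf) cbind(z)
    beta <- if (prior_only) stats::rnorm(ky, 0, sqrt(1 / prior_prec_y()))
            else draw_block(FtFy, Fy, Dy, l, precy, prior_prec_y())
    w <- if (causal) beta[i_w] else 0
    wz <- if (conf) beta[i_wz] else 0
    beta_f <- beta[seq_len(nfy)]
    fy_lin <- drop(Fy %*% beta_f)

    # -- latent true biomarker ---------------------------------------------
    a_full <- fx_lin + v * z
    if (prior_only) {
      x <- a_full + stats::rnorm(n, 0, 1 / sqrt(precx))
    } else {
      prec_xi <- precx + precxt + if (causal) precy * w^2 else 0
      num <- precx * a_full + precxt * xt
      if (causal) num <- num + precy * w * (l - fy_lin - wz * z)
      x <- stats::rnorm(n, num / prec_xi, 1 / sqrt(prec_xi))
    }

    # -- latent confounder --------------------------------------------------
    if (conf) {
      if (prior_only) {
        z <- stats::rnorm(n, 0, 1 / sqrt(precz))
      } else {
        c_mz <- fy_lin + (if (causal) w * x else 0)
        prec_zi <- precz + precx * v^2 + precy * wz^2
        num <- precx * v * (x - fx_lin) + precy * wz * (l - c_mz)
        z <- stats::rnorm(n, num / prec_zi, 1 / sqrt(prec_zi))
      }
    }

    # -- collapsed confounder-block move ------------------------------------
    if (conf && !prior_only) {
      v_cur <- v
      wz_cur <- wz
      dir_cur <- if (causal) w else if (reverse) alpha[i_wr] else 0
      fxw <- fx_lin - (if (reverse) dir_cur * y else 0)
      lbase <- fy_lin
      t2_v <- if (gauss) priors$gaussian_sd^2 else tau2x[i_v]
      t2_wz <- if (gauss) priors$gaussian_sd^2 else tau2y[i_wz]
      t2_dir <- if (causal) { if (gauss) priors$gaussian_sd^2 else tau2y[i_w] }
                else if (reverse) { if (gauss) priors$gaussian_sd^2 else tau2x[i_wr] }
                else 1
      commit_block <- function() {
        # write the working block back into the coefficient vectors and
        # refresh the latent confounder from its exact full conditional
        v <<- alpha[i_v] <<- v_cur
        wz <<- beta[i_wz] <<- wz_cur
        if (causal) w <<- beta[i_w] <<- dir_cur
        if (reverse) {
          alpha[i_wr] <<- dir_cur
          fx_lin <<- fxw + dir_cur * y
          alpha_f <<- alpha[seq_len(nfx)]
        }
        c_mz <- fy_lin + (if (causal) w * x else 0)
        prec_zi <- precz + precx * v^2 + precy * wz^2
        num <- precx * v * (x - fx_lin) + precy * wz * (l - c_mz)
        z <<- stats::rnorm(n, num / prec_zi, 1 / sqrt(prec_zi))
      }

      lp_cur <- collapsed_logpost(v_cur, dir_cur, wz_cur, fxw, lbase, x, l,
                                  precx, precy, t2_v, t2_dir, t2_wz)
      changed <- FALSE
      for (rep_c in seq_len(n_collapsed)) {
        step <- exp(log_sc) * drop(crossprod(blk_chol, stats::rnorm(3)))
        v_p <- v_cur + step[1]
        wz_p <- wz_cur + step[3]
        dir_p <- if (causal || reverse) dir_cur + step[2] else 0
        lp_p <- collapsed_logpost(v_p, dir_p, wz_p, fxw, lbase, x, l,
                                  precx, precy, t2_v, t2_dir, t2_wz)
        acc_c <- is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_cur
        if (acc_c) {
          v_cur <- v_p; wz_cur <- wz_p; dir_cur <- dir_p; lp_cur <- lp_p
          changed <- TRUE
        }
        if (config$adapt && it <= config$burn_in)
          log_sc <- log_sc + (as.numeric(acc_c) - 0.3) * min(0.1, 5 / sqrt(it))
      }
      if (changed) commit_block()

      # Liability-coupled companion move: propose the same block but shift
      # the stored liabilities by the implied change in the linear predictor
      # (l' = l + eta' - eta, a volume-preserving shear keeping the
      # liability noise e fixed, so the Gaussian liability term cancels).
      # Step size is then limited only by the Bernoulli and x-equation
      # terms, which are nearly flat along the direct-vs-confounded ridge;
      # this is what lets the chain traverse between the
      # likelihood-equivalent explanations. z stays part of the state here.
      changed <- FALSE
      for (rep_c in seq_len(n_collapsed)) {
        step <- exp(log_sc2) * drop(crossprod(blk_chol, stats::rnorm(3)))
        v_p <- v_cur + step[1]
        wz_p <- wz_cur + step[3]
        dir_p <- if (causal || reverse) dir_cur + step[2] else 0
        d_eta <- (wz_p - wz_cur) * z +
          (if (causal) (dir_p - dir_cur) * x else 0)
        l_p <- l + d_eta
        mx_cur <- fxw + (if (reverse) dir_cur * y else 0) + v_cur * z
        mx_p <- fxw + (if (reverse) dir_p * y else 0) + v_p * z
        lr <- sum(log_bernoulli_logit(y, l_p) - log_bernoulli_logit(y, l)) -
          0.5 * precx * sum((x - mx_p)^2 - (x - mx_cur)^2) +
          stats::dnorm(v_p, 0, sqrt(t2_v), log = TRUE) -
          stats::dnorm(v_cur, 0, sqrt(t2_v), log = TRUE) +
          stats::dnorm(wz_p, 0, sqrt(t2_wz), log = TRUE) -
          stats::dnorm(wz_cur, 0, sqrt(t2_wz), log = TRUE) +
          (if (causal || reverse)
            stats::dnorm(dir_p, 0, sqrt(t2_dir), log = TRUE) -
              stats::dnorm(dir_cur, 0, sqrt(t2_dir), log = TRUE) else 0)
        acc_c <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc_c) {
          v_cur <- v_p; wz_cur <- wz_p; dir_cur <- dir_p; l <- l_p
          changed <- TRUE
        }
        if (config$adapt && it <= config$burn_in)
          log_sc2 <- log_sc2 + (as.numeric(acc_c) - 0.3) * min(0.1, 5 / sqrt(it))
      }
      if (changed) {
        v <- alpha[i_v] <- v_cur
        wz <- beta[i_wz] <- wz_cur
        if (causal) w <- beta[i_w] <- dir_cur
        if (reverse) {
          alpha[i_wr] <- dir_cur
          fx_lin <- fxw + dir_cur * y
          alpha_f <- alpha[seq_len(nfx)]
        }
      }

      if (config$adapt && it <= config$burn_in) {
        blk <- c(v_cur, dir_cur, wz_cur)
        blk_n <- blk_n + 1L
        dlt <- blk - blk_mean
        blk_mean <- blk_mean + dlt / blk_n
        blk_m2 <- blk_m2 + tcrossprod(dlt, blk - blk_mean)
        if (blk_n > 100L && blk_n %% 25L == 0L) {
          cv <- blk_m2 / (blk_n - 1L)
          if (!(causal || reverse)) cv[2, ] <- cv[, 2] <- 0
          sig <- 2.38^2 / d_blk * cv + diag(1e-6, 3)
          ch <- tryCatch(chol(sig), error = function(e) NULL)
          if (!is.null(ch)) blk_chol <- ch
        }
      }
    }

    # -- x-equation coefficients -------------------------------------------
    alpha <- if (prior_only) stats::rnorm(kx, 0, sqrt(1 / prior_prec_x()))
             else draw_block(FtFx, Fx, if (conf) cbind(z), x, precx,
                             prior_prec_x())

    # -- Laplace scale mixture ---------------------------------------------
    if (!gauss) {
      upd_tau <- function(theta, gam, tau2) {
        j <- which(!is.na(gam))
        mu <- gam[j] / pmax(abs(theta[j]), 1e-10)
        it2 <- rinvgauss(length(j), mu, gam[j]^2)
        tau2[j] <- pmin(pmax(1 / it2, 1e-12), 1e12)
        tau2
      }
      tau2x <- upd_tau(alpha, ax_gam, tau2x)
      tau2y <- upd_tau(beta, ay_gam, tau2y)
    }

    # -- precisions ---------------------------------------------------------
    if (priors$precision_mode == "gamma" && !prior_only) {
      v_now <- if (conf) alpha[i_v] else 0
      xmean <- drop(Fx %*% alpha[seq_len(nfx)]) + v_now * z
      eta_now <- fy_lin + wz * z + (if (causal) w * x else 0)
      precx <- stats::rgamma(1, gshape + n / 2,
                             grate[1] + 0.5 * sum((x - xmean)^2))
      precxt <- stats::rgamma(1, gshape + n / 2,
                              grate[2] + 0.5 * sum((xt - x)^2))
      precy <- stats::rgamma(1, gshape + n / 2,
                             grate[3] + 0.5 * sum((l - eta_now)^2))
    }

    # -- sign alignment of the confounder reflection ------------------------
    if (conf && alpha[i_v] < 0) {
      alpha[i_v] <- -alpha[i_v]
      beta[i_wz] <- -beta[i_wz]
      z <- -z
    }

    if (!is.finite(sum(x) + sum(l) + sum(alpha) + sum(beta)))
      stop_invalid("sampler diverged (non-finite state) at iteration %d", it)

    # -- record -------------------------------------------------------------
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L &&
        kept < n_keep) {
      kept <- kept + 1L
      samples[kept, ] <- c(alpha, beta, precx, precxt, precy)
      dev[kept] <- deviance_from_focus(data, x, l, precxt)
      sum_x <- sum_x + x; sum_z <- sum_z + z; sum_l <- sum_l + l
    }
  }

  acc_rate <- if (acc_post_n > 0) acc_post / acc_post_n else NA_real_
  if (!prior_only && is.finite(acc_rate) &&
      (acc_rate < 0.05 || acc_rate > 0.95))
    warning(sprintf("liability-layer acceptance rate %.3f outside [0.05, 0.95]",
                    acc_rate), call. = FALSE)

  structure(list(
    samples = samples[seq_len(kept), , drop = FALSE],
    deviance = dev[seq_len(kept)],
    latent_mean = list(x = sum_x / kept, z = sum_z / kept, l = sum_l / kept),
    accept_rate = acc_rate,
    structure = struct, priors = priors, config = config,
    chain_id = chain_id, seed = seed, n = n, p = p,
    prior_only = prior_only
  ), class = "spiv_trace")
}

#' Fit a model by multiple MCMC chains
#'
#' Runs `config$n_chains` chains from random initializations and attaches
#' the pooled DIC decomposition.
#'
#' @inheritParams run_chain
#' @return Object of class `spiv_fit`: `traces` (list of `spiv_trace`),
#'   `dic` (a `spiv_dic`), plus the structure/priors/config used.
#' @export
fit_model <- function(data, structure, priors, config = mcmc_config()) {
  traces <- lapply(seq_len(config$n_chains), function(i)
    run_chain(data, structure, priors, config, chain_id = i))
  out <- list(traces = traces,
              dic = compute_dic(traces, data, structure, priors),
              structure = validate_structure(structure),
              priors = priors, config = config)
  class(out) <- "spiv_fit"
  out
}

#' @export
print.spiv_trace <- function(x, ...) {
  cat(sprintf("MCMC trace (chain %d, seed %d): %d retained draws, %d parameters\n",
              x$chain_id, x$seed, nrow(x$samples), ncol(x$samples)))
  cat(sprintf("Model %s; liability acceptance rate %.3f\n",
              x$structure$label, x$accept_rate))
  invisible(x)
}

#' @export
print.spiv_fit <- function(x, ...) {
  cat(sprintf("Fit of model %s (%d chains)\n", x$structure$label,
              length(x$traces)))
  print(x$dic)
  invisible(x)
}

as_trace_list <- function(x) {
  if (inherits(x, "spiv_fit")) x$traces
  else if (inherits(x, "spiv_trace")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "spiv_trace"))) x
  else stop_invalid("expected a spiv_trace, spiv_fit, or list of traces")
}

#' Posterior summary table
#'
#' Pools retained samples across chains and reports mean, SD and the
#' 2.5/50/97.5 percent quantiles for every stored parameter.
#'
#' @param trace A `spiv_trace`, `spiv_fit`, or list of traces.
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(trace) {
  traces <- as_trace_list(trace)
  sm <- do.call(rbind, lapply(traces, function(t) t$samples))
  if (nrow(sm) == 0L) stop_invalid("empty trace")
  qs <- t(apply(sm, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(parameter = colnames(sm), mean = colMeans(sm),
             sd = apply(sm, 2, stats::sd),
             q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
             row.names = NULL)
}

# Effective sample size via Geyer's initial monotone positive sequence.
ess_geyer <- function(v) {
  n <- length(v)
  if (n < 4L || stats::sd(v) == 0) return(NA_real_)
  rho <- stats::acf(v, lag.max = min(n - 1L, 500L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  m_max <- (length(rho) - 1L) %/% 2L
  gam <- numeric(0)
  for (m in 0:m_max) {
    gsum <- rho[2 * m + 1] + if (2 * m + 2 <= length(rho)) rho[2 * m + 2] else 0
    if (gsum <= 0) break
    gam <- c(gam, gsum)
  }
  if (length(gam) == 0) return(n)
  gam <- cummin(gam)  # enforce monotone non-increasing
  tau <- max(-1 + 2 * sum(gam), 1e-8)
  min(n / tau, n * 1.5)
}

# Split-chain potential scale reduction; values below 1 (finite-sample
# noise) are reported as exactly 1.
rhat_split <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    if (h < 2L) return(list(v))
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  nn <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(nn)])
  W <- mean(vapply(halves, stats::var, 0))
  if (!is.finite(W) || W == 0) return(1)
  B <- nn * stats::var(vapply(halves, mean, 0))
  var_plus <- (nn - 1) / nn * W + B / nn
  max(1, sqrt(var_plus / W))
}

#' MCMC convergence diagnostics
#'
#' Reports, per stored parameter, the pooled posterior mean, effective
#' sample size (Geyer initial monotone sequence, summed over chains) and the
#' split-chain potential scale reduction statistic, plus the posterior mean
#' deviance of each chain. A single short chain yields a report with
#' warnings rather than a failure.
#'
#' @param traces A `spiv_fit`, `spiv_trace` or list of traces.
#' @param rhat_threshold Flag parameters whose statistic exceeds this
#'   (default 1.1).
#' @return Object of class `spiv_diagnostics`: `parameters` data frame,
#'   `dbar_per_chain`, `warnings`.
#' @export
diagnose <- function(traces, rhat_threshold = 1.1) {
  traces <- as_trace_list(traces)
  sm <- lapply(traces, function(t) t$samples)
  pars <- colnames(sm[[1]])
  warnings <- character()
  if (length(traces) == 1L)
    warnings <- c(warnings, "single chain: scale-reduction statistic is within-chain only")
  if (nrow(sm[[1]]) < 100L)
    warnings <- c(warnings, "short chain: diagnostics are unreliable")
  stats_df <- data.frame(
    parameter = pars,
    mean = colMeans(do.call(rbind, sm)),
    ess = vapply(pars, function(p)
      sum(vapply(sm, function(s) ess_geyer(s[, p]), 0)), 0),
    rhat = vapply(pars, function(p)
      rhat_split(lapply(sm, function(s) s[, p])), 0),
    row.names = NULL)
  flagged <- stats_df$parameter[is.finite(stats_df$rhat) &
                                  stats_df$rhat > rhat_threshold]
  if (length(flagged))
    warnings <- c(warnings, sprintf("scale reduction > %g for: %s",
                                    rhat_threshold,
                                    paste(flagged, collapse = ", ")))
  structure(list(parameters = stats_df,
                 dbar_per_chain = vapply(traces, function(t)
                   mean(t$deviance), 0),
                 warnings = warnings),
            class = "spiv_diagnostics")
}

#' @export
print.spiv_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics over %d parameters\n", nrow(x$parameters)))
  cat(sprintf("Dbar per chain: %s\n",
              paste(sprintf("%.2f", x$dbar_per_chain), collapse = ", ")))
  worst <- x$parameters[which.max(x$parameters$rhat), ]
  cat(sprintf("Worst scale reduction: %.3f (%s)\n", worst$rhat, worst$parameter))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Persist a trace to disk
#'
#' Samples and deviance series go to a CSV; configuration, seed and latent
#' summaries to a JSON sidecar.
#'
#' @param trace A `spiv_trace`.
#' @param path Base path (without extension).
#' @return The base path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(cbind(as.data.frame(trace$samples),
                         deviance = trace$deviance),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(structure = unclass(trace$structure),
               priors = unclass(trace$priors),
               config = unclass(trace$config),
               chain_id = trace$chain_id, seed = trace$seed,
               accept_rate = trace$accept_rate,
               latent_mean = trace$latent_mean)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
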