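# The family of graphical models relating predictors g, true biomarker x,
# measured biomarker xt, latent confounder z and binary outcome y.
#
# A structure is a triple (direction of the x-y link, confounder on/off,
# pleiotropy on/off); the eight named members M1..M8 cover the structures
# used in the three model-comparison experiments. All linear layers are
# Gaussian; the outcome layer is a sparse logistic regression on a liability
# with Gaussian noise (precision precy).

MODEL_LABELS <- list(
  M1 = list(direction = "causal",  include_confounder = TRUE,  include_pleiotropy = TRUE),
  M2 = list(direction = "causal",  include_confounder = FALSE, include_pleiotropy = TRUE),
  M3 = list(direction = "reverse", include_confounder = FALSE, include_pleiotropy = TRUE),
  M4 = list(direction = "causal",  include_confounder = FALSE, include_pleiotropy = FALSE),
  M5 = list(direction = "reverse", include_confounder = FALSE, include_pleiotropy = FALSE),
  M6 = list(direction = "none",    include_confounder = TRUE,  include_pleiotropy = TRUE),
  M7 = list(direction = "causal",  include_confounder = TRUE,  include_pleiotropy = TRUE),
  M8 = list(direction = "reverse", include_confounder = TRUE,  include_pleiotropy = TRUE)
)

#' Define a graphical model structure
#'
#' Either give a canonical label (`"M1"`..`"M8"`) or the three structural
#' flags. The named models are: M1/M7 causal with confounder and pleiotropy;
#' M2 causal, no confounder; M3 reverse, no confounder; M4 causal without
#' confounder or pleiotropy; M5 its reverse twin; M6 association through the
#' confounder only; M8 reverse with confounder and pleiotropy. In the
#' no-pleiotropy models all predictors act only on the upstream variable
#' (the biomarker in M4, the outcome in M5).
#'
#' @param label Optional canonical label `"M1"`..`"M8"`.
#' @param direction One of `"causal"`, `"reverse"`, `"none"`.
#' @param include_confounder,include_pleiotropy Logical flags.
#' @return Object of class `spiv_structure`.
#' @export
model_structure <- function(label = NULL,
                            direction = c("causal", "reverse", "none"),
                            include_confounder = TRUE,
                            include_pleiotropy = TRUE) {
  if (!is.null(label)) {
    if (!label %in% names(MODEL_LABELS))
      stop_invalid("unknown model label '%s'; known labels: %s",
                   label, paste(names(MODEL_LABELS), collapse = ", "))
    s <- MODEL_LABELS[[label]]
    s$label <- label
  } else {
    s <- list(direction = match.arg(direction),
              include_confounder = isTRUE(include_confounder),
              include_pleiotropy = isTRUE(include_pleiotropy))
    s$label <- canonical_label(s)
  }
  validate_structure(structure(s, class = "spiv_structure"))
}

canonical_label <- function(s) {
  hit <- Filter(function(m)
    m$direction == s$direction &&
      m$include_confounder == s$include_confounder &&
      m$include_pleiotropy == s$include_pleiotropy,
    MODEL_LABELS)
  if (length(hit)) paste(names(hit), collapse = "/") else "null"
}

#' Validate a model structure
#'
#' Rejects inconsistent flag combinations and attaches the canonical label.
#' A structure with no association pathway at all (`direction = "none"`
#' without a confounder) is allowed but labelled `"null"`, outside M1-M8.
#'
#' @param structure A `spiv_structure`.
#' @return The checked structure.
#' @export
validate_structure <- function(structure) {
  s <- structure
  if (!s$direction %in% c("causal", "reverse", "none"))
    stop_invalid("direction must be causal, reverse or none")
  if (s$direction == "none" && !s$include_pleiotropy && !s$include_confounder)
    stop_invalid("structure has no pathway from predictors to the outcome at all")
  s$label <- canonical_label(s)
  s
}

#' @export
print.spiv_structure <- function(x, ...) {
  cat(sprintf("Model %s: direction = %s, confounder = %s, pleiotropy = %s\n",
              x$label, x$direction, x$include_confounder, x$include_pleiotropy))
  invisible(x)
}

#' Prior and noise settings of a model
#'
#' Linear coefficients carry zero-mean Laplace priors with density
#' `(gam/2) exp(-gam |theta|)`: `gam1` for the direct coefficient blocks
#' (u, w, wr, wg) and `gam2` (defaulting to `gam1`) for the confounder links
#' v and wz. `precx`, `precxt`, `precy` are the precisions (inverse
#' variances) of the true-biomarker residual, the measurement noise and the
#' liability noise; `precz` is fixed at 1 whenever the confounder is present,
#' for identifiability. Precisions are either held fixed or given conjugate
#' Gamma priors. Intercepts always carry broad Gaussian priors.
#'
#' @param gam1 Laplace concentration for the direct coefficient blocks
#'   (default 0.025).
#' @param gam2 Laplace concentration for the confounder links (default
#'   `gam1`).
#' @param precx,precxt,precy Positive precisions.
#' @param precz Confounder precision (fixed at 1).
#' @param precision_mode `"fixed"` or `"gamma"` (conjugate Gamma priors on
#'   precx, precxt, precy, initialized at the given values).
#' @param gamma_shape,gamma_rate Hyperparameters of the Gamma priors.
#' @param coef_prior `"laplace"` (default) or `"gaussian"` (fixed-variance
#'   Gaussian coefficients, useful for conjugate validation).
#' @param gaussian_sd Prior SD when `coef_prior = "gaussian"`.
#' @param intercept_sd Prior SD of the intercepts (default 10).
#' @return Object of class `spiv_priors`.
#' @export
prior_settings <- function(gam1 = 0.025, gam2 = gam1,
                           precx = 200, precxt = 200, precy = 100,
                           precz = 1,
                           precision_mode = c("fixed", "gamma"),
                           gamma_shape = 2, gamma_rate = NULL,
                           coef_prior = c("laplace", "gaussian"),
                           gaussian_sd = 1, intercept_sd = 10) {
  precision_mode <- match.arg(precision_mode)
  coef_prior <- match.arg(coef_prior)
  if (any(c(gam1, gam2, precx, precxt, precy, precz) <= 0))
    stop_invalid("gam1, gam2 and all precisions must be strictly positive")
  structure(list(
    gam1 = gam1, gam2 = gam2,
    precx = precx, precxt = precxt, precy = precy, precz = precz,
    precision_mode = precision_mode,
    gamma_shape = gamma_shape, gamma_rate = gamma_rate,
    coef_prior = coef_prior, gaussian_sd = gaussian_sd,
    intercept_sd = intercept_sd
  ), class = "spiv_priors")
}

PRIOR_PRESETS <- list(
  Setting1 = c(precxt = 200,  precx = 200,  precy = 100),
  Setting2 = c(precxt = 1000, precx = 1000, precy = 0.1),
  Setting3 = c(precxt = 100,  precx = 100,  precy = 100),
  S1 = c(precx = 1000, precxt = 1000, precy = 0.1),
  S2 = c(precx = 100,  precxt = 100,  precy = 100),
  S3 = c(precx = 1000, precxt = 1000, precy = 10),
  S4 = c(precx = 100,  precxt = 100,  precy = 200),
  S5 = c(precx = 20,   precxt = 20,   precy = 200)
)

#' Named precision presets
#'
#' `Setting1`-`Setting3` are the noise settings of the confounder and
#' LCMS-comparison experiments; `S1`-`S5` the settings of the full
#' causal-vs-reverse comparison. All use `gam1 = 0.025` unless overridden
#' and `precz = 1`.
#'
#' @param name Preset name (`"Setting1"`..`"Setting3"`, `"S1"`..`"S5"`).
#' @param ... Overrides passed to [prior_settings()].
#' @return A `spiv_priors` object.
#' @export
prior_preset <- function(name, ...) {
  if (!name %in% names(PRIOR_PRESETS))
    stop_invalid("unknown preset '%s'; available: %s", name,
                 paste(names(PRIOR_PRESETS), collapse = ", "))
  p <- PRIOR_PRESETS[[name]]
  args <- utils::modifyList(as.list(p), list(...))
  pr <- do.call(prior_settings, args)
  pr$preset <- name
  pr
}

#' @export
print.spiv_priors <- function(x, ...) {
  cat(sprintf("Priors%s: gam1 = %g, gam2 = %g; precx = %g, precxt = %g, precy = %g, precz = %g (%s)\n",
              if (!is.null(x$preset)) sprintf(" [%s]", x$preset) else "",
              x$gam1, x$gam2, x$precx, x$precxt, x$precy, x$precz,
              x$precision_mode))
  invisible(x)
}

#' Log density of the zero-mean Laplace prior
#'
#' `log[(gam/2) exp(-gam |theta|)]`. Larger `gam` concentrates mass at zero
#' and so favours sparser models.
#'
#' @param theta Numeric.
#' @param gam Positive concentration.
#' @return Numeric log density.
#' @export
laplace_log_density <- function(theta, gam) {
  if (any(gam <= 0)) stop_invalid("gam must be > 0")
  log(gam / 2) - gam * abs(theta)
}

#' Construct a parameter state
#'
#' Coefficients of links absent from the structure must be zero (checked by
#' [log_joint()]). `e` is the per-subject Gaussian liability noise; the
#' liability itself is `b_0 + w x + wg'g + wz z + e`.
#'
#' @param u,wg Numeric coefficient vectors (length p).
#' @param w,wr,v,wz,b_x,b_0 Scalars.
#' @param z,x,e Per-subject latent vectors.
#' @param precx,precxt,precy Optional realized precisions (defaults taken
#'   from the priors at evaluation time).
#' @return Object of class `spiv_state`.
#' @export
parameter_state <- function(u, w = 0, wr = 0, wg = NULL, v = 0, wz = 0,
                            b_x = 0, b_0 = 0, z = NULL, x = NULL, e = NULL,
                            precx = NULL, precxt = NULL, precy = NULL) {
  structure(list(u = u, w = w, wr = wr,
                 wg = if (is.null(wg)) numeric(length(u)) else wg,
                 v = v, wz = wz, b_x = b_x, b_0 = b_0,
                 z = z, x = x, e = e,
                 precx = precx, precxt = precxt, precy = precy),
            class = "spiv_state")
}

state_precisions <- function(state, priors) {
  c(precx = state$precx %||% priors$precx,
    precxt = state$precxt %||% priors$precxt,
    precy = state$precy %||% priors$precy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean of the x-equation and the outcome liability linear predictor, given
# a state and the structure.
linear_predictors <- function(state, data, structure) {
  g <- data$g
  x_mean <- state$b_x + drop(g %*% state$u) + state$v * state$z
  if (structure$direction == "reverse") x_mean <- x_mean + state$wr * data$y
  eta <- state$b_0 + drop(g %*% state$wg) + state$wz * state$z
  if (structure$direction == "causal") eta <- eta + state$w * state$x
  list(x_mean = x_mean, eta = eta)
}

check_state_structure <- function(state, structure) {
  if (structure$direction != "causal" && any(state$w != 0))
    stop_invalid("structure %s has no causal x->y link but w != 0",
                 structure$label)
  if (structure$direction != "reverse" && any(state$wr != 0))
    stop_invalid("structure %s has no reverse y->x link but wr != 0",
                 structure$label)
  if (!structure$include_confounder && (any(state$v != 0) || any(state$wz != 0)))
    stop_invalid("structure %s has no confounder but v/wz != 0", structure$label)
  if (!structure$include_pleiotropy) {
    if (structure$direction == "causal" && any(state$wg != 0))
      stop_invalid("no-pleiotropy causal structure requires wg = 0")
    if (structure$direction == "reverse" && any(state$u != 0))
      stop_invalid("no-pleiotropy reverse structure requires u = 0")
  }
  invisible(TRUE)
}

#' Log joint density of data, latents and parameters
#'
#' Sums, over individuals, the linear-Gaussian terms for the true biomarker,
#' its measurement and the liability noise, the Bernoulli outcome term, and
#' the standard-normal confounder term; plus (optionally) the coefficient
#' priors -- Laplace with `gam1` for the direct blocks, `gam2` for the
#' confounder links, broad Gaussians for the intercepts -- and Gamma prior
#' terms when `precision_mode = "gamma"`.
#'
#' @param state A `spiv_state` consistent with `structure`.
#' @param data A `spiv_data` (needs `g`, `xt`, `y`).
#' @param structure A `spiv_structure`.
#' @param priors A `spiv_priors`.
#' @param include_priors Include the prior terms (default `TRUE`).
#' @return Scalar log density.
#' @export
log_joint <- function(state, data, structure, priors, include_priors = TRUE) {
  check_state_structure(state, structure)
  pr <- state_precisions(state, priors)
  lp <- linear_predictors(state, data, structure)
  l <- lp$eta + state$e
  ll <- sum(log_dnorm_prec(state$x, lp$x_mean, pr["precx"])) +
    sum(log_dnorm_prec(data$xt, state$x, pr["precxt"])) +
    sum(log_dnorm_prec(state$e, 0, pr["precy"])) +
    sum(log_bernoulli_logit(data$y, l))
  if (structure$include_confounder)
    ll <- ll + sum(log_dnorm_prec(state$z, 0, priors$precz))
  if (include_priors) {
    coef_lp <- function(theta, gam)
      if (priors$coef_prior == "laplace") sum(laplace_log_density(theta, gam))
      else sum(stats::dnorm(theta, 0, priors$gaussian_sd, log = TRUE))
    active <- active_coefficients(structure)
    if ("u" %in% active)  ll <- ll + coef_lp(state$u, priors$gam1)
    if ("w" %in% active)  ll <- ll + coef_lp(state$w, priors$gam1)
    if ("wr" %in% active) ll <- ll + coef_lp(state$wr, priors$gam1)
    if ("wg" %in% active) ll <- ll + coef_lp(state$wg, priors$gam1)
    if ("v" %in% active)  ll <- ll + coef_lp(state$v, priors$gam2)
    if ("wz" %in% active) ll <- ll + coef_lp(state$wz, priors$gam2)
    ll <- ll + stats::dnorm(state$b_x, 0, priors$intercept_sd, log = TRUE) +
      stats::dnorm(state$b_0, 0, priors$intercept_sd, log = TRUE)
    if (priors$precision_mode == "gamma") {
      rate <- gamma_rates(priors)
      ll <- ll + sum(stats::dgamma(pr, shape = priors$gamma_shape,
                                   rate = rate, log = TRUE))
    }
  }
  if (!is.finite(ll)) {
    terms <- c(x_eq = sum(log_dnorm_prec(state$x, lp$x_mean, pr["precx"])),
               xt_eq = sum(log_dnorm_prec(data$xt, state$x, pr["precxt"])),
               e_eq = sum(log_dnorm_prec(state$e, 0, pr["precy"])),
               outcome = sum(log_bernoulli_logit(data$y, l)))
    bad <- names(terms)[!is.finite(terms)]
    stop_invalid("non-finite log joint (offending term(s): %s)",
                 paste(if (length(bad)) bad else "prior", collapse = ", "))
  }
  ll
}

# Which coefficient blocks exist for a structure.
active_coefficients <- function(structure) {
  act <- character()
  if (structure$direction != "reverse" || structure$include_pleiotropy)
    act <- c(act, "u")
  if (structure$direction == "causal") act <- c(act, "w")
  if (structure$direction == "reverse") act <- c(act, "wr")
  if (structure$direction != "causal" || structure$include_pleiotropy)
    act <- c(act, "wg")
  if (structure$include_confounder) act <- c(act, "v", "wz")
  act
}

# Gamma prior rates chosen so the prior mean equals the configured precision.
gamma_rates <- function(priors) {
  if (!is.null(priors$gamma_rate)) rep_len(priors$gamma_rate, 3L)
  else priors$gamma_shape / c(priors$precx, priors$precxt, priors$precy)
}

#' Deviance of the observed data given a parameter state
#'
#' `-2` times the observed-data log likelihood -- the measurement term
#' `log N(xt | x, 1/precxt)` and the outcome term
#' `log Bernoulli(y | sigmoid(liability))` -- conditioning on the latents
#' (z, x, e) as parameters in focus. Prior terms are excluded. Can be
#' negative when the measurement precision is high.
#'
#' @inheritParams log_joint
#' @return Scalar deviance.
#' @export
compute_deviance <- function(state, data, structure, priors) {
  check_state_structure(state, structure)
  pr <- state_precisions(state, priors)
  lp <- linear_predictors(state, data, structure)
  l <- lp$eta + state$e
  deviance_from_focus(data, state$x, l, pr["precxt"])
}

# Deviance as a function of the focused quantities only.
deviance_from_focus <- function(data, x, l, precxt) {
  d <- -2 * (sum(log_dnorm_prec(data$xt, x, precxt)) +
               sum(log_bernoulli_logit(data$y, l)))
  if (!is.finite(d)) stop_invalid("non-finite deviance")
  unname(d)
}

#' Serialize structures and priors to JSON
#'
#' @param x A `spiv_structure` or `spiv_priors`.
#' @param path Output path.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure or prior settings back from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @param what `"structure"` or `"priors"`.
#' @return The reconstructed object.
#' @export
read_model_json <- function(path, what = c("structure", "priors")) {
  what <- match.arg(what)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (what == "structure")
    model_structure(direction = obj$direction,
                    include_confounder = obj$include_confounder,
                    include_pleiotropy = obj$include_pleiotropy)
  else do.call(prior_settings, obj[intersect(names(obj), names(formals(prior_settings)))])
}
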