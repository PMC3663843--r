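# Preprocessing: from a raw cohort table to the analysis-ready predictor
# matrix g (scaled covariates + genotype principal components) and the
# May-standardized biomarker.

#' Center and scale the columns of a matrix
#'
#' Each column is centered by its mean and divided by its sample standard
#' deviation (denominator n - 1). Scaling parameters are retained as
#' attributes so the transform is reproducible.
#'
#' @param m Numeric matrix (or data frame of numerics).
#' @return Matrix with columns of mean 0 and SD 1, carrying attributes
#'   `"scaled:center"` and `"scaled:scale"`.
#' @export
scale_columns <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    nm <- colnames(m)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop_invalid("zero-variance column(s): %s", paste(nm, collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)
}

#' Principal-component scores of a genotype dosage matrix
#'
#' Computes PCA on the column-centered (but unstandardized) dosage matrix
#' and returns the first `k` score columns, ordered by non-increasing
#' explained variance. The sign of each component is fixed so that its
#' largest-magnitude loading is positive. Constant columns are dropped with
#' a warning before the decomposition.
#'
#' @param genotypes Numeric matrix of dosages (individuals x loci).
#' @param k Number of components to keep (default 6).
#' @return An `n x k` score matrix with a `"rotation"` attribute holding the
#'   loadings and `"sdev"` the component standard deviations.
#' @export
genotype_pcs <- function(genotypes, k = 6L) {
  g <- as.matrix(genotypes)
  sds <- apply(g, 2, stats::sd)
  const <- which(sds == 0)
  if (length(const)) {
    nm <- colnames(g)[const]
    if (is.null(nm)) nm <- as.character(const)
    warning(sprintf("dropping constant genotype column(s): %s",
                    paste(nm, collapse = ", ")), call. = FALSE)
    g <- g[, -const, drop = FALSE]
  }
  if (k > ncol(g)) stop_invalid("k = %d exceeds the %d usable loci", k, ncol(g))
  if (nrow(g) <= k) stop_invalid("need more individuals than components")
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(k))
  attr(scores, "rotation") <- rot
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  scores
}

#' Standardize a seasonal biomarker to its May-expected value
#'
#' Fits `value ~ a + b cos(2 pi m / 12) + c sin(2 pi m / 12)` by least
#' squares and returns the residual plus the fitted value at May (m = 5),
#' removing the seasonal oscillation while keeping the May baseline.
#'
#' @param values Numeric measurements.
#' @param months Integer sampling months in 1..12.
#' @return A list of class `spiv_biomarker`: `xt` (adjusted values),
#'   `coefficients` (a, b, c), `amplitude` (`sqrt(b^2 + c^2)`).
#' @export
deseasonalize_to_may <- function(values, months) {
  if (any(!months %in% 1:12)) stop_invalid("months must be integers in 1..12")
  if (length(values) != length(months)) stop_invalid("length mismatch")
  if (length(unique(months)) < 2L) {
    # A single sampling month carries no seasonal information. If that month
    # is May the May-adjustment is the identity and is returned exactly;
    # otherwise the fit is singular and the adjustment is undefined.
    if (unique(months) == 5L)
      return(structure(list(xt = values,
                            coefficients = c(intercept = mean(values),
                                             cos = 0, sin = 0),
                            amplitude = 0), class = "spiv_biomarker"))
    stop_invalid("all samples fall in one month; the seasonal fit is singular")
  }
  cc <- cos(2 * pi * months / 12)
  ss <- sin(2 * pi * months / 12)
  fit <- stats::lm(values ~ cc + ss)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  may <- cf[1] + cf[2] * cos(2 * pi * 5 / 12) + cf[3] * sin(2 * pi * 5 / 12)
  structure(list(
    xt = unname(stats::residuals(fit) + may),
    coefficients = stats::setNames(unname(cf), c("intercept", "cos", "sin")),
    amplitude = unname(sqrt(cf[2]^2 + cf[3]^2))
  ), class = "spiv_biomarker")
}

#' Assemble the scaled predictor matrix g
#'
#' Horizontally concatenates the environmental covariates (ordinal
#' categories already integer-coded) and the genotype principal-component
#' scores, then scales every column to mean 0 / SD 1.
#'
#' @param covariates Data frame or matrix of covariates.
#' @param pc_scores Optional matrix of genotype PC scores (may be `NULL`).
#' @return Scaled predictor matrix with named columns.
#' @export
assemble_predictors <- function(covariates, pc_scores = NULL) {
  cv <- as.matrix(covariates)
  if (!is.null(pc_scores)) {
    if (nrow(cv) != nrow(pc_scores))
      stop_invalid("covariates (%d rows) and pc_scores (%d rows) differ",
                   nrow(cv), nrow(pc_scores))
    cv <- cbind(cv, pc_scores)
  }
  scale_columns(cv)
}

#' Univariate logistic association of a predictor with the outcome
#'
#' Maximum-likelihood logistic regression of `y` on `predictor` (plus any
#' adjusters), with a two-sided Wald test on the predictor coefficient.
#'
#' @param y Binary outcome (0/1).
#' @param predictor Numeric vector.
#' @param adjusters Optional numeric matrix of adjustment covariates.
#' @return List with `estimate` (log odds ratio), `se`, `p_value`.
#' @export
univariate_association <- function(y, predictor, adjusters = NULL) {
  if (length(unique(y)) < 2L) stop_invalid("outcome y is constant")
  if (stats::sd(predictor) == 0) stop_invalid("predictor has zero variance")
  df <- data.frame(.y = y, .predictor = predictor)
  rhs <- ".predictor"
  if (!is.null(adjusters)) {
    adj <- as.data.frame(adjusters)
    names(adj) <- paste0(".adj", seq_along(adj))
    df <- cbind(df, adj)
    rhs <- c(rhs, names(adj))
  }
  fit <- suppressWarnings(stats::glm(stats::reformulate(rhs, ".y"),
                                     data = df, family = stats::binomial()))
  eta <- stats::predict(fit, type = "link")
  if (!fit$converged || any(abs(eta) > 30))
    stop_invalid("logistic fit did not converge (possible perfect separation)")
  row <- summary(fit)$coefficients[".predictor", ]
  list(estimate = unname(row[1]), se = unname(row[2]),
       p_value = unname(row[4]))
}

#' Preprocess a cohort into analysis-ready model inputs
#'
#' Runs the full preprocessing chain: May-standardization of the measured
#' biomarker, genotype PCA, covariate coding and column scaling.
#'
#' @param cohort A `spiv_cohort` (or any data frame in the cohort CSV
#'   dialect).
#' @param n_pcs Number of genotype principal components (default 6).
#' @param scale_biomarker If `TRUE`, z-score the May-adjusted biomarker; by
#'   default it stays on its (May-adjusted) concentration scale, so the
#'   interpretation of the analysis precisions is unchanged.
#' @param genotypes `"pcs"` (default) compresses the dosage matrix to
#'   `n_pcs` principal components; `"dosages"` keeps every scaled dosage
#'   column as its own predictor (useful when the fitted model must nest the
#'   generative one, e.g. in parameter-recovery studies of unlinked loci,
#'   where PC compression would push genetic biomarker variance into the
#'   confounder loading).
#' @return A list of class `spiv_data`: `g` (scaled predictor matrix),
#'   `xt` (standardized biomarker), `y` (outcome), `months`, `seasonal`
#'   (fitted seasonal model), `pca` (loadings/sdev attributes).
#' @export
preprocess_cohort <- function(cohort, n_pcs = 6L, scale_biomarker = FALSE,
                              genotypes = c("pcs", "dosages")) {
  genotypes <- match.arg(genotypes)
  needed <- c("y", "xt_raw", "month", covariate_names())
  miss <- setdiff(needed, names(cohort))
  if (length(miss))
    stop_invalid("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  snp_cols <- grep("^snp[0-9]+$", names(cohort), value = TRUE)
  season <- deseasonalize_to_may(cohort$xt_raw, cohort$month)
  xt <- season$xt
  if (scale_biomarker) xt <- drop(scale(xt))
  pcs <- if (genotypes == "dosages" && length(snp_cols))
    as.matrix(cohort[, snp_cols, drop = FALSE])
  else if (n_pcs > 0L && length(snp_cols))
    genotype_pcs(cohort[, snp_cols, drop = FALSE], k = n_pcs)
  else NULL
  g <- assemble_predictors(cohort[, covariate_names(), drop = FALSE], pcs)
  structure(list(
    g = g, xt = xt, y = as.integer(cohort$y), months = cohort$month,
    seasonal = season,
    pca = if (!is.null(pcs)) list(rotation = attr(pcs, "rotation"),
                                  sdev = attr(pcs, "sdev"))
  ), class = "spiv_data")
}

#' @export
print.spiv_data <- function(x, ...) {
  cat(sprintf("Analysis-ready data: n = %d (%d cases), p = %d predictors\n",
              length(x$y), sum(x$y == 1), ncol(x$g)))
  cat(sprintf("Seasonal amplitude removed: %.3f\n", x$seasonal$amplitude))
  invisible(x)
}
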