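# DIC computation, model comparison verdicts and experiment grids.

#' Assemble a DIC decomposition from deviance summaries
#'
#' `Dbar` is the posterior mean deviance, `Dhat` the deviance at the
#' posterior means of the focused quantities, `pD = Dbar - Dhat` the
#' effective number of parameters and `DIC = Dbar + pD`. The identities hold
#' exactly by construction.
#'
#' @param deviance_samples Numeric vector of per-draw deviances.
#' @param deviance_at_means Deviance evaluated at the posterior means of the
#'   focused quantities.
#' @param label,setting,seed Optional bookkeeping fields.
#' @return Object of class `spiv_dic`.
#' @export
dic_from_deviance <- function(deviance_samples, deviance_at_means,
                              label = NA_character_, setting = NA_character_,
                              seed = NA_integer_) {
  if (length(deviance_samples) == 0L)
    stop_invalid("empty deviance series")
  if (any(!is.finite(deviance_samples)) || !is.finite(deviance_at_means))
    stop_invalid("non-finite deviance input")
  dbar <- mean(deviance_samples)
  pd <- dbar - deviance_at_means
  structure(list(Dbar = dbar, Dhat = deviance_at_means, pD = pd,
                 DIC = dbar + pd, label = label, setting = setting,
                 seed = seed, n_samples = length(deviance_samples)),
            class = "spiv_dic")
}

#' Deviance information criterion from MCMC output
#'
#' Pools the per-sample deviance series across chains for `Dbar`, and
#' evaluates the deviance at the pooled posterior means of the focused
#' quantities -- the latent true biomarker and the liability (which together
#' carry the coefficients' and confounders' contribution to the
#' observed-data likelihood), plus the posterior mean measurement precision
#' when precisions are sampled -- for `Dhat`.
#'
#' @param trace A `spiv_trace`, `spiv_fit` or list of traces.
#' @param data The `spiv_data` the model was fitted to.
#' @param structure,priors Optional; defaults taken from the trace.
#' @return A `spiv_dic`.
#' @export
compute_dic <- function(trace, data, structure = NULL, priors = NULL) {
  traces <- as_trace_list(trace)
  tr1 <- traces[[1]]
  priors <- priors %||% tr1$priors
  struct <- structure %||% tr1$structure
  dev <- unlist(lapply(traces, function(t) t$deviance))
  if (length(dev) == 0L) stop_invalid("trace carries no deviance series")
  nk <- vapply(traces, function(t) length(t$deviance), 0)
  wsum <- function(f) Reduce(`+`, Map(function(t, w) w * t$latent_mean[[f]],
                                      traces, nk / sum(nk)))
  xbar <- wsum("x"); lbar <- wsum("l")
  precxt_bar <- if (priors$precision_mode == "gamma")
    mean(unlist(lapply(traces, function(t) t$samples[, "precxt"])))
  else priors$precxt
  dhat <- deviance_from_focus(data, xbar, lbar, precxt_bar)
  dic_from_deviance(dev, dhat, label = struct$label,
                    setting = priors$preset %||% NA_character_,
                    seed = tr1$config$seed)
}

#' @export
print.spiv_dic <- function(x, ...) {
  cat(sprintf("DIC %s%s: Dbar = %.2f, Dhat = %.2f, pD = %.2f, DIC = %.2f\n",
              if (!is.na(x$label)) x$label else "",
              if (!is.na(x$setting)) sprintf(" [%s]", x$setting) else "",
              x$Dbar, x$Dhat, x$pD, x$DIC))
  invisible(x)
}

dic_value <- function(x) {
  if (inherits(x, "spiv_dic")) x$DIC
  else if (inherits(x, "spiv_fit")) x$dic$DIC
  else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
  else stop_invalid("expected a spiv_dic, spiv_fit or scalar DIC value")
}

dbar_value <- function(x) {
  if (inherits(x, "spiv_dic")) x$Dbar
  else if (inherits(x, "spiv_fit")) x$dic$Dbar
  else if (inherits(x, "spiv_trace")) mean(x$deviance)
  else if (is.numeric(x)) mean(x)
  else stop_invalid("cannot extract a mean deviance from this object")
}

#' DIC difference between two models
#'
#' Returns `DIC_b - DIC_a`; positive values favour model `a` (lower DIC is
#' better).
#'
#' @param result_a,result_b `spiv_dic` objects, fits, or scalar DIC values.
#' @return Numeric difference.
#' @export
dic_difference <- function(result_a, result_b) {
  dic_value(result_b) - dic_value(result_a)
}

#' Interpret a DIC difference
#'
#' Absolute differences above 10 units are decisive against the higher-DIC
#' model; differences in the closed interval \[5, 10\] are substantial;
#' below 5 the comparison is inconclusive.
#'
#' @param delta Numeric DIC difference.
#' @return `"decisive"`, `"substantial"` or `"inconclusive"`.
#' @export
interpret_difference <- function(delta) {
  d <- abs(delta)
  ifelse(d > 10, "decisive", ifelse(d >= 5, "substantial", "inconclusive"))
}

#' Compare two models by posterior mean deviance
#'
#' Returns `Dbar_b - Dbar_a` in natural log-deviance units; positive values
#' favour model `a`.
#'
#' @param trace_a,trace_b Traces, fits, `spiv_dic`s or deviance vectors.
#' @return Numeric difference.
#' @export
compare_dbar <- function(trace_a, trace_b) {
  dbar_value(trace_b) - dbar_value(trace_a)
}

#' Pairwise model comparison with verdict
#'
#' @param result_a,result_b `spiv_dic` objects (or fits).
#' @return Object of class `spiv_comparison` with the DIC difference
#'   (`DIC_b - DIC_a`, positive favours a), the verdict from the 5/10-unit
#'   thresholds, and the Dbar difference when available.
#' @export
comparison_result <- function(result_a, result_b) {
  delta <- dic_difference(result_a, result_b)
  dd <- tryCatch(compare_dbar(result_a, result_b), error = function(e) NA_real_)
  structure(list(
    model_a = if (inherits(result_a, "spiv_dic")) result_a$label else
      if (inherits(result_a, "spiv_fit")) result_a$dic$label else NA_character_,
    model_b = if (inherits(result_b, "spiv_dic")) result_b$label else
      if (inherits(result_b, "spiv_fit")) result_b$dic$label else NA_character_,
    dic_difference = delta,
    verdict = interpret_difference(delta),
    dbar_difference = dd
  ), class = "spiv_comparison")
}

#' @export
print.spiv_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: DIC difference = %.2f (%s)\n",
              x$model_a, x$model_b, x$dic_difference, x$verdict))
  invisible(x)
}

#' Mean DIC over a group of results
#'
#' The experiment grids summarize each prior setting by the arithmetic mean
#' DIC over all causal and reverse models in the group.
#'
#' @param grid A `spiv_grid` data frame (or any data frame with a `DIC`
#'   column), or a plain numeric vector of DIC values.
#' @param group_key Optional column name to group by (e.g. `"gam1"` or
#'   `"setting"`); ignored for numeric input.
#' @return A named numeric vector of group means (a single value for
#'   ungrouped input).
#' @export
mean_dic <- function(grid, group_key = NULL) {
  if (is.numeric(grid)) {
    if (length(grid) == 0L) stop_invalid("empty group")
    return(mean(grid))
  }
  if (!"DIC" %in% names(grid)) stop_invalid("grid lacks a DIC column")
  if (nrow(grid) == 0L) stop_invalid("empty group")
  if (is.null(group_key)) return(mean(grid$DIC))
  if (!group_key %in% names(grid))
    stop_invalid("unknown group key '%s'", group_key)
  m <- tapply(grid$DIC, grid[[group_key]], mean)
  stats::setNames(as.vector(m), names(m))
}

experiment_structures <- function(experiment_id) {
  switch(as.character(experiment_id),
         "1" = c("M1", "M2", "M3"),
         "2" = c("M4", "M5", "M6"),
         "3-explore" = c("M7", "M8"),
         "3-final" = c("M7", "M8"),
         stop_invalid("unknown experiment id '%s' (use 1, 2, 3-explore, 3-final)",
                      experiment_id))
}

#' Draw a case-control subsample from preprocessed data
#'
#' @param data A `spiv_data`.
#' @param n_cases,n_controls Counts to keep.
#' @param seed RNG seed.
#' @return A `spiv_data` restricted to the sampled rows.
#' @export
subsample_data <- function(data, n_cases = 500L, n_controls = 500L, seed = 1L) {
  if (sum(data$y == 1) < n_cases || sum(data$y == 0) < n_controls)
    stop_invalid("not enough cases/controls to subsample")
  keep <- with_seed(seed, sort(c(sample(which(data$y == 1), n_cases),
                                 sample(which(data$y == 0), n_controls))))
  out <- data
  out$g <- data$g[keep, , drop = FALSE]
  out$xt <- data$xt[keep]
  out$y <- data$y[keep]
  out$months <- data$months[keep]
  out
}

#' Run a model-comparison experiment grid
#'
#' Fits every requested structure under every prior setting with `repeats`
#' seeds and collects the DIC decompositions plus pairwise comparisons per
#' setting. Experiment 1 compares the full causal model with confounders
#' (M1) against the causal (M2) and reverse (M3) models without confounders;
#' experiment 2 the conventional no-pleiotropy causal (M4) and reverse (M5)
#' models against the confounder-only model (M6); experiment 3 the full
#' causal (M7) and reverse (M8) models -- in its exploratory phase on a
#' seeded subsample of 500 cases and 500 controls over a (gam1, gam2) grid,
#' and in its final phase on the complete data over precision settings.
#' Chain failures are recorded per cell and the grid completes.
#'
#' @param experiment_id One of `1`, `2`, `"3-explore"`, `"3-final"`.
#' @param data A `spiv_data`.
#' @param settings A list of `spiv_priors` (for experiments 1, 2, 3-final);
#'   for `"3-explore"` give `gam1_grid`/`gam2_grid` instead.
#' @param config A `spiv_mcmc_config`; each repeat `r` offsets the seed.
#' @param repeats Number of seeded repeats per cell (default 1).
#' @param gam1_grid,gam2_grid Sparsity grids for the exploratory phase
#'   (defaults: the published 5 x 6 grid).
#' @param explore_priors Base priors for the exploratory phase (default
#'   preset `S1`).
#' @param subsample Case/control counts for the exploratory subsample.
#' @param labels Optional override of the structures to fit (canonical
#'   labels); defaults to the experiment's own set.
#' @return Object of class `spiv_grid`: a data frame with one row per
#'   (structure, setting, repeat) plus attributes `comparisons` (list of
#'   `spiv_comparison` per setting/repeat) and `failures`.
#' @export
run_experiment <- function(experiment_id, data, settings = NULL,
                           config = mcmc_config(), repeats = 1L,
                           gam1_grid = c(0.025, 0.1, 0.25, 1, 10),
                           gam2_grid = c(0.1, 0.5, 1, 3, 10, 20),
                           explore_priors = prior_preset("S1"),
                           subsample = c(500L, 500L), labels = NULL) {
  eid <- as.character(experiment_id)
  labels <- labels %||% experiment_structures(eid)
  if (eid == "3-explore") {
    data <- subsample_data(data, subsample[1], subsample[2],
                           seed = config$seed)
    settings <- list()
    for (g1 in gam1_grid) for (g2 in gam2_grid) {
      pr <- explore_priors
      pr$gam1 <- g1; pr$gam2 <- g2
      pr$preset <- sprintf("gam1=%g,gam2=%g", g1, g2)
      settings[[pr$preset]] <- pr
    }
  } else if (is.null(settings)) {
    settings <- if (eid == "3-final")
      lapply(stats::setNames(nm = paste0("S", 1:5)), prior_preset)
    else lapply(stats::setNames(nm = paste0("Setting", 1:3)), prior_preset)
  }
  if (is.null(names(settings)))
    names(settings) <- vapply(settings, function(p)
      p$preset %||% "custom", "")

  rows <- list(); comparisons <- list(); failures <- list()
  for (si in seq_along(settings)) {
    pr <- settings[[si]]
    set_name <- names(settings)[si]
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- config$seed + 104729L * (r - 1L)
      dics <- list()
      for (lab in labels) {
        res <- tryCatch(
          fit_model(data, model_structure(lab), pr, cfg)$dic,
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            list(label = lab, setting = set_name, repeat_index = r,
                 message = conditionMessage(res))
          next
        }
        dics[[lab]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, setting = set_name, repeat_index = r,
          seed = cfg$seed, gam1 = pr$gam1, gam2 = pr$gam2,
          Dbar = res$Dbar, Dhat = res$Dhat, pD = res$pD, DIC = res$DIC)
      }
      if (length(dics) >= 2L) {
        cmb <- utils::combn(names(dics), 2L, simplify = FALSE)
        for (pair in cmb) {
          key <- sprintf("%s|%s|%s_vs_%s", set_name, r, pair[1], pair[2])
          comparisons[[key]] <- comparison_result(dics[[pair[1]]],
                                                  dics[[pair[2]]])
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  attr(grid, "comparisons") <- comparisons
  attr(grid, "failures") <- failures
  attr(grid, "experiment_id") <- eid
  class(grid) <- c("spiv_grid", "data.frame")
  grid
}

#' @export
print.spiv_grid <- function(x, ...) {
  cat(sprintf("Experiment %s grid: %d cells (%d failures)\n",
              attr(x, "experiment_id"), nrow(x),
              length(attr(x, "failures"))))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' Write an experiment grid to TSV (+ JSON comparisons)
#'
#' @param grid A `spiv_grid`.
#' @param path Base output path (without extension).
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comp <- lapply(attr(grid, "comparisons"), unclass)
  jsonlite::write_json(comp, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Plot DIC differences across settings
#'
#' A difference plot in the style of the prior-sensitivity figures: one
#' point per setting, positive values favouring the first (causal) model,
#' with the mean DIC per setting drawn as a line on a secondary axis.
#'
#' @param grid A `spiv_grid` from an experiment comparing two structures.
#' @param labels Pair of structure labels to difference (default the two
#'   present).
#' @export
plot_dic_differences <- function(grid, labels = NULL) {
  df <- as.data.frame(grid)
  labs <- labels %||% unique(df$label)
  if (length(labs) != 2L)
    stop_invalid("need exactly two model labels to plot differences")
  a <- df[df$label == labs[1], ]; b <- df[df$label == labs[2], ]
  key <- paste(a$setting, a$repeat_index)
  m <- match(key, paste(b$setting, b$repeat_index))
  delta <- b$DIC[m] - a$DIC
  graphics::plot(seq_along(delta), delta, type = "h", lwd = 3,
                 xlab = "setting / repeat", ylab = sprintf(
                   "DIC(%s) - DIC(%s)  [positive favours %s]",
                   labs[2], labs[1], labs[1]),
                 main = "DIC differences across prior settings")
  graphics::abline(h = c(-10, 0, 10), lty = c(3, 1, 3))
  invisible(delta)
}
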