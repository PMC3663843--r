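# DIC arithmetic, comparison verdicts and experiment grids.

test_that("DIC decomposition identities hold by construction", {
  d <- dic_from_deviance(c(10, 12, 14), 9)
  expect_equal(d$Dbar, 12)
  expect_equal(d$pD, 3)
  expect_equal(d$DIC, d$Dbar + d$pD)
  expect_equal(d$pD, d$Dbar - d$Dhat)
  # constant deviance series carries no effective parameters
  d0 <- dic_from_deviance(rep(5, 100), 5)
  expect_equal(d0$pD, 0)
  expect_equal(d0$DIC, d0$Dbar)
  expect_error(dic_from_deviance(numeric(0), 1), "empty")
  expect_error(dic_from_deviance(c(1, NA), 1), "finite")
})

test_that("the normal-mean toy model has about one effective parameter", {
  set.seed(61)
  n <- 100
  yobs <- rnorm(n, 2, 1)
  mu_draws <- rnorm(40000, mean(yobs), 1 / sqrt(n))
  dev <- vapply(mu_draws, function(m) sum((yobs - m)^2), 0)
  dhat <- sum((yobs - mean(mu_draws))^2)
  d <- dic_from_deviance(dev, dhat)
  expect_lt(abs(d$pD - 1), 0.2)
})

test_that("DIC differences reproduce the published comparisons", {
  expect_equal(dic_difference(42132, 41911), -221)
  expect_equal(abs(dic_difference(42132, 41911)), 221)
  expect_equal(dic_difference(7, 7), 0)
  expect_equal(dic_difference(-3797, 42132), 45929)
})

test_that("verdicts follow the 5/10-unit thresholds", {
  expect_equal(interpret_difference(221), "decisive")
  expect_equal(interpret_difference(9.7), "substantial")
  expect_equal(interpret_difference(-5.2), "substantial")
  expect_equal(interpret_difference(3.2), "inconclusive")
  expect_equal(interpret_difference(5), "substantial")
  expect_equal(interpret_difference(10), "substantial")
  expect_equal(interpret_difference(10.0001), "decisive")
  expect_equal(interpret_difference(0), "inconclusive")
})

test_that("mean posterior deviances compare in natural log units", {
  expect_equal(compare_dbar(c(10, 12), c(20, 22)), 10)
  expect_equal(compare_dbar(c(3, 4, 5), c(3, 4, 5)), 0)
  a <- dic_from_deviance(c(10, 12), 9)
  expect_equal(compare_dbar(a, a), 0)
})

test_that("mean DIC reproduces the published per-setting summaries", {
  t4 <- reference_dic_table("experiment3_explore")
  row <- t4[t4$gam1 == 0.025, ]
  expect_equal(round(mean_dic(c(row$dic_causal, row$dic_reverse)), 2),
               -2801.12)
  t5 <- reference_dic_table("experiment3_final")
  expect_equal(mean_dic(with(t5[t5$setting == "S1", ],
                             c(dic_causal, dic_reverse))), -7320.5)
  expect_equal(mean_dic(42), 42)
  expect_error(mean_dic(numeric(0)), "empty")
  grid <- data.frame(DIC = c(1, 2, 3, 4), gam1 = c(1, 1, 2, 2))
  expect_equal(unname(mean_dic(grid, "gam1")), c(1.5, 3.5))
  expect_error(mean_dic(grid, "nope"), "group key")
})

test_that("comparison results carry labels, difference and verdict", {
  a <- dic_from_deviance(c(100, 102), 99, label = "M7")
  b <- dic_from_deviance(c(130, 132), 129, label = "M8")
  cr <- comparison_result(a, b)
  expect_equal(cr$model_a, "M7")
  expect_equal(cr$dic_difference, dic_difference(a, b))
  expect_equal(cr$verdict, "decisive")
  expect_equal(cr$dbar_difference, 30)
})

test_that("a single-cell experiment equals a direct model fit", {
  sim <- quick_cohort(n_cases = 80, n_controls = 120, seed = 62)
  dat <- quick_data(sim, genotypes = "pcs")
  cfg <- quick_config(seed = 4)
  grid <- run_experiment("1", dat,
                         settings = list(custom = matched_priors()),
                         config = cfg, labels = "M2")
  expect_equal(nrow(grid), 1L)
  direct <- fit_model(dat, model_structure("M2"), matched_priors(), cfg)$dic
  expect_equal(grid$DIC, direct$DIC)
  expect_equal(grid$Dbar, direct$Dbar)
})

test_that("experiment grids have the published factorial layout", {
  # default exploratory grid: 5 sparsity x 6 confounder-prior values,
  # hence 30 causal-vs-reverse comparisons
  f <- formals(run_experiment)
  expect_length(eval(f$gam1_grid), 5)
  expect_length(eval(f$gam2_grid), 6)
  expect_equal(length(eval(f$gam1_grid)) * length(eval(f$gam2_grid)), 30)
  expect_equal(sparseiv:::experiment_structures("1"), c("M1", "M2", "M3"))
  expect_equal(sparseiv:::experiment_structures("2"), c("M4", "M5", "M6"))
  expect_equal(sparseiv:::experiment_structures("3-final"), c("M7", "M8"))
  expect_error(sparseiv:::experiment_structures("7"), "unknown experiment")
})

test_that("the exploratory phase subsamples and spans its prior grid", {
  sim <- quick_cohort(n_cases = 90, n_controls = 110, seed = 63)
  dat <- quick_data(sim, genotypes = "pcs")
  grid <- run_experiment("3-explore", dat,
                         config = quick_config(n_iterations = 500,
                                               burn_in = 200, seed = 8),
                         gam1_grid = c(0.025, 1), gam2_grid = c(0.5, 3, 10),
                         explore_priors = matched_priors(),
                         subsample = c(40L, 40L))
  expect_equal(nrow(grid), 2 * 3 * 2)  # settings x structures
  expect_setequal(unique(grid$label), c("M7", "M8"))
  comps <- attr(grid, "comparisons")
  expect_equal(length(comps), 6)  # one M7-vs-M8 comparison per setting
  expect_true(all(vapply(comps, function(x)
    inherits(x, "spiv_comparison"), TRUE)))
})

test_that("subsampling keeps the requested case-control counts", {
  sim <- quick_cohort(n_cases = 90, n_controls = 110, seed = 64)
  dat <- quick_data(sim)
  sub <- subsample_data(dat, 30, 40, seed = 2)
  expect_equal(sum(sub$y == 1), 30L)
  expect_equal(sum(sub$y == 0), 40L)
  expect_equal(ncol(sub$g), ncol(dat$g))
  expect_error(subsample_data(dat, 500, 500, seed = 2), "not enough")
})

test_that("grids persist as TSV with JSON comparisons", {
  sim <- quick_cohort(n_cases = 60, n_controls = 80, seed = 65)
  dat <- quick_data(sim, genotypes = "pcs")
  grid <- run_experiment("1", dat,
                         settings = list(custom = matched_priors()),
                         config = quick_config(n_iterations = 500,
                                               burn_in = 200, seed = 5),
                         labels = c("M2", "M3"))
  base <- file.path(tempfile(), "grid")
  dir.create(dirname(base))
  write_grid(grid, base)
  back <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(back), 2L)
  comp <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(length(comp), 1L)
})
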