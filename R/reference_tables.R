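# Published reference DIC tables shipped with the package. These are inputs
# to the comparison arithmetic (the underlying patient-level cohort is not
# public), not outputs of this package's samplers.

#' Reference DIC tables from the original 25-OHD / colorectal cancer analysis
#'
#' Returns the published DIC scores for the three model-comparison
#' experiments: `"experiment1"` (M1/M2/M3 across three precision settings),
#' `"experiment2"` (M4/M5/M6), `"experiment3_explore"` (M7 vs M8 on a
#' 500+500 subsample over a gam1 x gam2 grid) and `"experiment3_final"`
#' (M7 vs M8 on the complete data, settings S1-S5).
#'
#' @param which One of `"experiment1"`, `"experiment2"`,
#'   `"experiment3_explore"`, `"experiment3_final"`.
#' @return A data frame.
#' @export
reference_dic_table <- function(which = c("experiment1", "experiment2",
                                          "experiment3_explore",
                                          "experiment3_final")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("reference_dic_%s.tsv", which),
                      package = "sparseiv", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
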