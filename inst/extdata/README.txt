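Reference DIC scores reported in the original SOCCS 25-hydroxyvitamin D /
colorectal cancer model-selection analysis (n = 2645; the underlying cohort
is not public). These tables are inputs to the package's comparison
arithmetic (dic_difference, interpret_difference, mean_dic); they are not
outputs of this package's samplers.

- reference_dic_experiment1.tsv: full causal with confounders (M1) vs
  causal (M2) and reverse (M3) without confounders, three precision
  settings.
- reference_dic_experiment2.tsv: conventional no-pleiotropy causal (M4) and
  reverse (M5) vs confounder-only (M6).
- reference_dic_experiment3_explore.tsv: full causal (M7) vs reverse (M8)
  on a 500 case / 500 control subsample over a gam1 x gam2 sparsity grid.
- reference_dic_experiment3_final.tsv: M7 vs M8 on the complete data over
  precision settings S1-S5.
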