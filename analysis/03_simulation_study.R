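#!/usr/bin/env Rscript
# Step 3 — estimator calibration on synthetic two-sample GWAS data.
#
# Two seeded experiments with 50-instrument panels sized like the real
# two-sample setting (n_exp 9,639; n_out 121,885):
#   (a) null causal effect, no pleiotropy: IVW type-I error and CI coverage
#       should sit at their nominal levels;
#   (b) theta = 0.2 with directional pleiotropy (alpha ~ N(0.05, 0.02),
#       independent of instrument strength, i.e. InSIDE holds): the Egger
#       intercept absorbs the shared direct effect, so MR-Egger should be
#       far less biased than IVW.

suppressPackageStartupMessages(library(selenomr))
dir.create("results", showWarnings = FALSE)

n_reps <- 500

null_cfg <- simulation_config(n_instruments = 50, theta = 0, seed = 1001)
null_res <- recovery_experiment(null_cfg, n_reps = n_reps, methods = "ivw")
null_res$experiment <- "null_no_pleiotropy"
cat(sprintf(
  "Null model: IVW type-I error %.3f (nominal 0.05), coverage %.3f, bias %.4f\n",
  null_res$rejection_rate, null_res$coverage, null_res$bias
))

dir_cfg <- simulation_config(
  n_instruments = 50, theta = 0.2,
  pleiotropy_mean = 0.05, pleiotropy_sd = 0.02, seed = 2001
)
dir_res <- recovery_experiment(dir_cfg, n_reps = n_reps, methods = c("ivw", "egger"))
dir_res$experiment <- "directional_pleiotropy_inside"
bias <- setNames(dir_res$bias, dir_res$method)
cat(sprintf(
  "Directional pleiotropy (theta = 0.2): |bias| IVW %.3f vs MR-Egger %.3f -> Egger corrects the shared direct effect\n",
  abs(bias[["ivw"]]), abs(bias[["egger"]])
))

out <- rbind(null_res, dir_res)
write.table(out, "results/simulation_summary.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("wrote results/simulation_summary.tsv\n")
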