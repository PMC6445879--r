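#!/usr/bin/env Rscript
# Step 2 — causal-effect estimation and diagnostics.
#
# Runs the full config-driven pipeline on the packaged fixture: harmonizes
# the selenium instrument against the endometrial cancer outcome statistics
# (12,906 cases / 108,979 controls), estimates the causal effect by
# random-effects IVW, MR-Egger and the weighted median, and attaches
# Cochran's Q, the Egger intercept test and I2_GX. Writes the lossless JSON
# report, display tables and a text summary under results/.

suppressPackageStartupMessages(library(selenomr))
dir.create("results", showWarnings = FALSE)

report <- run_analysis(selenium_config(seed = 42))
print(report)

write_report(report, "results/mr_report.json", "json")
write_report(report, "results/tables", "tsv_tables")
write_report(report, "results/mr_summary.txt", "text")

cat(sprintf(
  "\nConclusion: IVW OR %.2f (95%% CI %.2f-%.2f) per selenium Z-score unit -> no evidence of a causal effect on endometrial cancer risk;\nsensitivity estimators agree (weighted median OR %.2f, MR-Egger OR %.2f) and the Egger intercept CI includes 1.\n",
  report$estimates$ivw$odds_ratio,
  report$estimates$ivw$or_ci_low, report$estimates$ivw$or_ci_high,
  report$estimates$weighted_median$odds_ratio,
  report$estimates$mr_egger$odds_ratio
))
cat("wrote results/mr_report.json, results/tables/, results/mr_summary.txt\n")
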