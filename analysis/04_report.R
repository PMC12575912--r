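#!/usr/bin/env Rscript
# Step 4: collate the run into one plain-text report.

out <- "results"
files <- c(recovery = "recovery.csv",
           pet = "pet_metrics.csv",
           icc = "study_icc.csv",
           comparison = "study_comparison.csv",
           univariate = "study_univariate.csv",
           multivariate = "study_multivariate.csv",
           roc_parameters = "study_roc_parameters.csv",
           roc_combinations = "study_roc_combinations.csv")

report_path <- file.path(out, "final_report.txt")
con <- file(report_path, "w")
writeLines(c("Synthetic PET-IVIM-DKI biomarker study: run summary",
             strrep("=", 52), ""), con)
for (nm in names(files)) {
  path <- file.path(out, files[[nm]])
  if (!file.exists(path)) {
    writeLines(sprintf("[%s] missing (%s not found)", nm, path), con)
    next
  }
  writeLines(sprintf("--- %s (%s) ---", nm, files[[nm]]), con)
  tbl <- read.csv(path)
  writeLines(capture.output(print(tbl, digits = 3)), con)
  writeLines("", con)
}
close(con)
cat("collated report ->", report_path, "\n")
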