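#!/usr/bin/env Rscript
# Aggregate the outputs of the previous drivers into one compact report:
# per-cell maxima of |bias| and RMSE from the simulation study, and the
# JE vs DR precision comparison from the case study.
#
# Usage: Rscript analysis/06_report.R

source("analysis/00_utils.R")
out <- results_dir()

study_path <- "results/study/study_report.csv"
if (file.exists(study_path)) {
  report <- read.csv(study_path)
  cell <- aggregate(cbind(max_abs_bias = abs(report$bias),
                          max_rmse = report$rmse),
                    by = list(r_mean = report$r_mean, p_mean = report$p_mean,
                              parameter = report$parameter), FUN = max)
  conv <- aggregate(list(converged = report$converged),
                    by = list(r_mean = report$r_mean, p_mean = report$p_mean,
                              parameter = report$parameter), FUN = all)
  cell$converged <- conv$converged
  write.csv(cell, file.path(out, "study_cell_summary.csv"), row.names = FALSE)
  message("simulation study, per-cell maxima:")
  print(cell[cell$parameter %in% c("S", "F", "r"), ], digits = 3)
} else {
  message("no study report found; run analysis/04_simulation_study.R first")
}

cv_path <- "results/case_study/cv_by_year.csv"
if (file.exists(cv_path)) {
  cv <- read.csv(cv_path)
  cvmax <- aggregate(list(max_cv = cv$cv),
                     by = list(model = cv$model, parameter = cv$parameter),
                     FUN = max)
  write.csv(cvmax, file.path(out, "case_study_cv_summary.csv"),
            row.names = FALSE)
  message("case study, maximum per-year CV by model:")
  print(cvmax, digits = 3)
} else {
  message("no case-study output found; run analysis/05_case_study.R first")
}
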