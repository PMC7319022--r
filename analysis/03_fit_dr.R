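#!/usr/bin/env Rscript
# Summarize one simulated data set into a dead-recovery m-array, fit the
# Seber DR model, and write the m-array, posterior draws and summary.
#
# Usage: Rscript analysis/03_fit_dr.R [--seed 1] [--data results/sim_data/histories_r19_p90.csv] [--preset fast]

source("analysis/00_utils.R")
flags <- parse_flags(list(seed = 1L, preset = "fast",
                          data = "results/sim_data/histories_r19_p90.csv"))
out <- results_dir("fit_dr")

h <- read_histories(flags$data)
ma <- build_marray(h)
write_marray(ma, file.path(out, "marray.csv"))
message("m-array: ", sum(ma$releases), " releases, ",
        sum(ma$recoveries), " recoveries")

settings <- mcmc_preset(flags$preset, seed = flags$seed)
fit <- fit_until_converged(function(s) fit_dr(ma, prior_spec(), s), settings)
print(fit)

write_draws(fit, file.path(out, "draws.csv"))
write_fit_summary(fit, file.path(out, "summary.csv"))
write_manifest(out, flags, list(rhat = rhat_summary(fit)))
message("wrote m-array, draws and summary to ", out)
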