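#!/usr/bin/env Rscript
# Stability of the 253 K validation over ten seeds of the mixed-data
# pipeline: per-seed selected hyperparameters and the maximum absolute
# relative error over the 50-cell validation grid, against the +/-10%
# acceptance band.

suppressPackageStartupMessages(library(frozencarp))
dir.create("results", showWarnings = FALSE)

rows <- lapply(1:10, function(s) {
  res <- run_pipeline(run_config(source = list(type = "mixed"), seed = s))
  worst <- res$report$table[which.max(abs(res$report$table$relative_error)), ]
  data.frame(seed = s, neurons = res$scan$best$neurons,
             spread = res$scan$best$spread,
             max_abs_rel_error = res$report$max_abs_relative_error,
             worst_indicator = worst$indicator,
             worst_week = worst$time_weeks,
             within_10pct = res$report$pass)
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE, digits = 4)
cat(sprintf("\n%d of 10 seeds stay within the +/-10%% band; 9-of-10 level = %.2f%%\n",
            sum(tab$within_10pct), sort(tab$max_abs_rel_error)[9]))
cat("The binding cells are validation weeks whose 253 K design row fell into\n",
    "the held-out splits: their published means sit off any smooth curve by\n",
    "more than the band, so the mixed-data pipeline does not generally meet\n",
    "the +/-10% criterion that in-sample validation attains.\n", sep = "")
write.csv(tab, "results/validation_multiseed.csv", row.names = FALSE)
cat("Wrote results/validation_multiseed.csv\n")
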