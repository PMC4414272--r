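#!/usr/bin/env Rscript
# Single-point rate arithmetic for on-column tag cleavage: given the
# completeness observed at 15 min, what does the single-exponential model
# predict for 30 min and for full release?

suppressPackageStartupMessages(library(ublcleave))
dir.create("results", showWarnings = FALSE)

cases <- data.frame(fusion = c("xLC3B-MBP", "xGATE16-MBP"),
                    f15 = c(0.50, 0.80))
cases$k_app <- sapply(cases$f15, function(f) kapp_single_point(f, 15)$k_app)
cases$pred30_pct <- 100 * fraction_cleaved(cases$k_app, 30)
cases$pred60_pct <- 100 * fraction_cleaved(cases$k_app, 60)
cases$t95_min <- -log(0.05) / cases$k_app

write.csv(cases, "results/oncolumn_predictions.csv", row.names = FALSE)
print(cases, digits = 3)
cat("\nThe slower fusion (50% at 15 min) is predicted at exactly 75% by 30 min;\n")
cat("the faster one (80% at 15 min) at 96%, i.e. clearly above 90%. Both are\n")
cat("predicted essentially complete within the hour, matching how on-column\n")
cat("release is scheduled in practice.\n")
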