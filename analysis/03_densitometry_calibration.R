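#!/usr/bin/env Rscript
# Calibrate band intensities against a synthetic mixed cleavage standard
# and measure how well lane fractions are recovered under realistic
# per-band densitometry noise (log-normal, CV 0.10).

suppressPackageStartupMessages(library(ublcleave))
dir.create("results", showWarnings = FALSE)

r_true <- 0.6  # CCP band stains weaker per mole than the full-length band

std <- gen_standards(response_factor = r_true, noise = noise_model(0, 0, 0),
                     seed = 1)
curve <- build_standard_curve(std)
cat(sprintf("Planted response factor %.3f; calibrated r = %.4f (%.2f%% off)\n",
            r_true, curve$r, 100 * abs(curve$r - r_true) / r_true))

set.seed(1)
f_true <- rep(default_standard_ladder(), length.out = 500)
bands <- ublcleave:::bands_from_fraction(f_true, r_true,
                                         noise_model(intensity_cv = 0.10))
f_hat <- fraction_from_bands(bands$intensity_fl, bands$intensity_ccp, curve)
lanes <- data.frame(f_true = f_true, f_hat = f_hat,
                    abs_err = abs(f_hat - f_true))
write.csv(lanes, "results/densitometry_lanes.csv", row.names = FALSE)

cat(sprintf("500 noisy ladder lanes: %.1f%% within +/-0.05 of truth (median |err| %.3f)\n",
            100 * mean(lanes$abs_err <= 0.05), median(lanes$abs_err)))
cat("Mid-range lanes (f ~ 0.5) dominate the residual error, as expected:\n")
print(aggregate(abs_err ~ f_true, lanes, median), digits = 2)
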