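#!/usr/bin/env Rscript
# Stage 1 — synthetic study generation.
#
# Builds the default multi-subject flight-training study: 6 subjects, 4 test
# sessions (T1-T4) x 4 difficulty scenarios (L0-L3) x 2 trials, 24-channel
# montage. Ground-truth theta-band coupling follows the default effect map:
# flat density in the early sessions, density decreasing with difficulty in
# the post-schema sessions (T3, T4). Writes the trial label table and the
# effect map; later stages regenerate any recording deterministically from
# the same seed.

library(thetanet)

dir.create("results", showWarnings = FALSE)
seed <- 2026L

design <- study_design(
  n_subjects = 6, trials_per_scenario = 2,
  n_channels = 24, sample_rate = 250, duration = 32, rest_duration = 30,
  seed = seed)

cat("Study design:", design$n_subjects, "subjects,",
    length(design$tests), "tests x", length(design$scenarios), "scenarios x",
    design$trials_per_scenario, "trials\n")
cat("Trials per test session:",
    length(design$scenarios) * design$trials_per_scenario, "\n")

study <- generate_study(design, verbose = TRUE)

cat("Generated", length(study$task), "task recordings and",
    length(study$rest), "rest recordings\n")
cat("Subject alpha peaks (Hz):",
    paste(sprintf("%.2f", study$alpha_peaks), collapse = ", "), "\n")

write.csv(study$labels, "results/study_labels.csv", row.names = FALSE)
write.csv(design$effect_map, "results/effect_map.csv", row.names = FALSE)
write.csv(data.frame(subject = sprintf("S%02d", seq_along(study$alpha_peaks)),
                     alpha_peak = study$alpha_peaks),
          "results/alpha_peaks_true.csv", row.names = FALSE)
cat("Wrote results/study_labels.csv, results/effect_map.csv,",
    "results/alpha_peaks_true.csv\n")
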