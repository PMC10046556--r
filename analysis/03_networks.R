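#!/usr/bin/env Rscript
# Stage 3 — connectivity and network topology (the full pipeline).
#
# Runs simulate -> preprocess -> theta-band wPLI -> median-threshold graphs
# -> efficiency / clustering / small-worldness for the stage-1 study, with
# 50 degree-preserving surrogates per graph for the gamma/lambda/sigma
# normalizers. All tables land in results/run/. Takes a few minutes.

library(thetanet)

cfg <- default_config(
  synth = list(n_subjects = 6, trials_per_scenario = 2, n_channels = 24,
               sample_rate = 250, duration = 32, rest_duration = 30),
  preprocess = list(min_segment_s = 30),
  graph = list(n_surrogates = 50),
  stats = list(exclude_scenarios = "L3", alpha = 0.05),
  seed = 2026L)

res <- run_pipeline(cfg, out_dir = "results/run", verbose = TRUE)

m <- res$metrics
agg <- aggregate(cbind(E_global, E_local, sigma) ~ test + scenario, m, mean)
cat("\nCondition means (over subjects):\n")
print(agg[order(agg$test, agg$scenario), ], digits = 3)

post <- subset(m, test %in% c("T3", "T4") & scenario != "L3")
by_sc <- aggregate(E_global ~ scenario, post, mean)
cat("\nPost-schema sessions: mean E_global by scenario:\n")
print(by_sc, digits = 3)
if (all(diff(by_sc$E_global) < 0)) {
  cat("-> global efficiency decreases with task difficulty after schema formation\n")
}
cat(sprintf("\nShare of small-world condition networks (sigma > 1): %.2f\n",
            mean(m$sigma > 1, na.rm = TRUE)))
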