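#!/usr/bin/env Rscript
# Stage 5 — run summary and topographic rendering.
#
# Summarizes the stage-3 run (condition-mean table, ANOVA recap) and draws
# the per-channel local-efficiency scalp maps for the post-schema session
# T4, one panel per difficulty scenario.

library(thetanet)

s <- summarize_run("results/run")
cat("Condition means:\n")
print(s$condition_means, digits = 3, row.names = FALSE)

nodes <- read.csv("results/run/metrics_nodes.csv")
pdf("results/elocal_scalp_T4.pdf", width = 9, height = 3.4)
par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
for (sc in c("L0", "L1", "L2")) {
  sub <- subset(nodes, test == "T4" & scenario == sc)
  vals <- tapply(sub$E_local, sub$channel, mean)
  plot_scalp(vals, main = sprintf("T4 %s: local efficiency", sc))
}
dev.off()
cat("Wrote results/elocal_scalp_T4.pdf\n")

if (!is.null(s$anova)) {
  sig <- subset(s$anova, p < 0.05)
  cat("\nEffects with p < 0.05 (G-G corrected):\n")
  print(sig[, c("metric", "effect", "F", "p", "eta_g2")], digits = 3,
        row.names = FALSE)
}
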