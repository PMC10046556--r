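#!/usr/bin/env Rscript
# Stage 4 — repeated-measures statistics.
#
# Reads the stage-3 network metrics and runs the 3-scenario x 4-test fully
# within-subject ANOVA (L3 excluded) with unconditional Greenhouse-Geisser
# correction and generalized eta squared, per metric, followed by
# Bonferroni-corrected paired post hocs on the scenario means within the
# post-schema sessions.

library(thetanet)

metrics <- read.csv("results/run/metrics.csv")
dat <- subset(metrics, scenario != "L3")

anova_rows <- list()
for (metric in c("E_global", "E_local", "C", "sigma")) {
  d <- dat[, c("subject", "test", "scenario", metric)]
  names(d)[4] <- "value"
  res <- rm_anova_2way(d)
  res$metric <- metric
  anova_rows[[metric]] <- res
  cat(sprintf("\n%s:\n", metric))
  print(res[, c("effect", "df1_corr", "df2_corr", "epsilon", "F", "p", "eta_g2")],
        digits = 3, row.names = FALSE)
}
anova_tab <- do.call(rbind, anova_rows)
write.csv(anova_tab, "results/anova_summary.csv", row.names = FALSE)

# scenario contrasts within the post-schema sessions
cmp <- list(list(c("T4", "L0"), c("T4", "L1")),
            list(c("T4", "L1"), c("T4", "L2")),
            list(c("T4", "L0"), c("T4", "L2")),
            list(c("T3", "L0"), c("T3", "L2")))
d_eg <- dat[, c("subject", "test", "scenario", "E_global")]
names(d_eg)[4] <- "value"
ph <- posthoc_paired(d_eg, cmp)
cat("\nPost hoc paired t-tests on E_global (Bonferroni x", length(cmp), "):\n")
print(ph, digits = 3, row.names = FALSE)
write.csv(ph, "results/posthoc_eglobal.csv", row.names = FALSE)
cat("\nWrote results/anova_summary.csv, results/posthoc_eglobal.csv\n")
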