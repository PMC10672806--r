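#!/usr/bin/env Rscript
# Step 3: group comparisons.
#
# Pairwise Mann-Whitney tables (Bonferroni-corrected) for every per-cell
# metric, a Kolmogorov-Smirnov table for the patrolled-volume distribution,
# the per-cell proportion of turning angles below 90 degrees, intra- and
# inter-tissue one-way ANOVA of cell speed, and the greedy outlier-frame
# reduction with the ANOVA rerun on the reduced set.

suppressPackageStartupMessages(library(motility3d))

out <- "results"
cm <- read.csv(file.path(out, "cell_metrics.csv"), stringsAsFactors = FALSE)
steps <- read.csv(file.path(out, "step_table.csv"), stringsAsFactors = FALSE)

by_tissue <- function(df, col) split(df[[col]], df$tissue)
metrics <- c("cell_speed", "displacement_speed", "meandering_ratio",
             "msd_slope", "confined_ratio", "confined_time", "volume_rate")
for (mcol in metrics) {
  pw <- pairwise_ranksum(by_tissue(cm, mcol))
  write.csv(pw$p, file.path(out, paste0("pairwise_", mcol, ".csv")))
}
fb <- fraction_below(steps, threshold = 90)
write.csv(fb, file.path(out, "angle_fraction_below.csv"), row.names = FALSE)
pw_fb <- pairwise_ranksum(by_tissue(fb, "frac_below"))
write.csv(pw_fb$p, file.path(out, "pairwise_angle_frac_below90.csv"))
ks <- pairwise_ks(by_tissue(cm, "volume_rate"))
write.csv(ks$p, file.path(out, "pairwise_volume_rate_ks.csv"))

cat("Cell-speed pairwise Mann-Whitney (Bonferroni-corrected):\n")
print(pairwise_ranksum(by_tissue(cm, "cell_speed")))
cat("\nVolume-rate KS (distribution shape):\n")
print(ks)

av <- intra_inter_anova(cm, "cell_speed")
cat("\nIntra-tissue ANOVA p (frames within tissue):\n")
for (ti in names(av$intra)) {
  cat(sprintf("  %-10s p = %.3g\n", ti, av$intra[[ti]]$p))
}
cat(sprintf("Inter-tissue ANOVA: F = %.1f, p = %.3g\n",
            av$inter$F, av$inter$p))

red <- reduce_outlier_frames(cm, "cell_speed",
                             p_threshold = 1e-4, max_frac_removed = 0.55)
cat("\nOutlier-frame reduction (greedy p-maximizing removal):\n")
rows <- lapply(names(red$report), function(ti) {
  r <- red$report[[ti]]
  cat(sprintf("  %-10s removed %2d frame(s); p %.3g -> %.3g\n",
              ti, length(r$removed), r$p_initial, r$p_final))
  data.frame(tissue = ti, removed = paste(r$removed, collapse = ";"),
             p_initial = r$p_initial, p_final = r$p_final,
             retained_frames = length(r$retained_frames),
             retained_cells = r$retained_cells, reached = r$reached)
})
write.csv(do.call(rbind, rows), file.path(out, "reduction_report.csv"),
          row.names = FALSE)

av2 <- intra_inter_anova(red$metrics, "cell_speed")
cat(sprintf("\nInter-tissue ANOVA on the reduced set: F = %.1f, p = %.3g\n",
            av2$inter$F, av2$inter$p))
cat("Removing heterogeneous frames reduces within-tissue variance, so the",
    "between-tissue contrast stands out more clearly.\n")
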