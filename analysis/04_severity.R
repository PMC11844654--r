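#!/usr/bin/env Rscript
# Stage 4: multidimensional behavioral severity.
#
# Assembles the mice-by-measures cohort table from stage 1's battery and
# the per-mouse call counts of the simulated courtship and distress tests,
# then runs the severity analysis (z-score -> PCA -> k-means with k = 2 ->
# genotype accuracy and centroid distance) for the three measure sets:
# battery alone, battery + distress counts, battery + all call counts.

library(usvseverity)

SEED <- 20260926  # same cohort as stage 1
courtship <- generate_cohort(generator_config("courtship", seed = SEED))
distress <- generate_cohort(generator_config("distress", seed = SEED + 1))
dir.create("results", showWarnings = FALSE)

tab <- courtship$battery
count_of <- function(events, cat, mice) {
  sapply(mice, function(m) {
    sum(events$mouse_id == m & events$category == cat)
  })
}
tab$distress_usv <- count_of(distress$events, "USV", tab$mouse_id)
tab$distress_squeak <- count_of(distress$events, "squeak", tab$mouse_id)
tab$distress_ranging <- count_of(distress$events, "ranging", tab$mouse_id)
tab$courtship_usv <- count_of(courtship$events, "USV", tab$mouse_id)
tab$courtship_sv <- count_of(courtship$events, "SV", tab$mouse_id)
write_cohort_table(tab, "results/severity_cohort.csv")

summary_rows <- list()
for (set_name in c("battery7", "battery_distress9", "battery_usv12")) {
  res <- severity_analysis(tab, measure_set(set_name), seed = SEED)
  cat(sprintf("\n== %s ==\n", set_name))
  print(res)
  write_json_report(res, file.path("results",
                                   paste0("severity_", set_name, ".json")))
  scores <- data.frame(mouse_id = res$mouse_id, genotype = res$genotypes,
                       cluster = res$clusters,
                       pc1 = res$scores[, 1], pc2 = res$scores[, 2])
  write.csv(scores, file.path("results",
                              paste0("severity_", set_name, "_scores.csv")),
            row.names = FALSE)
  summary_rows[[set_name]] <- data.frame(
    measure_set = set_name, n_measures = length(res$measures),
    accuracy_pct = 100 * res$accuracy,
    centroid_distance = res$centroid_distance,
    pc1_variance_pct = res$explained_variance[1])
}

summary_tab <- do.call(rbind, summary_rows)
write.csv(summary_tab, "results/severity_summary.csv", row.names = FALSE)
cat("\n")
print(summary_tab, row.names = FALSE)
cat("\nseverity reports -> results/severity_*.json, results/severity_summary.csv\n")
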