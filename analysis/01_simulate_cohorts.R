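#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates one longitudinal cohort of 13 WT + 13 AS (Ube3a-deficient) male
# mice that performs a 20-min courtship test, a 60-s distress test, and the
# behavior battery. Ground-truth call tables and the battery table are
# written under results/ for the downstream stages.

library(usvseverity)

SEED <- 20260926
dir.create("results", showWarnings = FALSE)

courtship_cfg <- generator_config("courtship", seed = SEED)
distress_cfg <- generator_config("distress", seed = SEED + 1)

courtship <- generate_cohort(courtship_cfg)
distress <- generate_cohort(distress_cfg)

for (set in list(list(name = "courtship", coh = courtship),
                 list(name = "distress", coh = distress))) {
  ev <- set$coh$events
  ev$call_id <- ev$event_id
  ev$test_type <- set$name
  ev$true_category <- ev$category
  write_call_table(ev, file.path("results", paste0(set$name, "_truth_calls.csv")),
                   extra_columns = c("true_category", "true_inflections"))
  cat(sprintf("%s: %d calls from %d mice (WT %d, AS %d)\n", set$name,
              nrow(ev), length(unique(ev$mouse_id)),
              sum(ev$genotype == "WT"), sum(ev$genotype == "AS")))
}

write_cohort_table(courtship$battery, "results/battery.csv")
cat(sprintf("battery: %d mice x %d measures -> results/battery.csv\n",
            nrow(courtship$battery), ncol(courtship$battery) - 2L))

# provenance: configuration and seeds beside the outputs
write_json_report(list(
  seed = SEED,
  courtship = courtship_cfg[c("test_type", "n_per_genotype", "call_rate_mean",
                              "call_rate_dispersion", "session_s", "seed")],
  distress = distress_cfg[c("test_type", "n_per_genotype", "call_rate_mean",
                            "call_rate_dispersion", "session_s", "seed")]
), "results/simulation_metadata.json")
cat("metadata -> results/simulation_metadata.json\n")
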