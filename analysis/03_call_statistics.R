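#!/usr/bin/env Rscript
# Stage 3: call-level taxonomies, per-mouse aggregation, group statistics.
#
# Annotates the ground-truth call tables from stage 1, averages call
# properties mouse-by-mouse, computes pooled per-call category
# proportions, and runs the group comparisons: pooled-variance unpaired
# t-tests on per-mouse quantities and Fisher exact tests on pooled
# call-type proportions.

library(usvseverity)

SEED <- 20260926  # same cohort as stage 1
courtship <- generate_cohort(generator_config("courtship", seed = SEED))
distress <- generate_cohort(generator_config("distress", seed = SEED + 1))
dir.create("results", showWarnings = FALSE)

report <- list()
for (set in list(list(name = "courtship", coh = courtship),
                 list(name = "distress", coh = distress))) {
  tt <- set$name
  ann <- annotate_calls(set$coh$events, band_scheme(tt))
  mice <- set$coh$battery$mouse_id
  summ <- summarize_cohort(ann, tt, mice = mice)
  summ$genotype <- set$coh$battery$genotype[match(summ$mouse_id, mice)]
  write.csv(summ, file.path("results", paste0(tt, "_mouse_summary.csv")),
            row.names = FALSE)

  wt <- summ[summ$genotype == "WT", ]
  as_ <- summ[summ$genotype == "AS", ]
  tests <- list(total_calls = unpaired_t_test(wt$total_calls, as_$total_calls),
                n_usv = unpaired_t_test(wt$n_usv, as_$n_usv))
  if (tt == "courtship") {
    tests$n_sv <- unpaired_t_test(wt$n_sv, as_$n_sv)
    tests$usv_f_mean <- unpaired_t_test(wt$usv_f_mean, as_$usv_f_mean)
    tests$usv_f_range <- unpaired_t_test(wt$usv_f_range, as_$usv_f_range)
    tests$mean_abs_slope <- unpaired_t_test(wt$mean_abs_slope,
                                            as_$mean_abs_slope)
    tests$slope_ratio <- unpaired_t_test(wt$slope_ratio, as_$slope_ratio)
  } else {
    tests$n_squeak <- unpaired_t_test(wt$n_squeak, as_$n_squeak)
    tests$n_ranging <- unpaired_t_test(wt$n_ranging, as_$n_ranging)
  }

  pooled <- pooled_call_proportions(ann)
  fisher <- if (tt == "courtship") {
    fisher_exact_2x2(pooled$counts[c("WT", "AS"), c("USV", "SV")])
  } else {
    # squeaks vs everything else, the low-frequency shift
    counts <- cbind(squeak = pooled$counts[, "squeak"],
                    other = rowSums(pooled$counts[, c("USV", "ranging")]))
    fisher_exact_2x2(counts[c("WT", "AS"), ])
  }

  # complexity on a per-call level (courtship USVs)
  if (tt == "courtship") {
    usv <- ann[ann$category == "USV", ]
    comp <- table(usv$genotype, usv$complexity)[c("WT", "AS"),
                                                c("simple", "complex")]
    report$courtship_complexity <- list(
      counts = apply(comp, 1L, as.list),
      fisher_p = fisher_exact_2x2(comp))
  }

  report[[tt]] <- list(
    n_calls = nrow(ann),
    pooled_proportions = apply(pooled$proportions, 1L, as.list),
    fisher_p_category_mix = fisher,
    t_tests = tests)

  cat(sprintf("\n== %s ==\n", tt))
  cat(sprintf("calls: WT %d, AS %d\n", sum(ann$genotype == "WT"),
              sum(ann$genotype == "AS")))
  for (nm in names(tests)) {
    cat(sprintf("  %-15s t(%d) = %6.2f, p = %.3g\n", nm, tests[[nm]]$df,
                tests[[nm]]$t, tests[[nm]]$p))
  }
  cat(sprintf("  category mix Fisher p = %.3g\n", fisher))
}

write_json_report(report, "results/call_statistics.json")
cat("\nstatistics report -> results/call_statistics.json\n")
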