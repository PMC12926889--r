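#!/usr/bin/env Rscript
# Stage 5: cost-effectiveness acceptability curves by net-benefit
# regression over the willingness-to-pay grids (EUR 0-160,000/QALY and
# EUR 0-200/DFD), for the main scenarios and the four explorative
# subpopulation families.

library(trialcea)

out <- "results/run"
tdm <- read_trial_csv(file.path(out, "data"))
fx <- read_fixtures(file.path(out, "fixtures"))
tab <- analysis_table(tdm, fx$value_set)
stack <- read_stack_csv(file.path(out, "imputations"))

report_range <- function(curve, label) {
  for (tm in unique(curve$term)) {
    pr <- curve$probability[curve$term == tm]
    cat(sprintf("  %-28s %-20s %2.0f%% to %2.0f%%\n", label, tm,
                100 * min(pr), 100 * max(pr)))
  }
}

cat("CEAC probability ranges over the WTP grid:\n")
for (sc in c("base_societal", "payer", "complete_case", "dfd")) {
  res <- run_scenario(stack, sc, fx, tab_missing = tab)
  write.csv(res$ceac, file.path(out, paste0("ceac_", sc, ".csv")),
            row.names = FALSE)
  report_range(res$ceac, sc)
}

for (sg in c("gender", "depression_history", "addiction",
             "mini_depression_T1")) {
  res <- suppressWarnings(
    run_subgroup(stack, sg, "base_societal", fx))
  for (lv in names(res)) {
    write.csv(res[[lv]]$ceac,
              file.path(out, sprintf("ceac_subgroup_%s_%s.csv", sg, lv)),
              row.names = FALSE)
    write.csv(res[[lv]]$estimates,
              file.path(out,
                        sprintf("estimates_subgroup_%s_%s.csv", sg, lv)),
              row.names = FALSE)
    report_range(res[[lv]]$ceac, sprintf("%s=%s", sg, lv))
  }
}
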