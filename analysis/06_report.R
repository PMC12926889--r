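#!/usr/bin/env Rscript
# Stage 6: assemble the Markdown report from the stage outputs.

library(trialcea)

out <- "results/run"

lines <- c("# Synthetic-trial health-economic evaluation", "",
           "All numbers below are computed from the synthetic trial with",
           "null intervention effects; they illustrate the pipeline, not",
           "the original trial data.", "")

bal <- read.csv(file.path(out, "baseline_balance.csv"))
lines <- c(lines, "## Baseline balance (p vs no feedback)", "",
           "| variable | model | GP feedback | GP + patient feedback |",
           "|---|---|---|---|",
           sprintf("| %s | %s | %.3f | %.3f |", bal$variable, bal$model,
                   bal$p_gp, bal$p_gp_plus_patient), "")

for (sc in c("base_societal", "payer", "complete_case", "dfd")) {
  est <- read.csv(file.path(out, paste0("estimates_", sc, ".csv")))
  ic <- read.csv(file.path(out, paste0("icer_", sc, ".csv")))
  cc <- read.csv(file.path(out, paste0("ceac_", sc, ".csv")))
  rng <- aggregate(probability ~ term, cc, function(p)
    sprintf("%.0f%%-%.0f%%", 100 * min(p), 100 * max(p)))
  lines <- c(lines, sprintf("## Scenario: %s", sc), "",
             "| outcome | comparison | estimate | 95% CI | p |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %.4f | [%.4f; %.4f] | %.3f |",
                     est$outcome, est$term, est$estimate, est$ci_low,
                     est$ci_high, est$p), "",
             "Unadjusted ICERs:", "",
             sprintf("- %s: dC = %.0f, dE = %.4f, ICER = %s (%s)",
                     ic$comparison, ic$delta_cost, ic$delta_effect,
                     ifelse(is.na(ic$icer), "undefined",
                            sprintf("%.0f", ic$icer)), ic$quadrant), "",
             "CEAC ranges:", "",
             sprintf("- %s: %s", rng$term, rng$probability), "")
}

sub_files <- list.files(out, pattern = "^ceac_subgroup_")
if (length(sub_files)) {
  lines <- c(lines, "## Subpopulation CEAC ranges (base case)", "")
  for (f in sub_files) {
    cc <- read.csv(file.path(out, f))
    lab <- sub("^ceac_subgroup_", "", sub("\\.csv$", "", f))
    rng <- aggregate(probability ~ term, cc, function(p)
      sprintf("%.0f%%-%.0f%%", 100 * min(p), 100 * max(p)))
    lines <- c(lines, sprintf("- %s / %s: %s", lab, rng$term,
                              rng$probability))
  }
}

writeLines(lines, file.path(out, "summary.md"))
cat("wrote", file.path(out, "summary.md"), "\n")
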