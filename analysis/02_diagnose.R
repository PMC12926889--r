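#!/usr/bin/env Rscript
# Stage 2: missingness diagnostics (are the drivers of missingness the
# observed baseline variables, supporting MAR?) and baseline balance
# between the randomised arms.

library(trialcea)

out <- "results/run"
tdm <- read_trial_csv(file.path(out, "data"))
fx <- read_fixtures(file.path(out, "fixtures"))
tab <- analysis_table(tdm, fx$value_set)

diag <- missingness_diagnostics(tab)
write.csv(data.frame(variable = names(diag$fractions),
                     missing_fraction = diag$fractions),
          file.path(out, "missingness_fractions.csv"), row.names = FALSE)
write.csv(diag$regressions, file.path(out, "missingness_regressions.csv"),
          row.names = FALSE)

cat("missingness of costs/QALYs is predicted by (odds ratios):\n")
print(diag$regressions[, c("outcome", "predictor", "odds_ratio", "p")],
      digits = 3)

bal <- baseline_balance(tab)
write.csv(bal, file.path(out, "baseline_balance.csv"), row.names = FALSE)
nsig <- sum(c(bal$p_gp, bal$p_gp_plus_patient) < 0.05, na.rm = TRUE)
cat(sprintf("\nbaseline balance: %d of %d arm contrasts significant at 5%%\n",
            nsig, 2L * nrow(bal)))
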