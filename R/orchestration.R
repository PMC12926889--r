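#' Run the full health-economic evaluation end to end
#'
#' Executes the complete pipeline: generate the synthetic trial, impose
#' missingness, compute missingness diagnostics and baseline balance,
#' impute (M completed datasets), derive outcomes and costs, fit the
#' adjusted models, and produce ICERs and CEACs for the base case, the
#' payer and complete-case sensitivity scenarios, the depression-free-day
#' scenario and the four subpopulation families. All stage outputs are
#' written as CSV under `out_dir` together with a YAML run manifest
#' (config hash, seeds, file digests); rerunning with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config a [trial_config()] (its `seed` drives every stage).
#' @param out_dir report directory.
#' @param M number of imputations.
#' @param iterations chained-equation sweeps.
#' @param subgroups character vector of subgroup families to run (default
#'   all four); `NULL` skips subpopulation analyses.
#' @param fixtures costing fixtures.
#' @return invisible list with the in-memory results (`scenarios`,
#'   `subgroups`, `balance`, `missingness`, `manifest_path`).
#' @export
run_all <- function(config = trial_config(), out_dir, M = 20L,
                    iterations = 10L,
                    subgroups = c("gender", "depression_history",
                                  "addiction", "mini_depression_T1"),
                    fixtures = make_fixtures()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  # stage 1: generation + missingness
  td <- generate_trial(config)
  tdm <- apply_missingness(td, config)
  write_trial_csv(tdm, file.path(out_dir, "data"))
  write_fixtures(fixtures, file.path(out_dir, "fixtures"))
  tab <- analysis_table(tdm, fixtures$value_set)

  # stage 2: diagnostics
  diag <- missingness_diagnostics(tab)
  utils::write.csv(data.frame(variable = names(diag$fractions),
                              missing_fraction = diag$fractions),
                   file.path(out_dir, "missingness_fractions.csv"),
                   row.names = FALSE)
  if (nrow(diag$regressions))
    utils::write.csv(diag$regressions,
                     file.path(out_dir, "missingness_regressions.csv"),
                     row.names = FALSE)
  bal <- baseline_balance(tab)
  utils::write.csv(bal, file.path(out_dir, "baseline_balance.csv"),
                   row.names = FALSE)

  # stage 3: imputation
  stack <- mice_impute(tab, M = M, iterations = iterations,
                       seed = config$seed)
  write_stack_csv(stack, file.path(out_dir, "imputations"))

  # stage 4: scenarios
  scen_names <- c("base_societal", "payer", "complete_case", "dfd")
  scenarios <- list()
  for (sc in scen_names) {
    res <- tryCatch(
      run_scenario(stack, sc, fixtures, tab_missing = tab),
      error = function(e) {
        stop("stage 'scenario:", sc, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    scenarios[[sc]] <- res
    utils::write.csv(res$estimates,
                     file.path(out_dir, paste0("estimates_", sc, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$icers,
                     file.path(out_dir, paste0("icer_", sc, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$ceac,
                     file.path(out_dir, paste0("ceac_", sc, ".csv")),
                     row.names = FALSE)
  }

  # stage 5: subpopulations (base-case scenario, reduced covariates)
  subgroup_results <- list()
  for (sg in subgroups %||% character()) {
    res <- withCallingHandlers(
      run_subgroup(stack, sg, "base_societal", fixtures),
      warning = function(w) {
        note("subgroup %s: %s", sg, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    subgroup_results[[sg]] <- res
    for (lv in names(res)) {
      utils::write.csv(
        res[[lv]]$ceac,
        file.path(out_dir, sprintf("ceac_subgroup_%s_%s.csv", sg, lv)),
        row.names = FALSE)
      utils::write.csv(
        res[[lv]]$estimates,
        file.path(out_dir, sprintf("estimates_subgroup_%s_%s.csv", sg, lv)),
        row.names = FALSE)
    }
  }

  manifest <- run_manifest(config, out_dir, M, iterations, warnings_log)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(scenarios = scenarios, subgroups = subgroup_results,
                 balance = bal, missingness = diag,
                 manifest_path = file.path(out_dir, "manifest.yaml")))
}

run_manifest <- function(config, out_dir, M, iterations, warnings_log) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.yaml"))
  digests <- vapply(files, function(f)
    digest::digest(file.path(out_dir, f), file = TRUE, algo = "md5"),
    character(1L))
  list(
    package_version = as.character(utils::packageVersion("trialcea")),
    config_hash = digest::digest(unclass(config), algo = "md5"),
    master_seed = config$seed,
    stage_seeds = list(generate = stage_seed(config$seed, "generate"),
                       missing = stage_seed(config$seed, "missing"),
                       impute = stage_seed(config$seed, "impute")),
    M = as.integer(M), iterations = as.integer(iterations),
    file_digests = as.list(digests),
    warnings = as.list(warnings_log))
}

#' Summarise a completed run directory
#'
#' Assembles a human-readable Markdown summary from the CSV outputs of
#' [run_all()]: baseline balance, adjusted estimates, ICER quadrants and
#' the CEAC probability range per scenario and comparison.
#'
#' @param out_dir directory written by [run_all()].
#' @param path output Markdown file (default `summary.md` inside
#'   `out_dir`).
#' @return path to the Markdown file.
#' @export
summarise_run <- function(out_dir, path = file.path(out_dir, "summary.md")) {
  need <- c("manifest.yaml", "baseline_balance.csv",
            "estimates_base_societal.csv", "icer_base_societal.csv",
            "ceac_base_societal.csv")
  for (f in need)
    if (!file.exists(file.path(out_dir, f)))
      stop("missing stage output: ", f)
  manifest <- yaml::read_yaml(file.path(out_dir, "manifest.yaml"))
  lines <- c("# Health-economic evaluation summary", "",
             sprintf("Master seed: %d; M = %d imputations.",
                     manifest$master_seed, manifest$M), "")

  bal <- utils::read.csv(file.path(out_dir, "baseline_balance.csv"))
  lines <- c(lines, "## Baseline balance (p-values vs no feedback)", "",
             "| variable | model | GP feedback | GP+patient feedback |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %.3f | %.3f |", bal$variable, bal$model,
                     bal$p_gp, bal$p_gp_plus_patient), "")

  scens <- sub("^estimates_", "",
               sub("\\.csv$", "",
                   grep("^estimates_(?!subgroup)", list.files(out_dir),
                        value = TRUE, perl = TRUE)))
  for (sc in scens) {
    est <- utils::read.csv(file.path(out_dir,
                                     paste0("estimates_", sc, ".csv")))
    ic <- utils::read.csv(file.path(out_dir, paste0("icer_", sc, ".csv")))
    lines <- c(lines, sprintf("## Scenario: %s", sc), "",
               "### Adjusted differences vs no feedback", "",
               "| outcome | comparison | estimate | 95% CI | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.4f | [%.4f; %.4f] | %.3f |",
                       est$outcome, est$term, est$estimate, est$ci_low,
                       est$ci_high, est$p), "",
               "### Unadjusted ICERs", "",
               "| comparison | dCost | dEffect | ICER | classification |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.0f | %.4f | %s | %s |", ic$comparison,
                       ic$delta_cost, ic$delta_effect,
                       ifelse(is.na(ic$icer), "undefined",
                              sprintf("%.0f", ic$icer)), ic$quadrant), "")
    cc <- file.path(out_dir, paste0("ceac_", sc, ".csv"))
    if (file.exists(cc)) {
      ceac_df <- utils::read.csv(cc)
      rng <- stats::aggregate(probability ~ term, ceac_df, range)
      lines <- c(lines, "### CEAC probability range over the WTP grid", "",
                 sprintf("- %s: %.0f%% to %.0f%%", rng$term,
                         100 * rng$probability[, 1L],
                         100 * rng$probability[, 2L]), "")
    }
  }
  writeLines(lines, path)
  path
}
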