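#' Build the participant-level analysis table
#'
#' Flattens a `trial_data` object into one row per participant with scored
#' instruments: EQ-5D-5L index values and PHQ-9 totals at T0-T3, per-window
#' resource-use counts, sick days, informal-care hours and the MINI flag.
#' Missing raw fields propagate to missing scores. This is the table the
#' imputation, estimation and decision-analytic stages operate on.
#'
#' @param data a `trial_data` object.
#' @param value_set EQ-5D-5L value set used for scoring.
#' @return data.frame, one row per participant.
#' @export
analysis_table <- function(data, value_set = default_value_set()) {
  stopifnot(inherits(data, "trial_data"))
  bl <- data$baseline
  lg <- data$longitudinal
  tab <- bl
  dims <- c("mobility", "selfcare", "activity", "pain", "anxiety")
  for (tm in c("T0", "T1", "T2", "T3")) {
    rows <- lg[lg$time == tm, ]
    rows <- rows[match(bl$participant_id, rows$participant_id), ]
    tab[[paste0("eq5d_", tm)]] <-
      score_eq5d_index(as.matrix(rows[, dims]), value_set)
    tab[[paste0("phq9_", tm)]] <-
      ifelse(rowSums(is.na(rows[, paste0("phq", 1:9)])) > 0, NA_real_,
             rowSums(rows[, paste0("phq", 1:9)]))
    if (tm != "T0") {
      for (cat in cost_categories())
        tab[[paste(cat, tm, sep = "_")]] <- rows[[cat]]
      tab[[paste0("sick_days_", tm)]] <- rows$sick_days
      tab[[paste0("informal_hours_", tm)]] <- rows$informal_care_hours
    }
  }
  tab
}

#' Columns of the analysis table subject to imputation
#'
#' Follow-up outcome columns (EQ-5D index, PHQ-9 total, resource counts,
#' sick days, informal-care hours at T1-T3) and the MINI flag; baseline
#' scores, covariates and design columns are always observed.
#'
#' @param tab analysis table.
#' @export
imputable_columns <- function(tab) {
  fu <- c(outer(c("eq5d", "phq9", cost_categories(), "sick_days",
                  "informal_hours"),
                c("T1", "T2", "T3"), paste, sep = "_"))
  intersect(c(fu, "mini_depression_T1"), names(tab))
}

#' Derive economic outcomes on a (completed) analysis table
#'
#' Adds QALYs and depression-free days (area under the linearly
#' interpolated EQ-5D index / PHQ-9 trajectory), per-category direct costs,
#' informal-care and indirect (absenteeism) costs, and societal and payer
#' perspective totals, all at 2022 prices.
#'
#' @param tab completed analysis table (no missing outcome values).
#' @param fixtures list from [make_fixtures()] (or drop-in replacements).
#' @param reference_days days between consecutive assessments.
#' @param qaly_denominator days per year in the QALY formula.
#' @return `tab` with added columns `qaly`, `dfd`, `cost_<category>`,
#'   `cost_direct`, `cost_informal`, `cost_indirect`, `cost_societal`,
#'   `cost_payer`.
#' @export
derive_outcomes <- function(tab, fixtures = make_fixtures(),
                            reference_days = c(30, 150, 180),
                            qaly_denominator = 365) {
  eq <- as.matrix(tab[, paste0("eq5d_", c("T0", "T1", "T2", "T3"))])
  ph <- as.matrix(tab[, paste0("phq9_", c("T0", "T1", "T2", "T3"))])
  tab$qaly <- qaly_auc(eq, reference_days, qaly_denominator)
  tab$dfd <- dfd_auc(ph, reference_days)

  uc <- fixtures$unit_costs
  cpi <- fixtures$cpi
  direct <- 0
  for (cat in cost_categories()) {
    counts <- rowSums(tab[, paste(cat, c("T1", "T2", "T3"), sep = "_")])
    row <- uc[uc$category == cat, ]
    if (nrow(row) != 1L) stop("unknown resource category: ", cat)
    unit <- cpi_adjust(row$unit_cost, row$price_year, 2022, cpi)
    tab[[paste0("cost_", cat)]] <- counts * unit
    direct <- direct + tab[[paste0("cost_", cat)]]
  }
  lab <- fixtures$labour
  hours <- rowSums(tab[, paste0("informal_hours_", c("T1", "T2", "T3"))])
  days <- rowSums(tab[, paste0("sick_days_", c("T1", "T2", "T3"))])
  tab$cost_direct <- direct
  tab$cost_informal <- informal_care_cost(hours, lab$informal_wage_hour,
                                          lab$informal_nonwage_hour)
  tab$cost_indirect <- productivity_loss(days, lab$gross_day)
  tab$cost_societal <- assemble_perspective(
    tab$cost_direct, tab$cost_informal, tab$cost_indirect, "societal")
  tab$cost_payer <- assemble_perspective(
    tab$cost_direct, tab$cost_informal, tab$cost_indirect, "payer")
  tab
}
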