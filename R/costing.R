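#' Adjust a cost to a reference price year with a consumer price index
#'
#' @param amount Euro amount(s) valued in `from_year` prices.
#' @param from_year,to_year price years; both must appear in the series.
#' @param cpi data.frame with columns `year` and `index`.
#' @return amount expressed in `to_year` prices:
#'   `amount * index[to_year] / index[from_year]`.
#' @export
cpi_adjust <- function(amount, from_year, to_year, cpi) {
  i_from <- match(from_year, cpi$year)
  i_to <- match(to_year, cpi$year)
  if (anyNA(i_from) || anyNA(i_to))
    stop("price year not covered by the CPI series")
  amount * cpi$index[i_to] / cpi$index[i_from]
}

#' Productivity loss from absenteeism (human capital approach)
#'
#' Days absent from paid work are valued at the gross labour cost per
#' working day.
#'
#' @param sick_days days absent (>= 0).
#' @param gross_labour_cost Euro per day.
#' @return Euro.
#' @export
productivity_loss <- function(sick_days, gross_labour_cost) {
  if (any(sick_days < 0, na.rm = TRUE)) stop("sick_days must be >= 0")
  sick_days * gross_labour_cost
}

#' Informal-care cost (replacement cost approach)
#'
#' Hours of informal care are valued at the market wage of a professional
#' substitute (social-work sector) plus non-wage labour costs.
#'
#' @param hours informal-care hours (>= 0).
#' @param wage_rate,nonwage_rate Euro per hour.
#' @return Euro.
#' @export
informal_care_cost <- function(hours, wage_rate, nonwage_rate) {
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be >= 0")
  hours * (wage_rate + nonwage_rate)
}

#' Assemble a perspective total from cost components
#'
#' The societal perspective sums direct costs, informal care and indirect
#' (productivity loss) costs; the healthcare payer perspective includes
#' direct costs only. Intervention costs are never added (they were
#' negligible by design).
#'
#' @param direct,informal,indirect Euro component(s).
#' @param perspective `"societal"` or `"payer"`.
#' @return Euro total(s).
#' @export
assemble_perspective <- function(direct, informal, indirect,
                                 perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  if (perspective == "societal") direct + informal + indirect else direct
}

#' Sum per-category resource-use costs for one or more participants
#'
#' Multiplies per-window counts by CPI-adjusted unit costs and sums over the
#' follow-up windows. Works on the analysis table; [derive_outcomes()] is the
#' usual entry point, this helper exposes the per-category step.
#'
#' @param tab analysis table with complete count columns.
#' @param unit_costs unit-cost table.
#' @param cpi CPI series.
#' @return data.frame of per-category Euro costs (one column per category).
#' @export
cost_resource_use <- function(tab, unit_costs = default_unit_costs(),
                              cpi = default_cpi()) {
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (cat in cost_categories()) {
    row <- unit_costs[unit_costs$category == cat, ]
    if (nrow(row) != 1L) stop("unknown resource category: ", cat)
    unit <- cpi_adjust(row$unit_cost, row$price_year, 2022, cpi)
    out[[cat]] <- rowSums(
      tab[, paste(cat, c("T1", "T2", "T3"), sep = "_")]) * unit
  }
  out
}
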