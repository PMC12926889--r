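#' Configuration fixtures: value set, unit costs, CPI, labour costs
#'
#' The analysis needs three configuration tables: an EQ-5D-5L value set
#' (dimension/level decrements), a unit-cost table per resource category, and
#' a consumer-price-index series used to express all costs in 2022 Euros.
#' The tables returned here are *synthetic stand-ins* with the structural
#' properties of their real counterparts (a German-style value set anchored at
#' index 1.0 for full health and floor -0.661 for state 55555; plausible
#' German unit costs with mixed price years). Real tables can be supplied as
#' drop-in CSVs with the same columns.
#'
#' @return `make_fixtures()` returns a list with elements `value_set`,
#'   `unit_costs`, `cpi`, `labour` (gross labour cost per working day for
#'   absenteeism, and the informal-care replacement wage split into wage and
#'   non-wage components per hour, all at 2022 prices).
#' @export
make_fixtures <- function() {
  list(
    value_set  = default_value_set(),
    unit_costs = default_unit_costs(),
    cpi        = default_cpi(),
    labour     = default_labour_costs()
  )
}

eq5d_dimensions <- c("mobility", "selfcare", "activity", "pain", "anxiety")

#' Synthetic EQ-5D-5L value set
#'
#' Additive decrement table: index(state) = 1 - sum of the decrement of the
#' chosen level in each dimension. Level 1 carries decrement 0; decrements are
#' strictly increasing in level, so 11111 is the unique state with index 1.0.
#' Level-5 decrements sum to 1.661, reproducing the documented floor of the
#' German value set, index(55555) = -0.661.
#'
#' @return data.frame with columns `dimension`, `level`, `decrement`.
#' @export
default_value_set <- function() {
  dec <- rbind(
    mobility = c(0, 0.042, 0.077, 0.215, 0.337),
    selfcare = c(0, 0.050, 0.082, 0.234, 0.314),
    activity = c(0, 0.040, 0.062, 0.166, 0.274),
    pain     = c(0, 0.051, 0.097, 0.249, 0.368),
    anxiety  = c(0, 0.048, 0.089, 0.244, 0.368)
  )
  data.frame(
    dimension = rep(eq5d_dimensions, each = 5L),
    level = rep(1:5, times = 5L),
    decrement = as.vector(t(dec[eq5d_dimensions, ])),
    stringsAsFactors = FALSE
  )
}

#' Resource categories costed in the analysis
#' @export
cost_categories <- function() {
  c("gp_visit", "specialist_visit", "psychotherapy_session",
    "psychiatrist_contact", "nonphysician_contact", "inpatient_day",
    "medication_item", "formal_care_hour")
}

#' Synthetic unit-cost table
#'
#' One row per resource category with a Euro cost per unit and the price year
#' the cost was valued in; costs are inflated to 2022 with [cpi_adjust()].
#' Medication is costed per reported medication item per recall window, a
#' stand-in for pharmacy retail prices from a pharmaceutical directory.
#'
#' @return data.frame with columns `category`, `unit_cost`, `price_year`.
#' @export
default_unit_costs <- function() {
  data.frame(
    category = cost_categories(),
    unit_cost = c(40, 60, 100, 75, 30, 650, 35, 45),
    price_year = c(2022, 2020, 2021, 2020, 2021, 2019, 2021, 2022),
    stringsAsFactors = FALSE
  )
}

#' Synthetic consumer-price-index series (reference year 2022)
#' @return data.frame with columns `year`, `index`.
#' @export
default_cpi <- function() {
  data.frame(
    year = 2015:2022,
    index = c(100.0, 100.5, 102.0, 103.8, 105.3, 105.8, 109.1, 116.7)
  )
}

#' Synthetic labour-cost parameters (2022 prices)
#'
#' `gross_day` values one day of absenteeism from paid work under the human
#' capital approach. Informal care is valued with the replacement cost
#' approach at `informal_wage_hour` + `informal_nonwage_hour` per hour
#' (market wage of a professional substitute plus non-wage labour costs).
#'
#' @return list with `gross_day`, `informal_wage_hour`,
#'   `informal_nonwage_hour`, `price_year`.
#' @export
default_labour_costs <- function() {
  list(gross_day = 180, informal_wage_hour = 28, informal_nonwage_hour = 7,
       price_year = 2022)
}

#' Write / read fixture tables as CSV
#'
#' @param fixtures list as returned by [make_fixtures()].
#' @param dir directory for the CSV files.
#' @return `write_fixtures` returns the directory invisibly; `read_fixtures`
#'   returns a fixtures list.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fixtures$value_set, file.path(dir, "value_set.csv"),
                   row.names = FALSE)
  utils::write.csv(fixtures$unit_costs, file.path(dir, "unit_costs.csv"),
                   row.names = FALSE)
  utils::write.csv(fixtures$cpi, file.path(dir, "cpi.csv"), row.names = FALSE)
  lab <- fixtures$labour
  utils::write.csv(
    data.frame(parameter = names(lab), value = unlist(lab)),
    file.path(dir, "labour_costs.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labour_costs.csv"))
  labour <- as.list(stats::setNames(lab$value, lab$parameter))
  list(
    value_set = utils::read.csv(file.path(dir, "value_set.csv"),
                                stringsAsFactors = FALSE),
    unit_costs = utils::read.csv(file.path(dir, "unit_costs.csv"),
                                 stringsAsFactors = FALSE),
    cpi = utils::read.csv(file.path(dir, "cpi.csv")),
    labour = labour
  )
}
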