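#' Default five-year uptake schedule
#'
#' Yearly national PPH patient totals for 2021-2025 with the phased
#' (primary, then secondary, then tertiary) TXA uptake counts.  Patient
#' totals follow the projected growth of the Indian female population aged
#' 15-49 at constant PPH incidence; the packaged schedule ships these
#' published projections verbatim rather than re-deriving them from external
#' population data.
#'
#' @param path Optional CSV (columns `year,total_patients,txa_patients,
#'   soc_patients`).
#' @return Data frame of class `txa_schedule`.
#' @export
default_uptake_schedule <- function(path = system.file(
  "extdata", "uptake_schedule.csv", package = "txacea", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_schedule(df)
}

validate_schedule <- function(df) {
  needed <- c("year", "total_patients", "txa_patients", "soc_patients")
  stopifnot(all(needed %in% names(df)))
  if (any(df$txa_patients + df$soc_patients != df$total_patients))
    stop("uptake schedule: txa + soc patients must equal the yearly total")
  if (any(df$txa_patients < 0 | df$soc_patients < 0))
    stop("uptake schedule: negative counts")
  frac <- df$txa_patients / df$total_patients
  if (any(diff(frac) < -1e-9) && any(frac < 1))
    warning("uptake fraction decreases before reaching full coverage")
  class(df) <- c("txa_schedule", "data.frame")
  df
}

#' Project yearly PPH cohort sizes
#'
#' Default mode returns the shipped per-year totals; parametric mode applies
#' user-supplied year-on-year growth factors to a base-year count (constant
#' PPH incidence, population-driven growth).
#'
#' @param base_year_cases Base-year PPH count (parametric mode).
#' @param growth_factors Numeric vector of yearly growth multipliers; the
#'   first year equals `base_year_cases * growth_factors[1]`.
#' @return Integer vector of per-year PPH counts.
#' @export
project_cohort <- function(base_year_cases = NULL, growth_factors = NULL) {
  if (is.null(base_year_cases) && is.null(growth_factors))
    return(default_uptake_schedule()$total_patients)
  stopifnot(base_year_cases > 0, all(is.finite(growth_factors)))
  out <- base_year_cases * cumprod(growth_factors)
  if (any(out < 0)) stop("negative cohort projection")
  round(out)
}

#' Percentage budget impact
#'
#' @param with_cost Total yearly cost with TXA introduction (INR).
#' @param without_cost Total yearly cost without (INR, > 0).
#' @return `100 * (with - without) / without`.
#' @export
percentage_impact <- function(with_cost, without_cost) {
  stopifnot(all(without_cost > 0))
  100 * (with_cost - without_cost) / without_cost
}

#' Five-year budget impact of phased TXA introduction
#'
#' For each year, the cost with TXA introduction is `txa_patients *
#' cost_txa + soc_patients * cost_soc`; without introduction every patient
#' costs `cost_soc`.  Two costing modes are provided.
#' `"intervention_increment"` (default) prices the TXA tranche at the
#' standard-care cost plus the gross medical-management increment of adding
#' TXA — the budget-holder convention in which the new line item is the
#' drug-plus-administration package, with downstream resource offsets not
#' credited against the allocation.  `"net"` instead uses the full
#' difference between the two arms' expected per-patient costs, crediting
#' averted downstream care.
#'
#' @param schedule A [default_uptake_schedule()]-shaped data frame.
#' @param cost_soc Per-patient societal cost, standard care (INR).
#' @param cost_txa Per-patient societal cost, TXA arm (INR) — used by the
#'   `"net"` mode.
#' @param increment Gross per-patient medical-management increment (INR) —
#'   used by the `"intervention_increment"` mode.
#' @param mode `"intervention_increment"` or `"net"`.
#' @param exchange_rate INR per USD for the report columns.
#' @return Data frame (class `txa_bia`): per-year rows plus a cumulative
#'   row with with/without totals, difference, and percentage impact.
#' @export
run_bia <- function(schedule = default_uptake_schedule(),
                    cost_soc, cost_txa = NULL, increment = NULL,
                    mode = c("intervention_increment", "net"),
                    exchange_rate = 69.43) {
  mode <- match.arg(mode)
  schedule <- validate_schedule(as.data.frame(schedule))
  delta <- switch(mode,
    intervention_increment = {
      if (is.null(increment))
        stop("mode 'intervention_increment' needs `increment`")
      increment
    },
    net = {
      if (is.null(cost_txa)) stop("mode 'net' needs `cost_txa`")
      cost_txa - cost_soc
    })
  without <- schedule$total_patients * cost_soc
  with <- without + schedule$txa_patients * delta
  out <- data.frame(
    year = as.character(schedule$year),
    txa_patients = schedule$txa_patients,
    total_patients = schedule$total_patients,
    cost_with = with, cost_without = without,
    difference = with - without,
    stringsAsFactors = FALSE)
  cum <- data.frame(
    year = "cumulative",
    txa_patients = sum(schedule$txa_patients),
    total_patients = sum(schedule$total_patients),
    cost_with = sum(with), cost_without = sum(without),
    difference = sum(with) - sum(without),
    stringsAsFactors = FALSE)
  out <- rbind(out, cum)
  out$percentage_impact <- percentage_impact(out$cost_with, out$cost_without)
  out$cost_with_usd <- out$cost_with / exchange_rate
  out$cost_without_usd <- out$cost_without / exchange_rate
  out$difference_usd <- out$difference / exchange_rate
  class(out) <- c("txa_bia", "data.frame")
  out
}

#' Per-patient BIA cost inputs from a calibrated base case
#'
#' Extracts the standard-care per-patient societal cost, the TXA-arm cost,
#' and the gross medical-management increment (uptake-tranche weighted
#' across facility levels) from a model and its base-case result.
#'
#' @param model A [build_model()] object.
#' @param cea Optional [run_base_case()] result (computed if missing).
#' @return List `cost_soc`, `cost_txa`, `increment`.
#' @export
bia_cost_inputs <- function(model, cea = run_base_case(model)) {
  v <- model_values(model$tree)
  mix <- model$config$facility_mix
  increment <- sum(mix * c(v$cost_med_txa_primary - v$cost_med_soc_primary,
                           v$cost_med_txa_secondary - v$cost_med_soc_secondary,
                           v$cost_med_txa_tertiary - v$cost_med_soc_tertiary))
  list(cost_soc = cea$arms$cost_societal[cea$arms$arm == "soc"],
       cost_txa = cea$arms$cost_societal[cea$arms$arm == "txa"],
       increment = increment)
}
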