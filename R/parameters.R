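PARAM_ROLES <- c("probability", "relative_risk", "cost", "utility",
                 "resource_count", "rate")
LIMIT_RULES <- c("assumed_20pct", "source_CI", "cost_simulated_CI")

#' Create a model parameter
#'
#' A parameter is one named model input with a base value, sensitivity-analysis
#' bounds, a provenance role and a limit rule.  Probabilities and utilities
#' must lie in `[0, 1]`, costs and resource counts must be non-negative, and
#' relative risks must be positive.
#'
#' @param name Identifier (snake_case).
#' @param role One of `"probability"`, `"relative_risk"`, `"cost"`,
#'   `"utility"`, `"resource_count"`, `"rate"`.
#' @param base Base-case value.
#' @param low,high Lower/upper limits used in sensitivity analysis.  If
#'   missing they are filled by [apply_limit_rule()].
#' @param limit_rule How the limits were (or are to be) derived:
#'   `"assumed_20pct"` (20 percent variation either side, capped at 1 for
#'   probabilities and utilities), `"source_CI"` (printed source interval) or
#'   `"cost_simulated_CI"` (95\% CI from the costing study's Monte Carlo
#'   sub-component simulation, consumed as printed).
#' @param units Free-text units ("INR" for costs, "" otherwise).
#' @param sample Should probabilistic sensitivity analysis draw this
#'   parameter?  Analysis settings (discount rate, cohort age) are varied in
#'   one-way analysis only.
#' @return An object of class `txa_parameter`.
#' @export
parameter <- function(name, role, base, low = NA_real_, high = NA_real_,
                      limit_rule = "source_CI", units = "", sample = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, PARAM_ROLES)
  limit_rule <- match.arg(limit_rule, LIMIT_RULES)
  p <- structure(
    list(name = name, role = role, base = as.numeric(base),
         low = as.numeric(low), high = as.numeric(high),
         limit_rule = limit_rule, units = units, sample = isTRUE(sample)),
    class = "txa_parameter")
  if (is.na(p$low) || is.na(p$high)) p <- apply_limit_rule(p)
  validate_parameter(p)
  p
}

validate_parameter <- function(p) {
  with(p, {
    if (!is.finite(base)) stop("parameter '", name, "': non-finite base value")
    if (low > base + 1e-12 || base > high + 1e-12)
      stop("parameter '", name, "': base ", base,
           " outside [low, high] = [", low, ", ", high, "]")
    if (role %in% c("probability", "utility") &&
        (low < -1e-12 || high > 1 + 1e-12))
      stop("parameter '", name, "': ", role, " bounds must lie in [0, 1]")
    if (role %in% c("cost", "resource_count") && low < 0)
      stop("parameter '", name, "': ", role, " must be non-negative")
    if (role == "relative_risk" && base <= 0)
      stop("parameter '", name, "': relative risk must be positive")
  })
  invisible(p)
}

#' Fill sensitivity limits from a parameter's limit rule
#'
#' For `assumed_20pct` the limits are `0.8 * base` and `1.2 * base`, with the
#' upper limit capped at 1 for probabilities and utilities.  Parameters whose
#' limits come from a source interval are returned unchanged when limits are
#' already present.
#'
#' @param p A [parameter()].
#' @return The parameter with `low`/`high` populated.
#' @export
apply_limit_rule <- function(p) {
  stopifnot(inherits(p, "txa_parameter"))
  if (p$limit_rule == "assumed_20pct" || is.na(p$low) || is.na(p$high)) {
    p$low <- 0.8 * p$base
    p$high <- 1.2 * p$base
    if (p$role %in% c("probability", "utility")) {
      p$high <- min(p$high, 1)
      p$low <- max(p$low, 0)
    }
  }
  p
}

#' @export
print.txa_parameter <- function(x, ...) {
  cat(sprintf("<parameter> %s [%s]: %g (%g - %g) %s\n",
              x$name, x$role, x$base, x$low, x$high, x$units))
  invisible(x)
}

# Parameter names the tree/outcomes/cea modules reference; load_parameters()
# reports any that are missing collectively.
required_parameter_names <- function() {
  c("p_atonic", "p_further_txa", "p_further_soc",
    "p_ubt_primary", "p_ubt_secondary", "p_ubt_tertiary", "p_ubt_effective",
    "rr_death_bleed_txa", "p_death_bleed_soc", "p_direct_hyst",
    "p_hyst_after_devasc", "rr_death_all_txa", "p_death_all_soc",
    "p_icu_uncontrolled", "p_icu_controlled", "p_trauma_local_control",
    "cost_med_txa_primary", "cost_med_txa_secondary", "cost_med_txa_tertiary",
    "cost_med_soc_primary", "cost_med_soc_secondary", "cost_med_soc_tertiary",
    "cost_ubt_primary", "cost_ubt_secondary", "cost_ubt_tertiary",
    "cost_devasc_secondary", "cost_devasc_tertiary",
    "cost_hyst_secondary", "cost_hyst_tertiary",
    "cost_ipd_secondary", "cost_ipd_tertiary", "cost_icu_tertiary",
    "cost_local_primary", "cost_local_secondary", "cost_local_tertiary",
    "cost_referral", "cost_oop_childbirth",
    "u_death", "u_discharge_medical", "u_conservative",
    "u_devasc_short", "u_devasc_long", "u_hyst_short", "u_hyst_long", "u_icu",
    "age_start", "discount_rate")
}

#' Load the model parameter table
#'
#' Reads a CSV parameter table (columns `name, role, base, low, high,
#' limit_rule, units, sample`) into a parameter set.  The packaged default
#' table holds every model input: probabilities, relative risks, INR unit
#' costs at the three facility levels, utilities and analysis rates.
#'
#' @param path CSV file; defaults to the packaged table.
#' @return A named list of [parameter()] objects, class `txa_parameter_set`.
#' @export
load_parameters <- function(path = default_parameter_file()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed_cols <- c("name", "role", "base", "low", "high", "limit_rule")
  missing_cols <- setdiff(needed_cols, names(df))
  if (length(missing_cols))
    stop("parameter table missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("base", "low", "high")) {
    bad <- is.na(suppressWarnings(as.numeric(df[[col]])))
    if (any(bad))
      stop("malformed number in column '", col, "' for row(s): ",
           paste(df$name[bad], collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  if (is.null(df$units)) df$units <- character(nrow(df))
  df$units[is.na(df$units)] <- ""
  if (is.null(df$sample)) df$sample <- rep(TRUE, nrow(df))
  params <- lapply(seq_len(nrow(df)), function(i) {
    parameter(df$name[i], df$role[i], df$base[i], df$low[i], df$high[i],
              df$limit_rule[i], df$units[i], df$sample[i])
  })
  names(params) <- df$name
  missing <- setdiff(required_parameter_names(), names(params))
  if (length(missing))
    stop("parameter table is missing required parameters: ",
         paste(missing, collapse = ", "))
  structure(params, class = "txa_parameter_set")
}

#' @export
print.txa_parameter_set <- function(x, ...) {
  cat("<parameter set> ", length(x), " parameters\n", sep = "")
  invisible(x)
}

#' Path of the packaged default parameter table
#' @export
default_parameter_file <- function() {
  system.file("extdata", "parameters.csv", package = "txacea", mustWork = TRUE)
}

#' Base values of a parameter set as a named list
#'
#' @param params A `txa_parameter_set`.
#' @return Named list of base values, suitable as an evaluation environment
#'   for pathway probability and payoff expressions.
#' @export
base_values <- function(params) {
  stats::setNames(lapply(params, `[[`, "base"), names(params))
}

#' Serialize a parameter set back to a data frame
#'
#' Round trip: `load_parameters()` on the written CSV reproduces the set.
#' @param params A `txa_parameter_set`.
#' @export
as.data.frame.txa_parameter_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(p)
    data.frame(name = p$name, role = p$role, base = p$base, low = p$low,
               high = p$high, limit_rule = p$limit_rule, units = p$units,
               sample = p$sample, stringsAsFactors = FALSE)))
}

#' Fit the uncertainty distribution for a parameter
#'
#' Probabilities, proportions and utilities get a beta distribution; costs and
#' resource counts a gamma; relative risks a lognormal.  Beta and gamma are
#' fitted by the method of moments with mean equal to the base value and
#' standard deviation `(high - low) / 3.92` (the printed limits treated as a
#' 95\% interval).  The lognormal is centred so its *median* equals the base
#' value, with `sdlog = (log(high) - log(low)) / 3.92` (the log-scale symmetry
#' under which relative-risk confidence intervals are constructed).
#' Zero-width limits give a degenerate `fixed` distribution.
#'
#' @param p A [parameter()].
#' @return A `txa_distribution` with fields `family`, `pars`, `derivation`.
#' @export
fit_distribution <- function(p) {
  stopifnot(inherits(p, "txa_parameter"))
  sdv <- (p$high - p$low) / 3.92
  fixed <- function() structure(
    list(name = p$name, family = "fixed", pars = c(value = p$base),
         derivation = "degenerate"), class = "txa_distribution")
  if (sdv <= 0 || !p$sample) {
    if (sdv <= 0 && p$base != 0 && p$sample)
      warning("parameter '", p$name, "': degenerate bounds; treating as fixed")
    return(fixed())
  }
  d <- switch(
    p$role,
    probability = ,
    utility = {
      m <- p$base
      v <- sdv^2
      # method of moments on [0,1]; requires v < m(1-m)
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) return(fixed())
      k <- m * (1 - m) / v - 1
      list(family = "beta", pars = c(shape1 = m * k, shape2 = (1 - m) * k),
           derivation = "moments_from_base_and_limits")
    },
    cost = ,
    resource_count = ,
    rate = {
      m <- p$base
      v <- sdv^2
      if (m <= 0) return(fixed())
      list(family = "gamma", pars = c(shape = m^2 / v, scale = v / m),
           derivation = "moments_from_base_and_limits")
    },
    relative_risk = {
      sdlog <- (log(p$high) - log(p$low)) / 3.92
      list(family = "lognormal", pars = c(meanlog = log(p$base), sdlog = sdlog),
           derivation = "log_CI")
    })
  structure(c(list(name = p$name), d), class = "txa_distribution")
}

#' @export
print.txa_distribution <- function(x, ...) {
  cat(sprintf("<distribution> %s: %s(%s)\n", x$name, x$family,
              paste(sprintf("%s=%.4g", names(x$pars), x$pars), collapse = ", ")))
  invisible(x)
}

#' Mean of a fitted distribution (median for lognormal)
#' @param d A `txa_distribution`.
#' @export
distribution_centre <- function(d) {
  switch(d$family,
         fixed = unname(d$pars["value"]),
         beta = unname(d$pars["shape1"] / sum(d$pars)),
         gamma = unname(d$pars["shape"] * d$pars["scale"]),
         lognormal = exp(unname(d$pars["meanlog"])))
}

#' Draw from a fitted distribution
#'
#' @param d A `txa_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`; respects the family's domain.
#' @export
draw_distribution <- function(d, n) {
  switch(d$family,
         fixed = rep(unname(d$pars["value"]), n),
         beta = stats::rbeta(n, d$pars["shape1"], d$pars["shape2"]),
         gamma = stats::rgamma(n, shape = d$pars["shape"],
                               scale = d$pars["scale"]),
         lognormal = stats::rlnorm(n, d$pars["meanlog"], d$pars["sdlog"]))
}

#' Relative risk from 2x2 event counts
#'
#' Computes `RR = (e1/n1) / (e0/n0)` with the standard log-scale Wald 95\%
#' interval `exp(log RR -/+ 1.96 * sqrt(1/e1 - 1/n1 + 1/e0 - 1/n0))`.
#'
#' @param events_intervention,n_intervention Events and total in the
#'   intervention arm.
#' @param events_control,n_control Events and total in the control arm.
#' @param name Name for the resulting parameter.
#' @return A [parameter()] with role `relative_risk`.
#' @export
relative_risk <- function(events_intervention, n_intervention,
                          events_control, n_control, name = "rr") {
  e1 <- events_intervention; n1 <- n_intervention
  e0 <- events_control; n0 <- n_control
  stopifnot(n1 > 0, n0 > 0, e1 >= 0, e0 >= 0, e1 <= n1, e0 <= n0)
  if (e0 == 0) stop("relative risk undefined: zero events in control arm")
  rr <- (e1 / n1) / (e0 / n0)
  if (e1 == 0) {
    warning("zero events in intervention arm: RR = 0, CI unavailable")
    return(parameter(name, "relative_risk", base = .Machine$double.eps,
                     low = .Machine$double.eps, high = .Machine$double.eps,
                     limit_rule = "source_CI"))
  }
  se <- sqrt(1 / e1 - 1 / n1 + 1 / e0 - 1 / n0)
  ci <- exp(log(rr) + c(-1, 1) * 1.96 * se)
  parameter(name, "relative_risk", base = rr, low = ci[1], high = ci[2],
            limit_rule = "source_CI")
}

#' Analysis configuration
#'
#' Cohort constants and analysis settings: 3\% per-annum discount rate,
#' willingness-to-pay threshold INR 145,742 (2019-20 Indian GDP per capita),
#' exchange rate 69.43 INR/USD, annual cohort of 510,915 PPH cases, overall
#' female life expectancy 70.7 years with cohort age 21 at the event.
#'
#' @param discount_rate Per-annum outcome discount rate in `[0, 0.05]`.
#' @param wtp_threshold Willingness to pay, INR per QALY.
#' @param exchange_rate INR per USD, used at report time only.
#' @param annual_cohort Annual PPH cases.
#' @param life_expectancy Overall life expectancy (years).
#' @param perspective `"societal"` (health system + out-of-pocket) or
#'   `"health_system"`.
#' @param discounting `"differential"` (costs one-off undiscounted, outcomes
#'   discounted) or `"undiscounted"`.
#' @param convention QALY discounting convention: `"aggregate_horizon"`
#'   (single factor `(1+r)^-horizon` on lifetime QALYs; the calibrated
#'   default), `"continuous"` (continuous-time annuity) or `"annual"`
#'   (discrete annual integration).
#' @param horizon Effective discounting horizon (years) for the
#'   `aggregate_horizon` convention; calibrated by [calibrate_free_knobs()].
#' @param facility_mix Numeric length-3 simplex: shares of PPH cases
#'   presenting at primary/secondary/tertiary facilities.  Not printed by any
#'   source; the default is the calibrated value.
#' @param structure Structural switches, see [model_structure()].
#' @param psa_draws Monte Carlo draws for probabilistic sensitivity analysis.
#' @param rng_seed Integer seed.
#' @return A list of class `txa_config`.
#' @export
analysis_config <- function(discount_rate = 0.03,
                            wtp_threshold = 145742,
                            exchange_rate = 69.43,
                            annual_cohort = 510915,
                            life_expectancy = 70.7,
                            perspective = c("societal", "health_system"),
                            discounting = c("differential", "undiscounted"),
                            convention = c("aggregate_horizon", "continuous",
                                           "annual"),
                            horizon = 26.958,
                            facility_mix = c(primary = 0.000,
                                             secondary = 0.784,
                                             tertiary = 0.216),
                            structure = model_structure(),
                            psa_draws = 10000,
                            rng_seed = 1L) {
  stopifnot(discount_rate >= 0, discount_rate <= 0.05,
            psa_draws >= 1, annual_cohort > 0,
            length(facility_mix) == 3, all(facility_mix >= 0),
            abs(sum(facility_mix)) > 0)
  facility_mix <- facility_mix / sum(facility_mix)
  names(facility_mix) <- c("primary", "secondary", "tertiary")
  structure(list(discount_rate = discount_rate,
                 wtp_threshold = wtp_threshold,
                 exchange_rate = exchange_rate,
                 annual_cohort = annual_cohort,
                 life_expectancy = life_expectancy,
                 perspective = match.arg(perspective),
                 discounting = match.arg(discounting),
                 convention = match.arg(convention),
                 horizon = horizon,
                 facility_mix = facility_mix,
                 structure = structure,
                 psa_draws = psa_draws,
                 rng_seed = as.integer(rng_seed)),
            class = "txa_config")
}

#' Structural model switches
#'
#' The decision problem leaves a handful of structural choices open; they are
#' explicit switches so that calibration and sensitivity analyses can probe
#' them rather than bake them in silently.
#'
#' @param traumatic_gated Do traumatic PPH cases pass through the same
#'   further-intervention gate as atonic cases (default) or all receive local
#'   exploration/repair?
#' @param extra_ipd_further Do further-intervention episodes incur one
#'   additional indoor-admission package (escalation implies renewed
#'   admission)?
#' @param escalation_referral Do further-intervention episodes at
#'   primary/secondary facilities incur a referral cost?
#' @param oop One of `"further_cases"` (out-of-pocket childbirth expenditure
#'   attaches to further-intervention episodes) or `"all_cases"`.
#' @param utility_conservative Does the conservative-management utility
#'   (0.895) apply over the remaining lifetime (`"lifetime"`) or over the
#'   42-day post-partum convalescence with recovery to the discharge
#'   utility thereafter (`"short_term"`, the default: conservative measures
#'   are uterus-preserving and carry no lasting sequela)?
#' @param mortality Allocation of arm-level death risks to pathways:
#'   `"additive_icu"` (all-cause risk on every pathway, bleeding-death risk
#'   added on ICU-containing pathways), `"additive_uncontrolled"` (bleeding
#'   risk added on uncontrolled-bleeding pathways) or `"residual_uniform"`
#'   (bleeding deaths on uncontrolled pathways, residual all-cause spread
#'   uniformly).
#' @param surgeries_count `"events"` (a pathway with devascularization and
#'   hysterectomy contributes both) or `"patients"`.
#' @export
model_structure <- function(traumatic_gated = TRUE,
                            extra_ipd_further = TRUE,
                            escalation_referral = TRUE,
                            oop = c("further_cases", "all_cases"),
                            utility_conservative = c("short_term",
                                                     "lifetime"),
                            mortality = c("additive_icu",
                                          "additive_uncontrolled",
                                          "residual_uniform"),
                            surgeries_count = c("events", "patients")) {
  list(traumatic_gated = isTRUE(traumatic_gated),
       extra_ipd_further = isTRUE(extra_ipd_further),
       escalation_referral = isTRUE(escalation_referral),
       oop = match.arg(oop),
       utility_conservative = match.arg(utility_conservative),
       mortality = match.arg(mortality),
       surgeries_count = match.arg(surgeries_count))
}
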