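DAYS_YEAR <- 365.25
ICU_DAYS <- 1.5
SHORT_TERM_DAYS <- 42

#' Discounting weight over a time interval
#'
#' Returns the discounted duration of the interval `[t_start, t_end]` (years
#' from the event) so that a constant utility `u` over the interval
#' contributes `u * discount_weight(...)` QALYs.  A rate of zero returns the
#' plain duration under every convention.
#'
#' Conventions: `"continuous"` integrates `exp(-r t)`; `"annual"` integrates
#' `(1+r)^-t` (so the annualized factor over year 1 lies between
#' `(1+r)^-1` and 1); `"aggregate_horizon"` applies the single factor
#' `(1+r)^-horizon` to the whole duration — the convention under which the
#' discounted and undiscounted lifetime QALYs of every pathway share one
#' ratio, with `horizon` an explicit, calibrated quantity.
#'
#' @param t_start,t_end Interval in years, `0 <= t_start <= t_end`.
#' @param rate Per-annum discount rate (>= 0).
#' @param convention One of `"continuous"`, `"annual"`, `"aggregate_horizon"`.
#' @param horizon Effective horizon (years) for `aggregate_horizon`.
#' @return Dimensionless weight (discounted years).
#' @export
discount_weight <- function(t_start, t_end, rate,
                            convention = c("continuous", "annual",
                                           "aggregate_horizon"),
                            horizon = 0) {
  convention <- match.arg(convention)
  if (any(rate < 0)) stop("negative discount rate")
  stopifnot(all(t_start >= 0), all(t_end >= t_start))
  dur <- t_end - t_start
  if (all(rate == 0)) return(dur)
  switch(convention,
    continuous = (exp(-rate * t_start) - exp(-rate * t_end)) / rate,
    annual = ((1 + rate)^(-t_start) - (1 + rate)^(-t_end)) / log(1 + rate),
    aggregate_horizon = dur * (1 + rate)^(-horizon))
}

#' Utility trajectory of a pathway terminal
#'
#' Piecewise utility-over-time description: an optional ICU segment (1.5
#' days at the ICU utility), an optional 42-day post-partum short-term
#' surgical segment, and a terminal segment at the long-term (or discharge)
#' utility covering the remaining life expectancy.  Dead terminals get a
#' single zero-utility segment.  Segment durations always sum to the
#' remaining life expectancy at the event age.
#'
#' @param pathway One row of an [enumerate_pathways()] frame.
#' @param horizon_years Remaining life expectancy at event age.
#' @param conservative_short Treat conservative control (UBT success, local
#'   repair, continued medical/conservative care) as a 42-day convalescence
#'   at the conservative utility followed by the discharge utility, rather
#'   than a lifetime weight.
#' @return Data frame with columns `utility_param`, `t_start`, `t_end`.
#' @export
utility_trajectory <- function(pathway, horizon_years,
                               conservative_short = TRUE) {
  if (pathway$terminal_state == "dead")
    return(data.frame(utility_param = "u_death", t_start = 0,
                      t_end = horizon_years, stringsAsFactors = FALSE))
  segs <- list()
  t <- 0
  if (isTRUE(pathway$icu)) {
    segs[[1]] <- c("u_icu", t, t + ICU_DAYS / DAYS_YEAR)
    t <- t + ICU_DAYS / DAYS_YEAR
  }
  surgical <- isTRUE(pathway$devasc) || isTRUE(pathway$hyst)
  if (surgical) {
    short <- if (isTRUE(pathway$hyst)) "u_hyst_short" else "u_devasc_short"
    long <- if (isTRUE(pathway$hyst)) "u_hyst_long" else "u_devasc_long"
    t2 <- t + SHORT_TERM_DAYS / DAYS_YEAR
    segs[[length(segs) + 1]] <- c(short, t, t2)
    segs[[length(segs) + 1]] <- c(long, t2, horizon_years)
  } else if (identical(pathway$control, "conservative")) {
    if (conservative_short) {
      t2 <- t + SHORT_TERM_DAYS / DAYS_YEAR
      segs[[length(segs) + 1]] <- c("u_conservative", t, t2)
      segs[[length(segs) + 1]] <- c("u_discharge_medical", t2, horizon_years)
    } else {
      segs[[length(segs) + 1]] <- c("u_conservative", t, horizon_years)
    }
  } else {
    segs[[length(segs) + 1]] <- c("u_discharge_medical", t, horizon_years)
  }
  out <- do.call(rbind, segs)
  data.frame(utility_param = out[, 1], t_start = as.numeric(out[, 2]),
             t_end = as.numeric(out[, 3]), stringsAsFactors = FALSE)
}

# Facility level at which admission/surgery happens: primary presenters are
# stabilized and referred to secondary care.
receiving_level <- function(level) ifelse(level == "primary", "secondary", level)

#' Per-pathway unit-cost counts
#'
#' Builds the pathway-by-cost-parameter count matrix: how many units of each
#' Table-priced cost package a pathway consumes.  Health-system components:
#' medical management (with TXA in the intervention arm) at the presenting
#' level; one referral for primary presenters (stabilize-and-refer); an
#' indoor-admission package at the receiving level for every episode, plus
#' one additional admission package and (from primary/secondary) an
#' escalation referral for further-intervention episodes when those switches
#' are on; UBT and traumatic local repair at the presenting level; surgery at
#' the receiving level; ICU at tertiary with a referral when admitted from
#' below.  The out-of-pocket childbirth expenditure is kept in its own
#' column (`cost_oop_childbirth`) so perspectives can be separated.
#'
#' @param pathways An [enumerate_pathways()] frame.
#' @param structure [model_structure()] switches.
#' @return Integer matrix, `nrow(pathways)` rows, cost-parameter columns.
#' @export
cost_count_matrix <- function(pathways, structure = model_structure()) {
  cost_names <- grep("^cost_", required_parameter_names(), value = TRUE)
  m <- matrix(0L, nrow(pathways), length(cost_names),
              dimnames = list(pathways$pathway_id, cost_names))
  add <- function(i, nm, k = 1L) m[i, nm] <<- m[i, nm] + k
  for (i in seq_len(nrow(pathways))) {
    p <- pathways[i, ]
    lvl <- p$level
    rl <- receiving_level(lvl)
    med <- paste0("cost_med_", if (p$arm == "txa") "txa" else "soc", "_", lvl)
    add(i, med)
    add(i, paste0("cost_ipd_", rl))
    if (lvl == "primary") add(i, "cost_referral")
    if (isTRUE(p$further) ||
        (!structure$traumatic_gated && p$pph_type == "traumatic")) {
      if (structure$extra_ipd_further) add(i, paste0("cost_ipd_", rl))
      if (structure$escalation_referral && lvl != "tertiary")
        add(i, "cost_referral")
      if (structure$oop == "further_cases") add(i, "cost_oop_childbirth")
    }
    if (structure$oop == "all_cases") add(i, "cost_oop_childbirth")
    if (isTRUE(p$ubt)) add(i, paste0("cost_ubt_", lvl))
    if (isTRUE(p$local_repair)) add(i, paste0("cost_local_", lvl))
    if (isTRUE(p$devasc)) add(i, paste0("cost_devasc_", rl))
    if (isTRUE(p$hyst)) add(i, paste0("cost_hyst_", rl))
    if (isTRUE(p$icu)) {
      add(i, "cost_icu_tertiary")
      if (rl != "tertiary") add(i, "cost_referral")
    }
  }
  m
}

#' Per-pathway utility weight matrix
#'
#' For each pathway, the (possibly discounted) duration attached to each
#' utility parameter, so that pathway QALYs are the linear form
#' `weights %*% utilities`.
#'
#' @param pathways An [enumerate_pathways()] frame.
#' @param config An [analysis_config()].
#' @param discounted Apply the configured discounting (`TRUE`) or plain
#'   durations (`FALSE`)?
#' @param values Optional values list (to pick up varied `age_start` or
#'   `discount_rate`, e.g. in one-way sensitivity analysis).
#' @return Matrix, `nrow(pathways)` by utility parameters.
#' @export
qaly_weight_matrix <- function(pathways, config, discounted = TRUE,
                               values = NULL) {
  u_names <- grep("^u_", required_parameter_names(), value = TRUE)
  age <- if (!is.null(values$age_start)) unique(values$age_start) else 21
  rate <- if (!is.null(values$discount_rate)) unique(values$discount_rate)
    else config$discount_rate
  if (length(age) > 1 || length(rate) > 1)
    stop("qaly_weight_matrix needs a single age/discount-rate value")
  horizon_years <- config$life_expectancy - age
  if (horizon_years <= 0) stop("event age exceeds life expectancy")
  w <- matrix(0, nrow(pathways), length(u_names),
              dimnames = list(pathways$pathway_id, u_names))
  cons_short <- identical(config$structure$utility_conservative, "short_term")
  for (i in seq_len(nrow(pathways))) {
    traj <- utility_trajectory(pathways[i, ], horizon_years, cons_short)
    for (j in seq_len(nrow(traj))) {
      wt <- if (discounted)
        discount_weight(traj$t_start[j], traj$t_end[j], rate,
                        config$convention, config$horizon)
      else traj$t_end[j] - traj$t_start[j]
      w[i, traj$utility_param[j]] <- w[i, traj$utility_param[j]] + wt
    }
  }
  w
}

#' Pathway payoff bundle
#'
#' Combines the cost-count and QALY-weight matrices into one payoff object
#' shared by the analytic engine and the microsimulation oracle (single
#' source of truth).
#'
#' @param tree A `txa_tree`.
#' @param pathways Optional pre-enumerated pathways (both arms).
#' @return List with `pathways`, `cost_counts`, `w_disc`, `w_undisc`.
#' @export
build_payoffs <- function(tree, pathways = enumerate_pathways(tree)) {
  config <- tree$config
  values <- model_values(tree)
  list(pathways = pathways,
       cost_counts = cost_count_matrix(pathways, config$structure),
       w_disc = qaly_weight_matrix(pathways, config, TRUE, values),
       w_undisc = qaly_weight_matrix(pathways, config, FALSE, values))
}

#' Cost bundle of one pathway
#'
#' @param payoffs A [build_payoffs()] object.
#' @param values Parameter values (base case by default).
#' @return Data frame per pathway: `health_system`, `out_of_pocket`,
#'   `societal` (INR).
#' @export
pathway_cost <- function(payoffs, values) {
  cost_names <- colnames(payoffs$cost_counts)
  v <- vapply(cost_names, function(nm) {
    if (is.null(values[[nm]])) stop("missing unit cost: ", nm)
    values[[nm]]
  }, numeric(1))
  oop_col <- "cost_oop_childbirth"
  hs_names <- setdiff(cost_names, oop_col)
  hs <- drop(payoffs$cost_counts[, hs_names, drop = FALSE] %*% v[hs_names])
  oop <- payoffs$cost_counts[, oop_col] * v[oop_col]
  data.frame(pathway_id = payoffs$pathways$pathway_id,
             health_system = hs, out_of_pocket = oop, societal = hs + oop,
             stringsAsFactors = FALSE)
}

#' QALYs of each pathway
#'
#' @param payoffs A [build_payoffs()] object.
#' @param values Parameter values.
#' @return Data frame per pathway: `qaly_undisc`, `qaly_disc`.
#' @export
pathway_qaly <- function(payoffs, values) {
  u <- vapply(colnames(payoffs$w_disc), function(nm) values[[nm]], numeric(1))
  data.frame(pathway_id = payoffs$pathways$pathway_id,
             qaly_undisc = drop(payoffs$w_undisc %*% u),
             qaly_disc = drop(payoffs$w_disc %*% u),
             stringsAsFactors = FALSE)
}

#' Full per-pathway payoff table (exportable)
#'
#' @param tree A `txa_tree`.
#' @return Data frame: pathway id, arm, level, type, events, probability,
#'   costs by perspective, discounted/undiscounted QALYs.
#' @export
payoff_table <- function(tree) {
  payoffs <- build_payoffs(tree)
  values <- model_values(tree)
  cbind(payoffs$pathways[, c("pathway_id", "arm", "level", "pph_type",
                             "event_sequence", "terminal_state", "prob")],
        pathway_cost(payoffs, values)[, -1],
        pathway_qaly(payoffs, values)[, -1])
}
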