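#' Patient-level microsimulation through the decision tree
#'
#' Samples `n` individual women through one arm of the tree: at every chance
#' node the cohort is split multinomially according to the branch
#' probabilities evaluated at the supplied values (equivalent to independent
#' per-patient Bernoulli walks, drawn in one pass per node).  Each patient
#' record carries the matched pathway's payoffs exactly — the simulation
#' consumes the same payoff tables as the analytic engine, so discrepancies
#' isolate probability/expectation bugs rather than payoff bugs.
#'
#' @param model A [build_model()] object.
#' @param n Number of simulated patients.
#' @param arm `"soc"` or `"txa"`.
#' @param seed RNG seed.
#' @param values Parameter values (base case by default).
#' @return List of class `txa_microsim`: `records` (one row per patient),
#'   `summary` (means with standard errors), `arm`, `n`, `seed`.
#' @export
simulate_cohort <- function(model, n, arm = c("soc", "txa"),
                            seed = model$config$rng_seed,
                            values = model_values(model$tree)) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  set.seed(seed)
  pw <- model$payoffs$pathways
  # walk the tree splitting the cohort multinomially at each chance node
  counts <- integer(nrow(pw))
  leaf_i <- 0L
  arm_rows <- which(pw$arm == arm)
  walk <- function(node, n_here) {
    if (node$kind == "terminal") {
      leaf_i <<- leaf_i + 1L
      counts[arm_rows[leaf_i]] <<- n_here
      return(invisible())
    }
    probs <- vapply(node$branches, function(b) eval_expr(b$prob, values),
                    numeric(1))
    split <- if (n_here > 0)
      drop(stats::rmultinom(1, n_here, probs)) else integer(length(probs))
    for (i in seq_along(node$branches)) walk(node$branches[[i]]$child,
                                             split[i])
  }
  arm_branch <- Filter(function(b) b$tags$arm == arm, model$tree$root$branches)
  walk(arm_branch[[1]]$child, n)
  stopifnot(leaf_i == length(arm_rows), sum(counts) == n)
  # patient records: pathway assignment in randomized order, payoffs joined
  assignment <- sample(rep.int(arm_rows, counts[arm_rows]))
  costs <- pathway_cost(model$payoffs, values)
  qalys <- pathway_qaly(model$payoffs, values)
  surg <- surgery_counts(pw, model$config$structure$surgeries_count)
  records <- data.frame(
    id = seq_len(n),
    arm = arm,
    facility_level = pw$level[assignment],
    pph_type = pw$pph_type[assignment],
    pathway_id = pw$pathway_id[assignment],
    event_sequence = pw$event_sequence[assignment],
    terminal_state = pw$terminal_state[assignment],
    cost_health_system = costs$health_system[assignment],
    cost_societal = costs$societal[assignment],
    qaly_disc = qalys$qaly_disc[assignment],
    qaly_undisc = qalys$qaly_undisc[assignment],
    surgeries = surg[assignment],
    icu = as.numeric(pw$icu[assignment]),
    dead = as.numeric(pw$terminal_state[assignment] == "dead"),
    stringsAsFactors = FALSE)
  stat <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  summary <- as.data.frame(rbind(
    cost_societal = stat(records$cost_societal),
    cost_health_system = stat(records$cost_health_system),
    qaly_disc = stat(records$qaly_disc),
    qaly_undisc = stat(records$qaly_undisc),
    deaths = stat(records$dead),
    surgeries = stat(records$surgeries),
    icu = stat(records$icu)))
  summary$statistic <- rownames(summary)
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary[, c(3, 1, 2)],
                 arm = arm, n = n, seed = seed,
                 pathway_counts = stats::setNames(counts[arm_rows],
                                                  pw$pathway_id[arm_rows])),
            class = "txa_microsim")
}

#' @export
print.txa_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation: %d patients, %s arm (seed %d)\n",
              x$n, x$arm, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Compare microsimulation means to the analytic tree expectations
#'
#' Per statistic, reports `|simulated - analytic| / SE` and passes when the
#' deviation is within the tolerance (in standard-error multiples).
#'
#' @param sim A [simulate_cohort()] result.
#' @param model The same [build_model()] object.
#' @param tolerance Allowed deviation in SE multiples (default 4).
#' @param values Parameter values (must match the simulation's).
#' @return Data frame with columns `statistic`, `simulated`, `analytic`,
#'   `se`, `z`, `pass`; attribute `ok` is the conjunction.
#' @export
compare_to_tree <- function(sim, model, tolerance = 4,
                            values = model_values(model$tree)) {
  ex <- arm_expectations(model, values)[[sim$arm]]
  analytic <- c(cost_societal = ex$cost_hs + ex$cost_oop,
                cost_health_system = ex$cost_hs,
                qaly_disc = ex$qaly_disc,
                qaly_undisc = ex$qaly_undisc,
                deaths = ex$deaths,
                surgeries = ex$surgeries,
                icu = ex$icu)
  out <- sim$summary
  out$analytic <- unname(analytic[out$statistic])
  out$z <- ifelse(out$se > 0, abs(out$mean - out$analytic) / out$se,
                  ifelse(out$mean == out$analytic, 0, Inf))
  out$pass <- out$z <= tolerance
  names(out)[names(out) == "mean"] <- "simulated"
  attr(out, "ok") <- all(out$pass)
  out
}
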