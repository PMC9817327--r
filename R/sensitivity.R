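# Incremental results at given values; recomputes QALY weights when the
# variation touches age or the discount rate.
incremental_at <- function(model, values) {
  base_vals <- model_values(model$tree)
  needs_w <- !all(values$age_start == base_vals$age_start) ||
    !all(values$discount_rate == base_vals$discount_rate)
  if (needs_w) {
    w_disc <- qaly_weight_matrix(model$payoffs$pathways, model$config, TRUE,
                                 values)
    w_undisc <- qaly_weight_matrix(model$payoffs$pathways, model$config,
                                   FALSE, values)
  } else {
    w_disc <- model$payoffs$w_disc
    w_undisc <- model$payoffs$w_undisc
  }
  ex <- arm_expectations(model, values, w_disc, w_undisc)
  d_c_soc <- ex$txa$cost_hs + ex$txa$cost_oop -
    ex$soc$cost_hs - ex$soc$cost_oop
  d_c_hs <- ex$txa$cost_hs - ex$soc$cost_hs
  d_q_disc <- ex$txa$qaly_disc - ex$soc$qaly_disc
  d_q_undisc <- ex$txa$qaly_undisc - ex$soc$qaly_undisc
  d_cost <- if (model$config$perspective == "societal") d_c_soc else d_c_hs
  d_qaly <- if (model$config$discounting == "differential") d_q_disc else
    d_q_undisc
  nb <- net_benefit(d_cost, d_qaly, model$config$wtp_threshold)
  list(d_cost_societal = d_c_soc, d_cost_health_system = d_c_hs,
       d_qaly_disc = d_q_disc, d_qaly_undisc = d_q_undisc,
       d_cost = d_cost, d_qaly = d_qaly,
       icur = ifelse(abs(d_qaly) > 0, d_cost / d_qaly, NA_real_),
       nmb = nb$nmb, nhb = nb$nhb)
}

#' One-way sensitivity analysis (tornado)
#'
#' Varies each parameter to its lower and upper limit with all others at
#' base, recording the incremental result on both the ICUR and the NMB
#' scale.  Ranking defaults to NMB swing: the ICUR is a ratio and turns
#' unstable when a variation drives the incremental QALY gain across zero
#' (such entries are flagged).
#'
#' @param model A [build_model()] object.
#' @param result_scale `"nmb"` (default ranking scale) or `"icur"`.
#' @param parameters Optional subset of parameter names.
#' @return Data frame ranked by swing (descending), class `txa_owsa`.
#' @export
run_owsa <- function(model, result_scale = c("nmb", "icur"),
                     parameters = NULL) {
  result_scale <- match.arg(result_scale)
  params <- model$params
  if (is.null(parameters)) parameters <- names(params)
  base_vals <- model_values(model$tree)
  base_inc <- incremental_at(model, base_vals)
  rows <- lapply(parameters, function(nm) {
    p <- params[[nm]]
    at <- function(v) {
      vals <- base_vals
      vals[[nm]] <- v
      incremental_at(model, vals)
    }
    lo <- at(p$low)
    hi <- at(p$high)
    data.frame(
      parameter = nm, low = p$low, high = p$high,
      nmb_low = lo$nmb, nmb_high = hi$nmb,
      icur_low = lo$icur, icur_high = hi$icur,
      swing_nmb = abs(hi$nmb - lo$nmb),
      swing_icur = abs(hi$icur - lo$icur),
      qaly_sign_crossed = sign(lo$d_qaly) != sign(hi$d_qaly),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- if (result_scale == "nmb") out$swing_nmb else out$swing_icur
  key[is.na(key)] <- -Inf
  out <- out[order(-key), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "base_nmb") <- base_inc$nmb
  attr(out, "scale") <- result_scale
  class(out) <- c("txa_owsa", "data.frame")
  out
}

#' Top-of-tornado export
#'
#' @param owsa A [run_owsa()] result.
#' @param n Number of leading parameters (default 10).
#' @export
tornado_table <- function(owsa, n = 10) {
  utils::head(owsa[, c("rank", "parameter", "nmb_low", "nmb_high",
                       "swing_nmb", "qaly_sign_crossed")], n)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every sampled parameter from its fitted distribution (beta for
#' probabilities and utilities, gamma for costs and resource counts,
#' lognormal for relative risks), evaluates both arms under the same draw
#' (common random numbers) and records incremental costs, QALYs and net
#' benefits per draw.  Draws producing any pathway probability outside
#' `[0, 1]` are redrawn and counted.  Reproducible for a fixed seed; one RNG
#' stream with parameter-order-stable sampling.
#'
#' @param model A [build_model()] object.
#' @param n_draws Number of Monte Carlo draws (default from config).
#' @param seed RNG seed (default from config).
#' @return List of class `txa_psa`: `draws` (one row per draw),
#'   `proportion_cost_effective` at the configured threshold, `n_redraws`,
#'   `seed`.
#' @export
run_psa <- function(model, n_draws = model$config$psa_draws,
                    seed = model$config$rng_seed) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  dists <- lapply(model$params, fit_distribution)
  sampled <- names(model$params)[vapply(model$params, function(p)
    p$sample && p$high > p$low, logical(1))]
  draw_all <- function(n) {
    out <- list()
    for (nm in names(model$params)) {
      out[[nm]] <- if (nm %in% sampled) draw_distribution(dists[[nm]], n)
      else rep(model$params[[nm]]$base, n)
    }
    out
  }
  values <- model_values(model$tree)
  draws <- draw_all(n_draws)
  for (nm in names(draws)) values[[nm]] <- draws[[nm]]
  # validity: every pathway probability in [0,1] (mortality expressions are
  # capped, so violations are rare; redraw any offending draws)
  n_redraws <- 0L
  for (iter in 1:100) {
    P <- pathway_prob_matrix(model$payoffs$pathways, values)
    bad <- apply(P < -1e-12 | P > 1 + 1e-12, 2, any)
    if (!any(bad)) break
    n_redraws <- n_redraws + sum(bad)
    redraw <- draw_all(sum(bad))
    for (nm in sampled) values[[nm]][bad] <- redraw[[nm]]
  }
  inc <- incremental_at(model, values)
  icur_class <- mapply(icur_classify, inc$d_cost, inc$d_qaly)
  draws_df <- data.frame(
    draw = seq_len(n_draws),
    d_cost_societal = inc$d_cost_societal,
    d_cost_health_system = inc$d_cost_health_system,
    d_qaly_disc = inc$d_qaly_disc,
    d_qaly_undisc = inc$d_qaly_undisc,
    icur = inc$icur,
    icur_class = icur_class,
    nmb = inc$nmb, nhb = inc$nhb,
    stringsAsFactors = FALSE)
  structure(list(draws = draws_df,
                 proportion_cost_effective = mean(draws_df$nmb > 0),
                 n_redraws = n_redraws,
                 lambda = model$config$wtp_threshold,
                 seed = seed),
            class = "txa_psa")
}

#' @export
print.txa_psa <- function(x, ...) {
  cat(sprintf(
    "PSA: %d draws; %.1f%% cost-effective at threshold %.0f (seed %d)\n",
    nrow(x$draws), 100 * x$proportion_cost_effective, x$lambda, x$seed))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective — the fraction of PSA
#' draws with positive net benefit — across a willingness-to-pay grid.  The
#' curve plateaus, as the threshold grows, at the fraction of draws with a
#' positive incremental QALY gain.
#'
#' @param psa A [run_psa()] result.
#' @param thresholds Threshold grid (INR per QALY); default 0 to three times
#'   the configured threshold in 200 steps.
#' @return Data frame `threshold`, `probability_cost_effective`.
#' @export
ceac <- function(psa, thresholds = seq(0, 3 * psa$lambda, length.out = 201)) {
  stopifnot(nrow(psa$draws) > 0)
  dq <- psa$draws$d_qaly_disc
  dc <- psa$draws$d_cost_societal
  prob <- vapply(thresholds, function(t) mean(dq * t - dc > 0), numeric(1))
  data.frame(threshold = thresholds, probability_cost_effective = prob)
}

#' PSA net-benefit summary
#'
#' Means of net monetary and net health benefit over draws, with 95\%
#' intervals both as empirical 2.5/97.5 percentiles of the draws and as the
#' normal-theory interval of the mean.
#'
#' @param psa A [run_psa()] result.
#' @return Data frame with one row per statistic.
#' @export
psa_summary <- function(psa) {
  stopifnot(nrow(psa$draws) >= 2)
  one <- function(name, x) {
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(statistic = name, mean = mean(x),
               pct_lower = q[1], pct_upper = q[2],
               mean_ci_lower = mean(x) - 1.96 * se,
               mean_ci_upper = mean(x) + 1.96 * se,
               stringsAsFactors = FALSE)
  }
  rbind(one("nmb", psa$draws$nmb), one("nhb", psa$draws$nhb))
}
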