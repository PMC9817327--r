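#' Run the full analysis and write a report bundle
#'
#' Executes, in order: knob calibration (unless a config is supplied), the
#' deterministic base case (both perspectives and discounting modes), one-way
#' sensitivity analysis, probabilistic sensitivity analysis with its
#' acceptability curve, the five-year budget impact, and a microsimulation
#' validation run — then writes CSV/JSON artifacts plus a run manifest with
#' checksums.
#'
#' @param out_dir Output directory (created if missing).
#' @param params A `txa_parameter_set`.
#' @param config Optional [analysis_config()]; when `NULL` the calibrated
#'   configuration from [calibrate_free_knobs()] is used.
#' @param seed Seed overriding the config's.
#' @param psa_draws Number of PSA draws overriding the config's.
#' @param microsim_n Patients in the validation microsimulation.
#' @return Invisibly, a list with all stage results plus the manifest.
#' @export
run_all <- function(out_dir = "txacea-report",
                    params = load_parameters(),
                    config = NULL,
                    seed = NULL, psa_draws = NULL,
                    microsim_n = 200000) {
  calibration <- NULL
  if (is.null(config)) {
    message("* calibrating free structural knobs")
    calibration <- calibrate_free_knobs(params)
    config <- calibration$config
  }
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  if (!is.null(psa_draws)) config$psa_draws <- psa_draws
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_model(params, config)
  v <- validate_tree(model$tree)
  if (!v$ok) stop("tree validation failed; see validate_tree()")

  message("* base case")
  cea <- run_base_case(model)
  message("* one-way sensitivity analysis")
  owsa <- run_owsa(model)
  message("* probabilistic sensitivity analysis (",
          config$psa_draws, " draws)")
  psa <- run_psa(model)
  if (psa$n_redraws > 0) message("  redraws: ", psa$n_redraws)
  ce_curve <- ceac(psa)
  message("* budget impact")
  bia <- run_bia(schedule = default_uptake_schedule(),
                 cost_soc = bia_cost_inputs(model, cea)$cost_soc,
                 cost_txa = bia_cost_inputs(model, cea)$cost_txa,
                 increment = bia_cost_inputs(model, cea)$increment)
  message("* microsimulation validation (n = ", microsim_n, ")")
  sims <- lapply(c(soc = "soc", txa = "txa"), function(a)
    simulate_cohort(model, microsim_n, a, seed = config$rng_seed + 1L))
  checks <- lapply(sims, compare_to_tree, model = model)

  write1 <- function(obj, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    path
  }
  artifacts <- c(
    write1(cea_as_table(cea), "base_case.csv"),
    write1(cea$events, "clinical_events.csv"),
    write1(payoff_table(model$tree), "pathways.csv"),
    write1(as.data.frame(owsa), "tornado.csv"),
    write1(psa$draws, "psa_draws.csv"),
    write1(psa_summary(psa), "psa_summary.csv"),
    write1(ce_curve, "ceac.csv"),
    write1(as.data.frame(bia), "budget_impact.csv"),
    write1(do.call(rbind, lapply(names(checks), function(a)
      cbind(arm = a, checks[[a]]))), "microsim_check.csv"))
  if (!is.null(calibration))
    artifacts <- c(artifacts, write1(calibration$residuals,
                                     "calibration_residuals.csv"))
  manifest <- run_manifest(config, artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calibration = calibration, config = config, model = model,
                 cea = cea, owsa = owsa, psa = psa, ceac = ce_curve,
                 bia = bia, microsim = sims, microsim_checks = checks,
                 manifest = manifest))
}

# Results block shaped like the published costs/consequences table.
cea_as_table <- function(cea) {
  a <- cea$arms
  fx <- cea$config$exchange_rate
  ic <- cea$incremental
  row <- function(item, txa, soc) data.frame(
    item = item, txa = txa, soc = soc, stringsAsFactors = FALSE)
  rbind(
    row("total_cost_societal_inr", a$total_cost_societal[a$arm == "txa"],
        a$total_cost_societal[a$arm == "soc"]),
    row("cost_per_patient_societal_inr", a$cost_societal[a$arm == "txa"],
        a$cost_societal[a$arm == "soc"]),
    row("cost_per_patient_societal_usd",
        a$cost_societal[a$arm == "txa"] / fx,
        a$cost_societal[a$arm == "soc"] / fx),
    row("total_cost_health_system_inr",
        a$total_cost_health_system[a$arm == "txa"],
        a$total_cost_health_system[a$arm == "soc"]),
    row("cost_per_patient_health_system_inr",
        a$cost_health_system[a$arm == "txa"],
        a$cost_health_system[a$arm == "soc"]),
    row("qaly_undiscounted", a$qaly_undisc[a$arm == "txa"],
        a$qaly_undisc[a$arm == "soc"]),
    row("qaly_discounted", a$qaly_disc[a$arm == "txa"],
        a$qaly_disc[a$arm == "soc"]),
    row("icur_societal_undiscounted_inr_per_qaly",
        ic$icur_societal_undiscounted$value, NA),
    row("icur_societal_differential_inr_per_qaly",
        ic$icur_societal_differential$value, NA),
    row("icur_health_system_undiscounted_inr_per_qaly",
        ic$icur_health_system_undiscounted$value, NA),
    row("icur_health_system_differential_inr_per_qaly",
        ic$icur_health_system_differential$value, NA))
}

#' Run manifest
#'
#' Configuration hash, seed, package version, timestamp and artifact
#' checksums; identical configuration and seed give identical hashes for
#' the deterministic artifacts.
#'
#' @param config An [analysis_config()].
#' @param artifacts Character vector of file paths.
#' @return List (JSON-serializable).
#' @export
run_manifest <- function(config, artifacts = character()) {
  cfg_str <- paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n")
  list(package = "txacea",
       version = as.character(utils::packageVersion("txacea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = config$rng_seed,
       config_hash = checksum(cfg_str),
       artifacts = lapply(artifacts, function(p)
         list(file = basename(p), sha = checksum_file(p))))
}

checksum <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

checksum_file <- function(path) unname(tools::md5sum(path))
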