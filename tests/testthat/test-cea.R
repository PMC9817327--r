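test_that("identical arm parameters give indifference", {
  model <- base_model()
  vals <- model_values(model$tree)
  vals$p_further_txa <- vals$p_further_soc
  vals$rr_death_bleed_txa <- 1
  vals$rr_death_all_txa <- 1
  for (lvl in c("primary", "secondary", "tertiary"))
    vals[[paste0("cost_med_txa_", lvl)]] <- vals[[paste0("cost_med_soc_", lvl)]]
  cea <- run_base_case(model, vals)
  expect_equal(cea$incremental$d_cost_societal, 0, tolerance = 1e-9)
  expect_equal(cea$incremental$d_qaly_disc, 0, tolerance = 1e-12)
  expect_equal(cea$incremental$icur_societal_differential$class,
               "indifferent")
})

test_that("ICUR, NMB and NHB satisfy their defining identities", {
  # plug-in example: published per-patient block
  expect_equal((6607 - 6486) / (20.250 - 20.168), 1476, tolerance = 1e-3)
  nb <- net_benefit(100, 1, 145742)
  expect_equal(nb$nmb, 145642)
  expect_equal(nb$nhb, 1 - 100 / 145742, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:1000) {
    dc <- runif(1, -500, 500)
    dq <- runif(1, -0.2, 0.2)
    lambda <- runif(1, 1e4, 1e6)
    nb <- net_benefit(dc, dq, lambda)
    expect_equal(nb$nmb, dq * lambda - dc, tolerance = 1e-12)
    expect_equal(nb$nhb, dq - dc / lambda, tolerance = 1e-12)
    expect_equal(nb$nmb > 0, nb$nhb > 0)
    if (dq > 0) expect_equal(nb$nmb > 0, dc / dq < lambda)
  }
})

test_that("the base-case ICUR times the QALY gain reproduces the cost gain", {
  cea <- base_cea()
  ic <- cea$incremental$icur_societal_differential
  expect_equal(ic$value * cea$incremental$d_qaly_disc,
               cea$incremental$d_cost_societal, tolerance = 1e-6)
})

test_that("dominance is classified instead of reporting a misleading ratio", {
  expect_equal(txacea:::icur_classify(-10, 0.1), "dominant")
  expect_equal(txacea:::icur_classify(10, -0.1), "dominated")
  expect_equal(txacea:::icur_classify(10, 0.1), "trade-off")
  expect_equal(txacea:::icur_classify(0, 0), "indifferent")
})

test_that("cohort totals scale linearly and per-patient results do not", {
  model <- base_model()
  cfg2 <- model$config
  cfg2$annual_cohort <- 2 * cfg2$annual_cohort
  model2 <- build_model(base_params(), cfg2)
  a <- run_base_case(model)
  b <- run_base_case(model2)
  expect_equal(b$arms$total_cost_societal, 2 * a$arms$total_cost_societal)
  expect_equal(b$arms$cost_societal, a$arms$cost_societal)
  expect_equal(b$incremental$icur_societal_differential$value,
               a$incremental$icur_societal_differential$value)
  expect_equal(b$events$txa, 2 * a$events$txa)
})

test_that("per-100k rescaling matches the published arithmetic", {
  expect_equal(per_100k(1990, 510915), 389)
  expect_equal(per_100k(905, 510915), 177)
  expect_equal(per_100k(655, 510915), 128)
  expect_equal(per_100k(0, 510915), 0)
  expect_error(per_100k(1, 0))
})

test_that("clinical event counts sum dead-terminal pathway mass", {
  model <- base_model()
  ev <- clinical_event_counts(model)
  pw <- model$payoffs$pathways
  dead_mass <- sum(pw$prob[pw$arm == "soc" & pw$terminal_state == "dead"])
  expect_equal(ev$soc[ev$event == "maternal_deaths"],
               model$config$annual_cohort * dead_mass, tolerance = 1e-9)
  expect_equal(ev$averted, ev$soc - ev$txa)
})

test_that("calibration recovers a known configuration (self-consistency)", {
  params <- base_params()
  truth <- analysis_config(
    facility_mix = c(primary = 0.1, secondary = 0.6, tertiary = 0.3),
    horizon = 25)
  model <- build_model(params, truth)
  ex <- txacea:::arm_expectations(model)
  summ <- txacea:::calibration_summary(ex, truth$annual_cohort, 1.03^-25)
  targets <- calibration_targets()
  targets$value <- unname(summ[paste(targets$target, targets$arm, sep = ".")])
  # restrict the switch search to the generating structure for speed
  sg <- as.data.frame(truth$structure[c("traumatic_gated",
                                        "extra_ipd_further",
                                        "escalation_referral", "oop",
                                        "utility_conservative", "mortality")])
  cal <- calibrate_free_knobs(params, targets, grid_step = 0.1,
                              switch_grid = sg)
  expect_lt(cal$score, 5e-3)
  expect_equal(unname(cal$config$facility_mix), c(0.1, 0.6, 0.3),
               tolerance = 0.02)
  expect_equal(cal$horizon, 25, tolerance = 0.1)
  expect_true(all(abs(cal$residuals$rel_err) < 0.01))
})
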