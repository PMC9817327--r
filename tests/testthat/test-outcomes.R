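test_that("discount weights match closed forms", {
  expect_equal(discount_weight(0, 10, 0), 10)
  expect_equal(discount_weight(0, 49.7, 0.03, "continuous"),
               (1 - exp(-0.03 * 49.7)) / 0.03, tolerance = 1e-12)
  expect_equal(discount_weight(0, 49.7, 0.03, "continuous"), 25.83,
               tolerance = 1e-3)
  w <- discount_weight(0, 1, 0.03, "annual")
  expect_gt(w, 1.03^-1)
  expect_lt(w, 1)
  expect_equal(discount_weight(0, 10, 0.03, "aggregate_horizon", 26.958),
               10 * 1.03^-26.958)
  expect_error(discount_weight(0, 1, -0.01), "negative")
})

test_that("utility trajectories cover the full remaining life expectancy", {
  model <- base_model()
  pw <- model$payoffs$pathways
  h <- 70.7 - 21
  for (i in seq_len(nrow(pw))) {
    traj <- utility_trajectory(pw[i, ], h)
    expect_equal(sum(traj$t_end - traj$t_start), h, tolerance = 1e-9)
    expect_equal(traj$t_start[1], 0)
  }
  dead <- pw[pw$terminal_state == "dead", ][1, ]
  expect_equal(utility_trajectory(dead, h)$utility_param, "u_death")
})

test_that("pathway QALYs match piecewise arithmetic oracles", {
  model <- base_model()
  payoffs <- model$payoffs
  vals <- model_values(model$tree)
  pw <- payoffs$pathways
  q <- pathway_qaly(payoffs, vals)
  # dead pathways earn zero
  expect_true(all(q$qaly_undisc[pw$terminal_state == "dead"] == 0))
  expect_true(all(q$qaly_disc[pw$terminal_state == "dead"] == 0))
  # uncomplicated medical discharge: 0.93 x 49.7 undiscounted
  i <- which(pw$arm == "soc" & pw$terminal_state == "alive" & !pw$icu &
               pw$control == "medical" & !pw$devasc & !pw$hyst)[1]
  expect_equal(q$qaly_undisc[i], 0.93 * 49.7, tolerance = 1e-9)
  expect_equal(q$qaly_undisc[i], 46.221, tolerance = 1e-9)
  # hysterectomy survivor without ICU: 42 d short-term then long-term
  j <- which(pw$terminal_state == "alive" & pw$hyst & !pw$icu)[1]
  oracle <- 0.560 * (42 / 365.25) + 0.880 * (49.7 - 42 / 365.25)
  expect_equal(q$qaly_undisc[j], oracle, tolerance = 1e-9)
  # discounted never exceeds undiscounted at positive rate
  alive <- pw$terminal_state == "alive"
  expect_true(all(q$qaly_disc[alive] < q$qaly_undisc[alive]))
})

test_that("unit utilities at zero rate give remaining life expectancy", {
  model <- base_model()
  vals <- model_values(model$tree)
  for (nm in grep("^u_", names(vals), value = TRUE)) vals[[nm]] <- 1
  cfg0 <- analysis_config(discount_rate = 0,
                          facility_mix = model$config$facility_mix,
                          structure = model$config$structure)
  m0 <- build_model(base_params(), cfg0)
  vals0 <- model_values(m0$tree)
  for (nm in grep("^u_", names(vals0), value = TRUE)) vals0[[nm]] <- 1
  q <- pathway_qaly(m0$payoffs, vals0)
  alive <- m0$payoffs$pathways$terminal_state == "alive"
  expect_equal(q$qaly_undisc[alive], rep(49.7, sum(alive)), tolerance = 1e-9)
})

test_that("pathway costs assemble the printed unit-cost packages", {
  model <- base_model()
  payoffs <- model$payoffs
  vals <- model_values(model$tree)
  pw <- payoffs$pathways
  costs <- pathway_cost(payoffs, vals)
  # TXA arm, secondary level, controlled medically, no ICU:
  # medical management with TXA + one indoor admission
  i <- which(pw$arm == "txa" & pw$level == "secondary" &
               pw$control == "medical" & !pw$further & !pw$icu &
               pw$terminal_state == "alive")[1]
  expect_equal(costs$health_system[i], 1685 + 2230)
  # same pathway under standard care: medical component 1475, difference 210
  j <- which(pw$arm == "soc" & pw$level == "secondary" &
               pw$control == "medical" & !pw$further & !pw$icu &
               pw$terminal_state == "alive")[1]
  expect_equal(costs$health_system[j], 1475 + 2230)
  expect_equal(costs$health_system[i] - costs$health_system[j], 210)
  # primary presenters carry the referral fee
  k <- which(pw$level == "primary")
  counts <- cost_count_matrix(pw, model$config$structure)
  expect_true(all(counts[k, "cost_referral"] >= 1))
  # ICU admission from a non-tertiary facility adds a second referral
  k2 <- which(pw$level == "secondary" & pw$icu)
  expect_true(all(counts[k2, "cost_referral"] >= 1))
  expect_true(all(counts[pw$icu, "cost_icu_tertiary"] == 1))
})

test_that("out-of-pocket spending separates the societal perspective", {
  model <- base_model()
  costs <- pathway_cost(model$payoffs, model_values(model$tree))
  expect_true(all(costs$societal == costs$health_system + costs$out_of_pocket))
  expect_true(all(costs$out_of_pocket >= 0))
  # under the all-cases switch every pathway carries the childbirth OOP
  st <- model_structure(oop = "all_cases")
  counts <- cost_count_matrix(model$payoffs$pathways, st)
  expect_true(all(counts[, "cost_oop_childbirth"] >= 1))
})

test_that("societal minus health-system equals OOP times episode weight per arm", {
  model <- base_model()
  ex <- txacea:::arm_expectations(model)
  pw <- model$payoffs$pathways
  counts <- model$payoffs$cost_counts
  P <- pathway_prob_matrix(pw, model_values(model$tree))
  for (a in c("soc", "txa")) {
    idx <- pw$arm == a
    weight <- sum(P[idx, 1] * counts[idx, "cost_oop_childbirth"])
    expect_equal(ex[[a]]$cost_oop, 3015 * weight, tolerance = 1e-9)
  }
})
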