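test_that("one-way analysis is deterministic with zero-width parameters last", {
  model <- base_model()
  owsa <- cached("owsa", run_owsa(model))
  owsa2 <- run_owsa(model)
  expect_equal(as.data.frame(owsa), as.data.frame(owsa2))
  expect_equal(owsa$swing_nmb[owsa$parameter == "u_death"], 0)
  expect_equal(owsa$rank[owsa$parameter == "u_death"], nrow(owsa))
  expect_setequal(owsa$rank, seq_len(nrow(owsa)))
})

test_that("the TXA effectiveness relative risks dominate the tornado", {
  owsa <- cached("owsa", run_owsa(base_model()))
  top <- tornado_table(owsa, 10)
  expect_true(any(c("p_further_txa", "p_further_soc", "rr_death_all_txa")
                  %in% top$parameter[1:5]))
})

test_that("a cost-only parameter's NMB swing equals its width times its weight", {
  # linearity oracle: NMB is linear in any unit cost with everything else fixed
  model <- base_model()
  p <- model$params$cost_icu_tertiary
  owsa <- cached("owsa", run_owsa(model))
  row <- owsa[owsa$parameter == "cost_icu_tertiary", ]
  pw <- model$payoffs$pathways
  P <- pathway_prob_matrix(pw, model_values(model$tree))
  counts <- model$payoffs$cost_counts[, "cost_icu_tertiary"]
  # incremental ICU-cost weight between arms (TXA uses less ICU care)
  w_txa <- sum(P[pw$arm == "txa", 1] * counts[pw$arm == "txa"])
  w_soc <- sum(P[pw$arm == "soc", 1] * counts[pw$arm == "soc"])
  oracle <- abs((p$high - p$low) * (w_txa - w_soc))
  expect_equal(row$swing_nmb, oracle, tolerance = 1e-9)
})

test_that("PSA is seed-deterministic and collapses to the base case when fixed", {
  model <- base_model()
  a <- run_psa(model, 200, seed = 99)
  b <- run_psa(model, 200, seed = 99)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(model, 200, seed = 100)
  expect_false(identical(a$draws$nmb, c_$draws$nmb))

  # all-fixed parameter set: every draw equals the deterministic base case
  fixed_params <- base_params()
  for (nm in names(fixed_params)) fixed_params[[nm]]$sample <- FALSE
  fm <- build_model(fixed_params, model$config)
  psa_fixed <- run_psa(fm, 5, seed = 1)
  cea <- run_base_case(fm)
  expect_equal(psa_fixed$draws$nmb, rep(cea$incremental$nmb, 5),
               tolerance = 1e-9)
  expect_equal(psa_fixed$draws$d_qaly_disc,
               rep(cea$incremental$d_qaly_disc, 5), tolerance = 1e-12)
})

test_that("PSA draws stay inside parameter domains", {
  model <- base_model()
  psa <- cached("psa2k", run_psa(model, 2000, seed = 3))
  expect_equal(nrow(psa$draws), 2000)
  expect_equal(psa$n_redraws, 0)
  expect_true(all(is.finite(psa$draws$nmb)))
})

test_that("the CEAC has its denominator, threshold and plateau anchors", {
  psa <- cached("psa2k", run_psa(base_model(), 2000, seed = 3))
  cc <- ceac(psa, thresholds = c(0, psa$lambda, 1e9))
  expect_equal(cc$probability_cost_effective[1],
               mean(psa$draws$d_cost_societal < 0))
  expect_equal(cc$probability_cost_effective[2],
               psa$proportion_cost_effective)
  expect_equal(cc$probability_cost_effective[3],
               mean(psa$draws$d_qaly_disc > 0), tolerance = 1e-3)
  expect_true(all(cc$probability_cost_effective >= 0 &
                    cc$probability_cost_effective <= 1))
})

test_that("proportion cost-effective equals the positive-NMB fraction", {
  psa <- cached("psa2k", run_psa(base_model(), 2000, seed = 3))
  expect_equal(psa$proportion_cost_effective, mean(psa$draws$nmb > 0))
})

test_that("net-benefit summaries degenerate correctly and match analytics", {
  psa <- cached("psa2k", run_psa(base_model(), 2000, seed = 3))
  s <- psa_summary(psa)
  expect_equal(s$mean[s$statistic == "nmb"], mean(psa$draws$nmb))
  # constant draws: zero-width percentile interval
  const <- psa
  const$draws <- psa$draws[rep(1, 10), ]
  s0 <- psa_summary(const)
  expect_equal(s0$pct_lower, s0$pct_upper)
  expect_equal(s0$mean_ci_lower, s0$mean_ci_upper)
})
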