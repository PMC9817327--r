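test_that("the base tree validates and both arms are structurally symmetric", {
  model <- base_model()
  v <- validate_tree(model$tree)
  expect_true(v$ok)
  expect_length(v$dangling_refs, 0)
  pw <- model$payoffs$pathways
  expect_equal(sum(pw$arm == "soc"), sum(pw$arm == "txa"))
  # identical topology: event signatures match pairwise in enumeration order
  sig <- function(a) paste(pw$level, pw$pph_type, pw$event_sequence)[pw$arm == a]
  expect_equal(sig("soc"), sig("txa"))
})

test_that("pathway probabilities conserve mass at base values and random draws", {
  model <- base_model()
  pw <- model$payoffs$pathways
  for (a in c("soc", "txa"))
    expect_equal(sum(pw$prob[pw$arm == a]), 1, tolerance = 1e-9)
  for (seed in 1:5) {
    vals <- random_values(model, seed)
    P <- pathway_prob_matrix(pw, vals)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
    for (a in c("soc", "txa"))
      expect_equal(sum(P[pw$arm == a, 1]), 1, tolerance = 1e-9)
    expect_true(validate_tree(model$tree, vals)$ok)
  }
})

test_that("neutralizing the TXA-specific parameters makes the arms identical", {
  model <- base_model()
  vals <- model_values(model$tree)
  vals$p_further_txa <- vals$p_further_soc
  vals$rr_death_bleed_txa <- 1
  vals$rr_death_all_txa <- 1
  pw <- model$payoffs$pathways
  P <- pathway_prob_matrix(pw, vals)
  expect_equal(P[pw$arm == "soc", 1], P[pw$arm == "txa", 1],
               tolerance = 1e-12)
})

test_that("degenerate parameter settings zero out the expected branches", {
  model <- base_model()
  pw <- model$payoffs$pathways
  # all-atonic: traumatic pathways carry no probability
  vals <- model_values(model$tree, list(p_atonic = 1))
  P <- pathway_prob_matrix(pw, vals)
  expect_true(all(P[pw$pph_type == "traumatic", 1] == 0))
  # perfect UBT and no direct hysterectomy: no hysterectomy mass via UBT
  vals <- model_values(model$tree,
                       list(p_ubt_effective = 1, p_direct_hyst = 0))
  P <- pathway_prob_matrix(pw, vals)
  idx <- pw$ubt & pw$hyst
  expect_true(all(P[idx, 1] == 0))
})

test_that("lowering the TXA further-intervention risk never increases surgical mass", {
  model <- base_model()
  pw <- model$payoffs$pathways
  surg_mass <- function(p_further) {
    vals <- model_values(model$tree, list(p_further_txa = p_further))
    P <- pathway_prob_matrix(pw, vals)
    sum(P[pw$arm == "txa" & (pw$devasc | pw$hyst), 1])
  }
  masses <- vapply(seq(0.3, 0.05, by = -0.05), surg_mass, numeric(1))
  expect_true(all(diff(masses) <= 1e-12))
})

test_that("validate_tree flags broken probabilities and orphan references", {
  model <- base_model()
  vals <- model_values(model$tree, list(p_atonic = 1.2))
  v <- validate_tree(model$tree, vals)
  expect_false(v$ok)
  expect_true(any(!v$node_report$ok))
  vals2 <- model_values(model$tree)
  vals2$p_atonic <- NULL
  expect_error(validate_tree(model$tree, vals2))
})

test_that("pathway enumeration is deterministic with stable ordering", {
  model <- base_model()
  a <- enumerate_pathways(model$tree)
  b <- enumerate_pathways(model$tree)
  expect_identical(a, b)
  expect_identical(a$pathway_id, unique(a$pathway_id))
})

test_that("the tree exports to a versioned nested structure", {
  lst <- tree_as_list(base_model()$tree)
  expect_equal(lst$format_version, "1.0")
  expect_equal(lst$root$kind, "decision")
  expect_length(lst$root$branches, 2)
})
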