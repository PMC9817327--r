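test_that("limit rule fills 20% bounds, capping probabilities and utilities at 1", {
  p <- parameter("p_atonic", "probability", 0.80, limit_rule = "assumed_20pct")
  expect_equal(c(p$low, p$high), c(0.64, 0.96))

  z <- parameter("u_death", "utility", 0, limit_rule = "assumed_20pct")
  expect_equal(c(z$low, z$high), c(0, 0))

  u <- parameter("u_discharge", "utility", 0.93, limit_rule = "assumed_20pct")
  expect_equal(u$high, 1)  # 1.116 capped
  expect_equal(u$low, 0.744)
})

test_that("parameter invariants are enforced", {
  expect_error(parameter("x", "probability", 1.4, 1.2, 1.6), "\\[0, 1\\]")
  expect_error(parameter("x", "cost", 100, 120, 150), "outside")
  expect_error(parameter("x", "relative_risk", -1, -1, 2), "positive")
})

test_that("the packaged table loads with every required parameter", {
  params <- base_params()
  expect_s3_class(params, "txa_parameter_set")
  expect_true(all(required_parameter_names() %in% names(params)))
  expect_equal(params$p_ubt_effective$base, 0.92)
  expect_equal(params$p_ubt_effective$low, 0.74)
  expect_equal(params$cost_referral$base, 1096)
  expect_equal(params$u_death$base, 0)
})

test_that("malformed and incomplete tables are reported collectively", {
  tf <- tempfile(fileext = ".csv")
  writeLines("name,role,base,low,high,limit_rule", tf)
  expect_error(load_parameters(tf), "missing required parameters")
  df <- utils::read.csv(default_parameter_file())
  df$base[df$name == "p_atonic"] <- "eighty"
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(load_parameters(tf), "p_atonic")
})

test_that("load -> serialize -> load round trip is idempotent", {
  params <- base_params()
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(params), tf, row.names = FALSE)
  again <- load_parameters(tf)
  expect_equal(as.data.frame(again), as.data.frame(params),
               ignore_attr = TRUE)
})

test_that("fitted distributions recover the base value as centre", {
  # symmetric beta keeps its mean
  p <- parameter("p", "probability", 0.5, 0.402, 0.598)
  d <- fit_distribution(p)
  expect_equal(d$family, "beta")
  expect_equal(distribution_centre(d), 0.5, tolerance = 1e-6)
  # lognormal centred on the median
  rr <- parameter("rr", "relative_risk", 0.69, 0.52, 0.91)
  drr <- fit_distribution(rr)
  expect_equal(drr$family, "lognormal")
  expect_equal(distribution_centre(drr), 0.69, tolerance = 1e-6)
  # gamma by method of moments: shape = mean^2/var, scale = var/mean
  g <- parameter("c", "cost", 1096, 876, 1315)
  dg <- fit_distribution(g)
  sd_target <- (1315 - 876) / 3.92
  expect_equal(dg$family, "gamma")
  expect_equal(unname(dg$pars["shape"] * dg$pars["scale"]), 1096,
               tolerance = 1e-9)
  expect_equal(unname(sqrt(dg$pars["shape"]) * dg$pars["scale"]), sd_target,
               tolerance = 1e-9)
})

test_that("sampled draws respect domains and recover means within 3 SE", {
  set.seed(42)
  n <- 1e5
  for (p in base_params()) {
    if (!p$sample || p$high <= p$low) next
    d <- fit_distribution(p)
    if (d$family == "fixed") next
    x <- draw_distribution(d, n)
    if (d$family == "beta") expect_true(all(x >= 0 & x <= 1))
    if (d$family == "gamma") expect_true(all(x >= 0))
    if (d$family == "lognormal") expect_true(all(x > 0))
    centre <- if (d$family == "lognormal") stats::median(x) else mean(x)
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(centre - p$base), max(3 * se, 1.253 * 3 * se),
              label = paste(p$name, "centre recovery"))
  }
})

test_that("relative risk matches its closed form and a brute-force oracle", {
  expect_equal(relative_risk(10, 100, 10, 100)$base, 1)
  expect_equal(relative_risk(20, 200, 20, 100)$base, 0.5)
  rr <- relative_risk(10, 100, 20, 100)
  expect_equal(rr$base, 0.5)
  expect_equal(rr$low, 0.2466, tolerance = 1e-3)
  expect_equal(rr$high, 1.0138, tolerance = 1e-3)

  set.seed(7)
  for (i in 1:1000) {
    n1 <- sample(10:500, 1); n0 <- sample(10:500, 1)
    e1 <- sample(1:n1, 1); e0 <- sample(1:n0, 1)
    # brute force: risks as means of explicit indicator vectors
    risk1 <- mean(rep(c(1, 0), c(e1, n1 - e1)))
    risk0 <- mean(rep(c(1, 0), c(e0, n0 - e0)))
    expect_equal(relative_risk(e1, n1, e0, n0)$base, risk1 / risk0,
                 tolerance = 1e-12)
  }
})

test_that("degenerate 2x2 inputs are rejected or flagged", {
  expect_error(relative_risk(5, 100, 0, 100), "control")
  expect_warning(rr0 <- relative_risk(0, 100, 5, 100), "CI unavailable")
  expect_lt(rr0$base, 1e-10)
})
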