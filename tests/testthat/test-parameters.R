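test_that("beta and gamma moment matching is exact", {
  expect_equal(fit_beta(0.5, 0.05), c(alpha = 49.5, beta = 49.5))
  expect_equal(fit_gamma(100, 10), c(shape = 100, scale = 1))

  # round-trip: fitted moments reproduce (mean, se) to 1e-9 relative
  cases <- expand.grid(m = c(0.05, 0.4, 0.85, 0.99), cv = c(0.02, 0.1, 0.3))
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; se <- cases$cv[i] * m
    if (se^2 >= m * (1 - m)) next
    ab <- fit_beta(m, se)
    mean_fit <- ab[["alpha"]] / sum(ab)
    var_fit <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
    expect_equal(mean_fit, m, tolerance = 1e-9)
    expect_equal(sqrt(var_fit), se, tolerance = 1e-9)
    sh <- fit_gamma(m * 1000, se * 1000)
    expect_equal(sh[["shape"]] * sh[["scale"]], m * 1000, tolerance = 1e-9)
    expect_equal(sqrt(sh[["shape"]]) * sh[["scale"]], se * 1000, tolerance = 1e-9)
  }
  expect_error(fit_beta(0.5, 0.6), "infeasible")
  expect_error(fit_gamma(-1, 1), "mean > 0")
})

test_that("sampled draws reproduce the requested mean", {
  d <- dist_spec("beta", 0.85, 0.03)
  x <- withr::with_seed(1, draw_dist(d, 1e6))
  expect_lt(abs(mean(x) - 0.85), 3 * 0.03 / sqrt(1e6))
  g <- dist_spec("gamma", 350, 35)
  y <- withr::with_seed(2, draw_dist(g, 1e6))
  expect_lt(abs(mean(y) - 350), 3 * 35 / sqrt(1e6))
  # degenerate limit: zero se concentrates at the mean
  expect_equal(draw_dist(dist_spec("gamma", 350, 0), 10), rep(350, 10))
})

test_that("parameter files round-trip and defaults fill in", {
  ps <- generate_parameter_set("base_like")
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(ps, f1)
  p1 <- load_parameters(f1)
  save_parameters(p1, f2)
  p2 <- load_parameters(f2)
  expect_equal(p2, p1)
  expect_equal(p1$arpi_abi_share, 0.5)
  expect_equal(p1$wtp, 80000)

  # minimal config: only the lines block; every analysis setting defaulted
  minimal <- list(lines = yaml::read_yaml(f1)$lines)
  f3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(minimal, f3)
  pm <- load_parameters(f3)
  expect_equal(pm$arpi_abi_share, 0.5)
  expect_equal(pm$wtp, 80000)
  expect_equal(pm$discount_rate_costs, 0.04)
  expect_equal(pm$discount_rate_effects, 0.015)
  expect_equal(pm$ctdna_ppv$mean, 0.85)
  expect_equal(pm$ctdna_cost_per_sample$mean, 350)
  expect_equal(pm$ctdna_n_samples, 3L)
})

test_that("validation names the offending field", {
  ps <- toy_params()
  bad <- ps
  bad$lines$docetaxel$utility <- list(kind = "fixed", mean = 1.2, se = 0)
  class(bad$lines$docetaxel$utility) <- "dist_spec"
  expect_error(validate_parameters(bad), "lines.docetaxel.utility")
  bad2 <- ps
  bad2$lines$arpi_durable_responder$os <-
    surv_spec("exponential_median", median = 10)
  expect_error(validate_parameters(bad2), "arpi_durable_responder")
  expect_error(parameter_set(ps$lines, wtp = -5), "wtp")
  expect_error(parameter_set(ps$lines[-1]), "treatment line missing")
})

test_that("sample_parameters is deterministic, schema-preserving, in-support", {
  ps <- generate_parameter_set("base_like")
  s1 <- sample_parameters(ps, 123)
  s2 <- sample_parameters(ps, 123)
  expect_identical(s1, s2)
  s3 <- sample_parameters(ps, 124)
  expect_false(identical(s1$lines$abiraterone$utility$mean,
                         s3$lines$abiraterone$utility$mean))

  # all-fixed input passes through unchanged
  fz <- freeze_params(ps)
  sf <- sample_parameters(fz, 99)
  attr(sf, "sampled") <- NULL
  expect_equal(sf, fz)

  for (seed in 1:25) {
    d <- sample_parameters(ps, seed)
    for (nm in names(d$lines)) {
      expect_gte(d$lines[[nm]]$utility$mean, 0)
      expect_lte(d$lines[[nm]]$utility$mean, 1)
      expect_gte(d$lines[[nm]]$drug_cost_per_cycle$mean, 0)
      expect_gt(d$lines[[nm]]$os$median, 0)
    }
    expect_gte(d$ctdna_ppv$mean, 0)
    expect_lte(d$ctdna_ppv$mean, 1)
    expect_gte(d$ctdna_cost_per_sample$mean, 0)
  }
})

test_that("set_param addresses parameters and preserves uncertainty shape", {
  ps <- generate_parameter_set("base_like")
  p2 <- set_param(ps, "ctdna_cost_per_sample", 100)
  expect_equal(p2$ctdna_cost_per_sample$mean, 100)
  # coefficient of variation preserved when shifting a distributed mean
  cv0 <- ps$ctdna_cost_per_sample$se / ps$ctdna_cost_per_sample$mean
  expect_equal(p2$ctdna_cost_per_sample$se / 100, cv0)
  p3 <- set_param(ps, "lines.docetaxel.os.median", 17)
  expect_equal(p3$lines$docetaxel$os$median, 17)
  expect_error(set_param(ps, "not_a_parameter", 1), "valid top-level names")
  expect_error(set_param(ps, "lines.docetaxel.nope", 1), "valid line fields")
  # base object untouched
  expect_equal(ps$ctdna_cost_per_sample$mean, 350)
})

test_that("parameters_table flattens every scalar for audit", {
  tab <- parameters_table(generate_parameter_set("base_like"))
  expect_true(all(c("parameter", "value", "dist", "se") %in% names(tab)))
  expect_true("lines.docetaxel.os.median" %in% tab$parameter)
  expect_equal(tab$value[tab$parameter == "wtp"], 80000)
})
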