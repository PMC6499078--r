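test_that("per-prediction summaries match textbook mean and sample variance", {
  et <- ensemble_table(rbind(a = c(5, 5, 5, 5), b = c(1, 2, 3, 4)))
  s <- summarize_predictions(et)
  expect_equal(s$z, c(5, 2.5))
  expect_equal(s$v, c(0, 5 / 3))
  expect_equal(s$z2, c(25, 6.25))

  # error-free generative limit: every across-ensemble variance is zero
  sim <- simulate_ensembles(simulation_spec(20, 10, seed = 1))
  expect_equal(summarize_predictions(sim$table)$v, rep(0, 20))
})

test_that("weighted mean option changes z but not v", {
  et <- ensemble_table(rbind(a = c(1, 2, 3, 4)))
  expect_error(summarize_predictions(et), NA)
  et2 <- ensemble_table(rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2)))
  sw <- summarize_predictions(et2, weights = c(1, 0, 0, 0))
  expect_equal(sw$z, c(1, 2))
  expect_equal(sw$v, summarize_predictions(et2)$v)
})

test_that("pairwise statistics match hand values and pair counts", {
  et <- ensemble_table(rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  p <- pairwise_stats(et)
  expect_equal(nrow(p), 1L)
  expect_equal(p$c, 5 / 3)   # identical rows: covariance equals the variance
  expect_equal(p$zz, 6.25)

  et2 <- ensemble_table(rbind(a = c(1, 2, 3, 4), b = c(8, 6, 4, 2)))
  expect_equal(pairwise_stats(et2)$c, -10 / 3)

  et3 <- rand_table(40, 6, seed = 8)
  expect_equal(nrow(pairwise_stats(et3)), 40 * 39 / 2)
  expect_error(pairwise_stats(ensemble_table(rbind(a = c(1, 2)))),
               "at least 2 predictions")
})

test_that("streamed blocks agree with brute force for any block size", {
  et <- rand_table(57, 9, seed = 21)
  ref <- bf_pairwise(et$values)
  for (bs in c(5L, 16L, 57L, 512L)) {
    p <- pairwise_stats(et, block_size = bs)
    expect_equal(p$i, ref$i)
    expect_equal(p$j, ref$j)
    expect_equal(p$c, ref$c, tolerance = 1e-12)
    expect_equal(p$zz, ref$zz, tolerance = 1e-12)
  }
})

test_that("shared regression recovers a flat response and rejects degenerate input", {
  pairs <- data.frame(i = 1, j = 2, c = rep(0.5, 10), zz = 1:10)
  f <- fit_shared_regression(pairs)
  expect_equal(f$intercept, 0.5)
  expect_equal(f$slope, 0)
  expect_error(fit_shared_regression(data.frame(c = 1:5, zz = rep(2, 5))),
               "degenerate")
})

test_that("unshared regression is zero for error-free ensembles", {
  sim <- simulate_ensembles(simulation_spec(50, 20, seed = 2))
  f <- fit_unshared_regression(summarize_predictions(sim$table))
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
})

test_that("regression slopes match generative expectations (Monte Carlo)", {
  # analytic: Cov(X_i, X_j) = sigma_SM2 * Z_i Z_j, V_i expectation slope
  # (1 + sigma_SM2)(1 + sigma_M2) - 1
  sim <- simulate_ensembles(simulation_spec(
    500, 120, sigma_SM2 = 0.01, z_dist = "uniform", z_params = c(10, 100),
    seed = 31))
  fs <- fit_shared_regression(pairwise_stats(sim$table))
  expect_equal(fs$slope, 0.01, tolerance = 0.15)
  expect_equal(fs$intercept, 0, tolerance = 2)

  sim2 <- simulate_ensembles(simulation_spec(
    1000, 120, sigma_M2 = 0.02, z_dist = "uniform", z_params = c(10, 100),
    seed = 32))
  fu <- fit_unshared_regression(summarize_predictions(sim2$table))
  expect_equal(fu$slope, 0.02, tolerance = 0.1)
})

test_that("component solver matches its closed forms and truncation rules", {
  # no sharing: sigma_M2 equals the unshared slope exactly
  c1 <- solve_components(fit_from(0, 0), fit_from(0, 0.005))
  expect_identical(c1$sigma_M2, 0.005)
  # (1.1)(1.1) - 1 = 0.21
  c2 <- solve_components(fit_from(0, 0.1), fit_from(0, 0.21))
  expect_equal(c2$sigma_M2, 0.1, tolerance = 1e-12)
  # truncation flags set iff a raw estimate was negative
  c3 <- solve_components(fit_from(-0.25, 0.0003), fit_from(-5.4, 0.0078))
  expect_true(c3$truncated[["sigma_SA2"]])
  expect_true(c3$truncated[["sigma_A2"]])
  expect_false(c3$truncated[["sigma_SM2"]])
  expect_false(c3$truncated[["sigma_M2"]])
  expect_true(all(c(c3$sigma_SM2, c3$sigma_M2, c3$sigma_SA2, c3$sigma_A2) >= 0))
  # impossible total relative variance
  expect_error(solve_components(fit_from(0, 0), fit_from(0, -1.2)),
               "slope <= -1")
})

test_that("solver inverts the generative slope composition to machine precision", {
  set.seed(99)
  for (rep in 1:25) {
    sm2 <- runif(1, 0, 0.05); m2 <- runif(1, 0, 0.05)
    sa2 <- runif(1, 0, 2); a2 <- runif(1, 0, 2)
    shared <- fit_from(sa2, sm2)
    unshared <- fit_from(sa2 + a2, (1 + sm2) * (1 + m2) - 1)
    sol <- solve_components(shared, unshared)
    expect_equal(sol$sigma_SM2, sm2, tolerance = 1e-12)
    expect_equal(sol$sigma_M2, m2, tolerance = 1e-12)
    expect_equal(sol$sigma_SA2, sa2, tolerance = 1e-12)
    expect_equal(sol$sigma_A2, a2, tolerance = 1e-12)
    expect_false(any(sol$truncated))
    # multiplicative composition holds when nothing truncates
    expect_equal(1 + unshared$slope,
                 (1 + sol$sigma_SM2) * (1 + sol$sigma_M2),
                 tolerance = 1e-12)
  }
})

test_that("end-to-end decomposition is zero in the error-free limit and robust over repeats", {
  sim <- simulate_ensembles(simulation_spec(120, 12, seed = 5))
  res <- run_suma(sim$table)
  expect_equal(res$components$sigma_SM2, 0, tolerance = 1e-10)
  expect_equal(res$components$sigma_M2, 0, tolerance = 1e-10)
  expect_equal(res$components$sigma_SA2, 0, tolerance = 1e-10)
  expect_equal(res$components$sigma_A2, 0, tolerance = 1e-10)

  sim2 <- simulate_ensembles(simulation_spec(
    400, 120, sigma_SM2 = 0.0005, sigma_M2 = 0.0075,
    z_dist = "uniform", z_params = c(10, 100), seed = 6))
  res2 <- run_suma(sim2$table, spec = sample_spec(200, 5, seed = 7))
  expect_length(res2$repeats, 5L)
  sm <- vapply(res2$repeats, function(r) r$sigma_SM2, numeric(1))
  # repeats draw from one population sharing one set of replicate-level
  # shared factors, so their estimates cluster tightly
  expect_lt((max(sm) - min(sm)) / mean(sm), 0.5)
})

test_that("stratified decomposition degenerates to the pooled one for a single stratum", {
  sim <- simulate_ensembles(simulation_spec(
    150, 40, sigma_SM2 = 0.001, sigma_M2 = 0.004,
    z_dist = "uniform", z_params = c(10, 100), seed = 8))
  meta <- sim$meta
  meta$period <- "all"
  st <- stratified_suma(sim$table, meta, "period",
                        sample_spec(150, 1, seed = 3))
  pooled <- run_suma(sim$table, NULL, sample_spec(150, 1, seed = 3))
  expect_equal(st$strata[["all"]]$components$sigma_SM2,
               pooled$components$sigma_SM2)
  expect_equal(st$strata[["all"]]$components$sigma_M2,
               pooled$components$sigma_M2)
  expect_named(st$strata[["all"]]$summary,
               c("statistic", "covariance", "product_mean"))
})

test_that("undersized strata fall back to the whole stratum with a warning", {
  sim <- simulate_ensembles(simulation_spec(60, 10, sigma_M2 = 0.01, seed = 9))
  meta <- sim$meta
  meta$period <- rep(c("p1", "p2"), c(40, 20))
  expect_warning(
    st <- stratified_suma(sim$table, meta, "period",
                          sample_spec(30, 1, seed = 1)),
    "whole stratum")
  expect_equal(st$table$n, c(30, 20))
})
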