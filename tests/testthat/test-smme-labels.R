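test_that("mean covariance matches hand averages and the full-matrix oracle", {
  pairs <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                      c = c(2, 4, 0), zz = 1)
  attr(pairs, "prediction_ids") <- c("a", "b", "c")
  mc <- mean_covariances(pairs)
  expect_equal(mc$mean_cov, c(3, 1, 2))
  expect_equal(mc$prediction_id, c("a", "b", "c"))

  # all pair covariances equal k -> every mean covariance is k
  pairs$c <- 7
  expect_equal(mean_covariances(pairs)$mean_cov, rep(7, 3))

  for (seed in c(4, 5)) {
    et <- rand_table(60, 8, seed)
    mc2 <- mean_covariances(pairwise_stats(et))
    expect_equal(mc2$mean_cov, unname(bf_mean_cov(et$values)),
                 tolerance = 1e-10)
  }

  # error-free ensembles: all covariances, hence all means, are zero
  sim <- simulate_ensembles(simulation_spec(10, 6, seed = 1))
  expect_equal(mean_covariances(pairwise_stats(sim$table))$mean_cov,
               rep(0, 10))
})

test_that("dichotomization uses interpolated percentiles with ties going high", {
  mc <- data.frame(prediction_id = as.character(1:10), mean_cov = 1:10)
  lb <- dichotomize(mc, 80)
  expect_equal(attr(lb, "threshold"), 8.2)
  expect_equal(as.character(lb$prediction_id[lb$label == "high"]),
               c("9", "10"))

  # continuous sample: exactly the top 20% labelled high
  set.seed(3)
  mc2 <- data.frame(prediction_id = as.character(1:500),
                    mean_cov = rnorm(500))
  expect_equal(sum(dichotomize(mc2)$label == "high"), 100L)

  # degenerate distribution: ties rule sends everything high, with warning
  mc3 <- data.frame(prediction_id = as.character(1:6), mean_cov = rep(2, 6))
  expect_warning(lb3 <- dichotomize(mc3), "identical")
  expect_true(all(lb3$label == "high"))

  expect_error(dichotomize(data.frame(prediction_id = "1", mean_cov = 1)),
               "at least 5")
  mc4 <- mc; mc4$mean_cov[3] <- Inf
  expect_error(dichotomize(mc4), "non-finite")
  expect_error(dichotomize(mc, 150), "percentile")
})

test_that("labelling recovers a planted high-shared-error subset", {
  # 20% of predictions carry extra group-shared multiplicative error at
  # 5x the background; their mean covariances should stand out
  sens <- vapply(1:5, function(seed) {
    n <- 300
    grp <- rep(c("plain", "noisy"), c(240, 60))
    # exposures with moderate spread: mean covariance scales with Z_i, so
    # a very wide Z range would mask group membership (the magnitude
    # artifact inherent to unstandardized covariances); 120 replicates as
    # in a full ensemble
    sim <- simulate_ensembles(simulation_spec(
      n, 120, sigma_SM2 = 0.001, sigma_M2 = 0.0075,
      z_dist = "uniform", z_params = c(40, 60),
      groups = list(labels = grp, extra_sm2 = c(noisy = 0.005)),
      seed = seed))
    lb <- dichotomize(mean_covariances(pairwise_stats(sim$table)))
    mean(lb$label[grp == "noisy"] == "high")
  }, numeric(1))
  expect_gte(mean(sens), 0.8)
})

test_that("group comparison reports Welch results and the low-minus-high convention", {
  ids <- sprintf("p%03d", 1:40)
  lb <- make_labels(ids, rep(c(FALSE, TRUE), each = 20))
  set.seed(12)
  vals <- rnorm(20)
  meta <- data.frame(prediction_id = ids, same = c(vals, vals),
                     flat = 1, stringsAsFactors = FALSE)
  cmp <- compare_groups(lb, meta, c("same", "flat"))
  r <- cmp[cmp$variable == "same", ]
  expect_equal(r$mean_low - r$mean_high, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$t_stat, 0)
  rf <- cmp[cmp$variable == "flat", ]
  expect_true(is.na(rf$p_value))
  expect_match(rf$note, "zero variance")

  # N(0,1) vs N(1,1): difference (low - high) near -1, decisively nonzero
  ids2 <- sprintf("q%04d", 1:1000)
  lb2 <- make_labels(ids2, rep(c(FALSE, TRUE), each = 500))
  set.seed(13)
  meta2 <- data.frame(prediction_id = ids2,
                      v = c(rnorm(500, 0), rnorm(500, 1)),
                      stringsAsFactors = FALSE)
  cmp2 <- compare_groups(lb2, meta2, "v")
  # oracle: closed-form Welch statistic
  lo <- meta2$v[1:500]; hi <- meta2$v[501:1000]
  tw <- (mean(lo) - mean(hi)) / sqrt(var(lo) / 500 + var(hi) / 500)
  expect_equal(cmp2$t_stat, tw, tolerance = 1e-12)
  expect_equal(cmp2$mean_low - cmp2$mean_high, -1, tolerance = 0.2)
  expect_lt(cmp2$p_value, 0.001)
  expect_true(cmp2$ci_low < -1 && -1 < cmp2$ci_high)
})

test_that("seasons derive from dates with a December-start winter", {
  d <- as.Date(c("2001-12-15", "2002-02-01", "2002-04-10", "2002-07-04",
                 "2002-10-31"))
  expect_equal(as.character(season_from_date(d)),
               c("winter", "winter", "spring", "summer", "fall"))
})

test_that("label tabulation gives column percentages and detects seasonal structure", {
  # null structure: labels independent of season
  n <- 2000
  ids <- sprintf("p%05d", 1:n)
  set.seed(21)
  high <- rbinom(n, 1, 0.2) == 1
  lb <- make_labels(ids, high)
  meta <- data.frame(prediction_id = ids,
                     season = sample(c("winter", "spring", "summer", "fall"),
                                     n, TRUE),
                     stringsAsFactors = FALSE)
  tab <- tabulate_labels(lb, meta, "season")
  expect_equal(sum(tab$n_low) + sum(tab$n_high), n)
  expect_equal(sum(tab$pct_low), 100)
  expect_equal(sum(tab$pct_high), 100)
  expect_lt(max(abs(tab$pct_high - 25)), 10)
  expect_true(is.na(tab$p_value[1]))

  expect_error(tabulate_labels(lb, meta, "region"), "unknown grouping")

  # winter-inflated shared error: winter over-represented among high labels
  n2 <- 400
  season <- sample(c("winter", "spring", "summer", "fall"), n2, TRUE)
  sim <- simulate_ensembles(simulation_spec(
    n2, 80, sigma_SM2 = 0.0003, sigma_M2 = 0.0075,
    z_dist = "uniform", z_params = c(10, 100),
    groups = list(labels = season, extra_sm2 = c(winter = 0.003)),
    seed = 22))
  lb2 <- dichotomize(mean_covariances(pairwise_stats(sim$table)))
  meta2 <- data.frame(prediction_id = sim$table$prediction_ids,
                      season = season, stringsAsFactors = FALSE)
  tab2 <- tabulate_labels(lb2, meta2, "season")
  w <- tab2[tab2$category == "winter", ]
  expect_gt(w$pct_high, w$pct_low)
})
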