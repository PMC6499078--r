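# Independent oracles and small fixture builders shared across tests.

# Brute-force pairwise statistics: double loop over pairs, covariance via
# stats::cov per pair.  Deliberately naive; the streamed implementation is
# checked against this.
bf_pairwise <- function(X) {
  n <- nrow(X)
  z <- rowMeans(X)
  out <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      out[[k]] <- data.frame(i = i, j = j,
                             c = stats::cov(X[i, ], X[j, ]),
                             zz = z[i] * z[j])
    }
  }
  do.call(rbind, out)
}

# Brute-force mean covariance: full covariance matrix, average off-diagonal.
bf_mean_cov <- function(X) {
  C <- stats::cov(t(X))
  (rowSums(C) - diag(C)) / (nrow(X) - 1L)
}

rand_table <- function(n_pred, n_ens, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_pred * n_ens, 50, 10), n_pred, n_ens,
              dimnames = list(NULL, sprintf("ens_%03d", seq_len(n_ens))))
  ensemble_table(m)
}

# suma_fit built from known intercept/slope (for desk arithmetic on the
# component solver, which only needs those two fields).
fit_from <- function(intercept, slope, label = "given") {
  structure(list(intercept = intercept, slope = slope,
                 se_intercept = NA_real_, se_slope = NA_real_,
                 p_intercept = NA_real_, p_slope = NA_real_,
                 n_obs = NA_integer_, label = label),
            class = "suma_fit")
}

# SMME label set built directly from a binary vector (for spatial-model
# tests where labels are generated from a known odds surface rather than
# from ensemble covariances).
make_labels <- function(ids, high) {
  structure(data.frame(prediction_id = as.character(ids),
                       mean_cov = as.numeric(high),
                       label = factor(ifelse(high, "high", "low"),
                                      c("low", "high")),
                       stringsAsFactors = FALSE),
            threshold = NA_real_, percentile = 80,
            class = c("smme_labels", "data.frame"))
}

# Uniform locations plus Bernoulli labels whose odds are `odds_mult` times
# higher inside a disc; the null case is odds_mult = 1.
sim_spatial_labels <- function(n, seed, odds_mult = 1, p0 = 0.2,
                               disc = c(x = 30000, y = 30000, r = 17841)) {
  set.seed(seed)
  x <- runif(n, 0, 100000); y <- runif(n, 0, 100000)
  inside <- (x - disc[["x"]])^2 + (y - disc[["y"]])^2 <= disc[["r"]]^2
  odds <- p0 / (1 - p0) * ifelse(inside, odds_mult, 1)
  p <- odds / (1 + odds)
  high <- rbinom(n, 1, p) == 1
  ids <- sprintf("p%05d", seq_len(n))
  list(labels = make_labels(ids, high),
       meta = data.frame(prediction_id = ids, x = x, y = y,
                         in_disc = as.numeric(inside),
                         stringsAsFactors = FALSE),
       inside = inside)
}
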