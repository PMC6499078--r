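#' Per-prediction summaries across ensemble replicates
#'
#' For each prediction i, computes the across-ensemble mean Z_i, the
#' across-ensemble sample variance V_i (denominator n_ens - 1), and the
#' squared mean Z_i^2.  Z_i plays the role of the reported exposure
#' estimate; V_i carries the unshared error signal.
#'
#' @param table an [ensemble_table()].
#' @param weights optional replicate weights for Z_i (the ensemble mean may
#'   be performance-weighted in practice); default is the unweighted mean.
#'   Weights affect Z only; V remains the unweighted sample variance.
#' @return A `data.frame` with columns `prediction_id`, `z` (ppb),
#'   `v` (ppb^2), `z2` (ppb^2).
#' @export
summarize_predictions <- function(table, weights = NULL) {
  stopifnot(inherits(table, "ensemble_table"))
  X <- table$values
  if (is.null(weights)) {
    z <- rowMeans(X)
  } else {
    stopifnot(length(weights) == table$n_ens, all(weights >= 0))
    z <- as.vector(X %*% (weights / sum(weights)))
  }
  v <- rowSums((X - rowMeans(X))^2) / (table$n_ens - 1L)
  data.frame(prediction_id = table$prediction_ids,
             z = z, v = v, z2 = z^2,
             stringsAsFactors = FALSE)
}

#' Pairwise across-ensemble covariances and mean products
#'
#' For every unordered pair of predictions (i, j), i < j, computes the
#' sample covariance C_ij of their realizations across replicates
#' (denominator n_ens - 1) and the product of means Z_i * Z_j.  These are
#' the response and regressor of the shared-error regression.
#'
#' Pairs are produced blockwise: the centered matrix is cross-multiplied
#' in row blocks so that a 2500-prediction table (about 3.1 million pairs)
#' is processed without ever forming objects much larger than the output.
#'
#' @param table an [ensemble_table()] with at least 2 predictions.
#' @param block_size rows per block for the streamed computation.
#' @return A `data.frame` with integer columns `i`, `j` (row indices,
#'   i < j) and numeric `c` (ppb^2), `zz` (ppb^2); the table's
#'   `prediction_ids` are attached as an attribute of the same name.
#' @export
pairwise_stats <- function(table, block_size = 512L) {
  stopifnot(inherits(table, "ensemble_table"))
  n <- nrow(table$values)
  if (n < 2L) stop("pairwise statistics need at least 2 predictions")
  X <- table$values
  z <- rowMeans(X)
  Xc <- X - z
  denom <- table$n_ens - 1L
  starts <- seq(1L, n, by = block_size)
  out <- vector("list", length(starts) * (length(starts) + 1L) / 2L)
  k <- 0L
  for (a in seq_along(starts)) {
    ia <- starts[a]:min(starts[a] + block_size - 1L, n)
    for (b in a:length(starts)) {
      ib <- starts[b]:min(starts[b] + block_size - 1L, n)
      C <- tcrossprod(Xc[ia, , drop = FALSE], Xc[ib, , drop = FALSE]) / denom
      ii <- rep(ia, times = length(ib))
      jj <- rep(ib, each = length(ia))
      keep <- ii < jj
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.frame(i = ii[keep], j = jj[keep],
                             c = as.vector(C)[keep],
                             zz = z[ii[keep]] * z[jj[keep]])
    }
  }
  pairs <- do.call(rbind, out[seq_len(k)])
  ord <- order(pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "prediction_ids") <- table$prediction_ids
  pairs
}

# Simple-OLS wrapper used by both component regressions.  Standard errors
# and p-values are the nominal lm() ones; for the pairwise regression the
# observations are dependent, so those are descriptive only.
.ols_fit <- function(y, x, label) {
  n <- length(y)
  if (n < 3L) stop(label, ": need at least 3 observations")
  if (stats::var(x) == 0) stop(label, ": degenerate regressor (all equal)")
  fit <- stats::lm(y ~ x)
  # error-free ensembles fit perfectly; the summary warning adds nothing
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(intercept = unname(cf[1L, 1L]), slope = unname(cf[2L, 1L]),
         se_intercept = unname(cf[1L, 2L]), se_slope = unname(cf[2L, 2L]),
         p_intercept = unname(cf[1L, 4L]), p_slope = unname(cf[2L, 4L]),
         n_obs = n, label = label),
    class = "suma_fit")
}

#' @export
print.suma_fit <- function(x, ...) {
  cat(x$label, "regression (n =", x$n_obs, "pairs/predictions)\n")
  m <- rbind(intercept = c(x$intercept, x$se_intercept, x$p_intercept),
             slope = c(x$slope, x$se_slope, x$p_slope))
  colnames(m) <- c("Value", "Std.error", "p")
  print(signif(m, 4))
  invisible(x)
}

#' Shared-error regression: covariance on product of means
#'
#' Fits C_ij = a0 + a1 * Z_i Z_j by ordinary least squares over all
#' prediction pairs.  Under the shared/unshared error model the intercept
#' a0 estimates the shared additive variance and the slope a1 estimates
#' the shared multiplicative variance.
#'
#' @param pairs output of [pairwise_stats()].
#' @return A `suma_fit` with intercept/slope estimates, their nominal
#'   standard errors and p-values, and `n_obs`.  Pair records share
#'   replicates, so the standard errors are descriptive, not exact.
#' @export
fit_shared_regression <- function(pairs) {
  stopifnot(all(c("c", "zz") %in% names(pairs)))
  .ols_fit(pairs$c, pairs$zz, "shared (covariance ~ product of means)")
}

#' Unshared-error regression: variance on squared mean
#'
#' Fits V_i = b0 + b1 * Z_i^2 by ordinary least squares over predictions.
#' Under the error model the intercept estimates the sum of the additive
#' variances (shared + unshared) and the slope estimates the total
#' relative variance (1 + sigma_SM2)(1 + sigma_M2) - 1.
#'
#' @param summaries output of [summarize_predictions()].
#' @return A `suma_fit`.
#' @export
fit_unshared_regression <- function(summaries) {
  stopifnot(all(c("v", "z2") %in% names(summaries)))
  .ols_fit(summaries$v, summaries$z2, "unshared (variance ~ squared mean)")
}

#' Solve the two regression fits for the four error components
#'
#' The shared regression identifies sigma_SM2 (slope) and sigma_SA2
#' (intercept) directly.  The unshared regression slope equals
#' (1 + sigma_SM2)(1 + sigma_M2) - 1, so sigma_M2 is recovered by
#' division, and its intercept equals sigma_SA2 + sigma_A2, so sigma_A2
#' is recovered by differencing.  Negative raw estimates are truncated to
#' zero — variances cannot be negative — and truncation happens before
#' solving: sigma_SM2 is truncated before dividing for sigma_M2, and
#' sigma_SA2 before differencing for sigma_A2.
#'
#' @param shared_fit `suma_fit` from [fit_shared_regression()].
#' @param unshared_fit `suma_fit` from [fit_unshared_regression()].
#' @return An object of class `suma_components`: list with the four final
#'   (truncated) components `sigma_SM2`, `sigma_M2`, `sigma_SA2`,
#'   `sigma_A2`, the raw (untruncated) regression quantities, logical
#'   `truncated` flags, and the two fits.
#' @export
solve_components <- function(shared_fit, unshared_fit) {
  stopifnot(inherits(shared_fit, "suma_fit"), inherits(unshared_fit, "suma_fit"))
  if (unshared_fit$slope <= -1)
    stop("unshared regression slope <= -1: total relative variance ",
         "(1 + slope) would be non-positive, which no error model can produce")
  raw <- c(sigma_SM2 = shared_fit$slope,
           sigma_SA2 = shared_fit$intercept,
           total_rel = unshared_fit$slope,
           total_add = unshared_fit$intercept)
  sigma_SM2 <- max(raw[["sigma_SM2"]], 0)
  sigma_SA2 <- max(raw[["sigma_SA2"]], 0)
  # exact no-sharing path: with sigma_SM2 = 0 the unshared slope IS sigma_M2
  raw_M2 <- if (sigma_SM2 == 0) raw[["total_rel"]]
            else (1 + raw[["total_rel"]]) / (1 + sigma_SM2) - 1
  sigma_M2 <- max(raw_M2, 0)
  raw_A2 <- raw[["total_add"]] - sigma_SA2
  sigma_A2 <- max(raw_A2, 0)
  structure(
    list(sigma_SM2 = sigma_SM2, sigma_M2 = sigma_M2,
         sigma_SA2 = sigma_SA2, sigma_A2 = sigma_A2,
         raw = c(sigma_SM2 = raw[["sigma_SM2"]], sigma_M2 = raw_M2,
                 sigma_SA2 = raw[["sigma_SA2"]], sigma_A2 = raw_A2),
         truncated = c(sigma_SM2 = raw[["sigma_SM2"]] < 0,
                       sigma_M2 = raw_M2 < 0,
                       sigma_SA2 = raw[["sigma_SA2"]] < 0,
                       sigma_A2 = raw_A2 < 0),
         shared_fit = shared_fit, unshared_fit = unshared_fit),
    class = "suma_components")
}

#' @export
print.suma_components <- function(x, ...) {
  cat("SUMA measurement-error components\n")
  comp <- c("Shared multiplicative (sigma_SM2)" = x$sigma_SM2,
            "Unshared multiplicative (sigma_M2)" = x$sigma_M2,
            "Shared additive (sigma_SA2)" = x$sigma_SA2,
            "Unshared additive (sigma_A2)" = x$sigma_A2)
  tr <- x$truncated[c("sigma_SM2", "sigma_M2", "sigma_SA2", "sigma_A2")]
  for (k in seq_along(comp))
    cat(sprintf("  %-36s %.6g%s\n", names(comp)[k], comp[k],
                if (tr[k]) "  (raw estimate negative, truncated to 0)" else ""))
  invisible(x)
}

#' One-row summary of a component solution (mirrors a report table row set)
#'
#' @param x a `suma_components`.
#' @param ... unused.
#' @return `data.frame` with component, value, raw value, SE and p-value
#'   of the regression quantity each component derives from.
#' @export
as.data.frame.suma_components <- function(x, ...) {
  sf <- x$shared_fit; uf <- x$unshared_fit
  data.frame(
    component = c("sigma_SA2", "sigma_SM2", "sigma_A2", "sigma_M2"),
    value = c(x$sigma_SA2, x$sigma_SM2, x$sigma_A2, x$sigma_M2),
    raw = unname(x$raw[c("sigma_SA2", "sigma_SM2", "sigma_A2", "sigma_M2")]),
    std_error = c(sf$se_intercept, sf$se_slope, uf$se_intercept, NA),
    p_value = c(sf$p_intercept, sf$p_slope, uf$p_intercept, NA),
    stringsAsFactors = FALSE)
}

#' End-to-end SUMA decomposition
#'
#' Runs the full pipeline — optional repeated subsampling, per-prediction
#' summaries, pairwise statistics, the two regressions, and the component
#' solution — and, when several repeats are requested, reports the spread
#' of the estimates across repeats as a robustness check.
#'
#' @param table an [ensemble_table()].
#' @param meta optional metadata (needed only for stratum filters).
#' @param spec optional [sample_spec()]; `NULL` analyses the full table
#'   once.
#' @param block_size passed to [pairwise_stats()].
#' @return An object of class `suma_result`: list with `components` (from
#'   the first repeat), `repeats` (list of per-repeat `suma_components`),
#'   and `spread` (per-component min/median/max across repeats).
#' @export
run_suma <- function(table, meta = NULL, spec = NULL, block_size = 512L) {
  stopifnot(inherits(table, "ensemble_table"))
  sets <- if (is.null(spec)) list(list(table = table, meta = meta))
          else subsample(table, meta, spec)
  reps <- lapply(sets, function(s) {
    sm <- summarize_predictions(s$table)
    pr <- pairwise_stats(s$table, block_size = block_size)
    solve_components(fit_shared_regression(pr), fit_unshared_regression(sm))
  })
  est <- t(vapply(reps, function(r)
    c(sigma_SM2 = r$sigma_SM2, sigma_M2 = r$sigma_M2,
      sigma_SA2 = r$sigma_SA2, sigma_A2 = r$sigma_A2), numeric(4)))
  spread <- data.frame(
    component = colnames(est),
    min = apply(est, 2, min), median = apply(est, 2, stats::median),
    max = apply(est, 2, max), stringsAsFactors = FALSE)
  rownames(spread) <- NULL
  structure(list(components = reps[[1L]], repeats = reps, spread = spread,
                 samples = sets),
            class = "suma_result")
}

#' @export
print.suma_result <- function(x, ...) {
  print(x$components)
  if (length(x$repeats) > 1L) {
    cat("\nSpread over", length(x$repeats), "independent subsamples:\n")
    print(transform(x$spread, min = signif(min, 4), median = signif(median, 4),
                    max = signif(max, 4)))
  }
  invisible(x)
}

#' Time- (or otherwise-) stratified SUMA decomposition
#'
#' Partitions the predictions by a metadata column (e.g. calendar-year
#' tertiles), draws an independent subsample within each stratum, and
#' runs the full decomposition per stratum.  Alongside the components it
#' reports per-stratum descriptive summaries (min/max/median) of the
#' pairwise covariances and mean products.
#'
#' @param table an [ensemble_table()].
#' @param meta metadata with the stratifying column.
#' @param strata name of the metadata column defining the strata.
#' @param spec a [sample_spec()]; when a stratum holds fewer predictions
#'   than `sample_size`, the whole stratum is used with a warning.
#' @param block_size passed to [pairwise_stats()].
#' @return An object of class `suma_strata`: named list of per-stratum
#'   results, each with `components`, `summary` (covariance / product
#'   descriptives) and `n`; plus a combined `table` data.frame.
#' @export
stratified_suma <- function(table, meta, strata, spec = sample_spec(),
                            block_size = 512L) {
  stopifnot(inherits(table, "ensemble_table"))
  meta <- validate_meta(meta, table)
  if (!strata %in% names(meta)) stop("unknown strata column '", strata, "'")
  levels_ <- unique(as.character(meta[[strata]]))
  out <- list()
  for (lv in levels_) {
    ids <- meta$prediction_id[meta[[strata]] == lv]
    sub <- subset_ensemble_table(table, ids)
    sz <- spec$sample_size
    if (sz > length(ids)) {
      warning("stratum '", lv, "' has only ", length(ids),
              " predictions; sampling the whole stratum")
      sz <- length(ids)
    }
    sp <- sample_spec(sz, spec$n_repeats, spec$seed)
    res <- run_suma(sub, NULL, sp, block_size = block_size)
    pr <- pairwise_stats(res$samples[[1L]]$table, block_size = block_size)
    out[[lv]] <- list(
      components = res$components,
      repeats = res$repeats,
      n = sz,
      summary = data.frame(
        statistic = c("min", "max", "median"),
        covariance = c(min(pr$c), max(pr$c), stats::median(pr$c)),
        product_mean = c(min(pr$zz), max(pr$zz), stats::median(pr$zz)),
        stringsAsFactors = FALSE))
  }
  tab <- data.frame(
    stratum = levels_,
    sigma_SM2 = vapply(out, function(s) s$components$sigma_SM2, numeric(1)),
    sigma_M2 = vapply(out, function(s) s$components$sigma_M2, numeric(1)),
    n = vapply(out, function(s) s$n, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(strata = out, table = tab, column = strata),
            class = "suma_strata")
}

#' @export
print.suma_strata <- function(x, ...) {
  cat("Stratified SUMA decomposition by '", x$column, "'\n", sep = "")
  print(transform(x$table, sigma_SM2 = signif(sigma_SM2, 4),
                  sigma_M2 = signif(sigma_M2, 4)))
  invisible(x)
}
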