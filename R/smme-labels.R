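#' Mean pairwise covariance per prediction
#'
#' A prediction that consistently covaries with the others across
#' replicates carries shared uncertainty; its mean covariance over all
#' other sampled predictions summarizes that tendency in one number per
#' prediction.
#'
#' @param pairs output of [pairwise_stats()].
#' @return A `data.frame` with columns `prediction_id` and `mean_cov`
#'   (ppb^2), one row per prediction, in the original table order.
#' @export
mean_covariances <- function(pairs) {
  stopifnot(all(c("i", "j", "c") %in% names(pairs)))
  ids <- attr(pairs, "prediction_ids")
  n <- if (!is.null(ids)) length(ids) else max(pairs$i, pairs$j)
  cnt <- tabulate(pairs$i, n) + tabulate(pairs$j, n)
  if (any(cnt == 0L))
    stop("prediction(s) without any pair: ",
         paste(utils::head(which(cnt == 0L), 5), collapse = ", "))
  s <- numeric(n)
  a <- rowsum(pairs$c, pairs$i)
  s[as.integer(rownames(a))] <- s[as.integer(rownames(a))] + a[, 1L]
  b <- rowsum(pairs$c, pairs$j)
  s[as.integer(rownames(b))] <- s[as.integer(rownames(b))] + b[, 1L]
  data.frame(prediction_id = if (!is.null(ids)) ids else as.character(seq_len(n)),
             mean_cov = s / cnt, stringsAsFactors = FALSE)
}

#' Dichotomize mean covariances into high / low SMME labels
#'
#' Labels the upper tail of the mean-covariance distribution as carrying
#' "high" shared multiplicative measurement error.  The threshold is the
#' empirical percentile computed with linear interpolation between order
#' statistics (`quantile()` type 7); ties at the threshold are labelled
#' high, i.e. `high` means `mean_cov >= threshold`.
#'
#' @param mean_covs output of [mean_covariances()] (or any data.frame with
#'   `prediction_id` and `mean_cov`).
#' @param percentile the cut percentile in (0, 100); default 80, so the
#'   top 20\% are labelled high.
#' @return An object of class `smme_labels`: the input data.frame plus a
#'   `label` factor (`low`/`high`), with attributes `threshold` and
#'   `percentile`.
#' @export
dichotomize <- function(mean_covs, percentile = 80) {
  stopifnot(is.data.frame(mean_covs), "mean_cov" %in% names(mean_covs))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  mc <- mean_covs$mean_cov
  if (length(mc) < 5L)
    stop("need at least 5 predictions to dichotomize")
  if (!all(is.finite(mc))) stop("non-finite mean covariances")
  thr <- unname(stats::quantile(mc, percentile / 100, type = 7))
  if (min(mc) == max(mc))
    warning("all mean covariances identical; every prediction labelled high")
  out <- mean_covs
  out$label <- factor(ifelse(mc >= thr, "high", "low"),
                      levels = c("low", "high"))
  attr(out, "threshold") <- thr
  attr(out, "percentile") <- percentile
  class(out) <- c("smme_labels", "data.frame")
  out
}

#' @export
print.smme_labels <- function(x, ...) {
  cat("SMME labels: ", sum(x$label == "high"), " high / ",
      sum(x$label == "low"), " low (cut at the ",
      attr(x, "percentile"), "th percentile, threshold ",
      signif(attr(x, "threshold"), 4), " ppb^2)\n", sep = "")
  invisible(x)
}

#' Compare covariate distributions between high- and low-SMME predictions
#'
#' For each requested variable, reports group means and SDs, the Welch
#' two-sided t statistic and p-value, and the 95% confidence interval of
#' the mean difference (low minus high).
#'
#' @param labels an `smme_labels` object.
#' @param meta metadata `data.frame` joinable by `prediction_id`.
#' @param variables character vector of numeric metadata columns.
#' @return A `data.frame`, one row per variable.  Variables with zero
#'   variance in both groups are reported with `NA` test results and a
#'   `note`.
#' @export
compare_groups <- function(labels, meta, variables) {
  stopifnot(inherits(labels, "smme_labels"))
  m <- merge(as.data.frame(labels), meta, by = "prediction_id")
  if (!all(table(m$label) > 1L))
    stop("both label groups must contain more than one prediction")
  rows <- lapply(variables, function(v) {
    if (!v %in% names(m)) stop("unknown variable '", v, "'")
    lo <- m[[v]][m$label == "low"]
    hi <- m[[v]][m$label == "high"]
    base <- data.frame(variable = v,
                       mean_low = mean(lo), sd_low = stats::sd(lo),
                       mean_high = mean(hi), sd_high = stats::sd(hi),
                       stringsAsFactors = FALSE)
    if (stats::sd(lo) == 0 && stats::sd(hi) == 0) {
      cbind(base, t_stat = NA_real_, p_value = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_,
            note = "zero variance in both groups; test undefined")
    } else {
      tt <- stats::t.test(lo, hi)  # Welch by default; difference = low - high
      cbind(base, t_stat = unname(tt$statistic), p_value = tt$p.value,
            ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L], note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive meteorological season from a date
#'
#' Winter is December-February, spring March-May, summer June-August,
#' fall September-November.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return A factor with levels `winter`, `spring`, `summer`, `fall`.
#' @export
season_from_date <- function(date) {
  mo <- as.integer(format(as.Date(date), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "fall", "fall", "fall", "winter")[mo]
  factor(s, levels = c("winter", "spring", "summer", "fall"))
}

#' Tabulate SMME labels by season, period or region
#'
#' Cross-tabulates high/low labels against a categorical metadata
#' variable, reporting counts and column percentages (each label group
#' sums to 100%), plus a per-category two-sample proportion test of the
#' high share in that category against the first (reference) category.
#'
#' @param labels an `smme_labels` object.
#' @param meta metadata joinable by `prediction_id`.  When `by = "season"`
#'   and no `season` column exists, the season is derived from a `date`
#'   column.
#' @param by grouping column name (e.g. `"season"`, `"period"`,
#'   `"region"`).
#' @return A `data.frame` with columns `category`, `n_low`, `pct_low`,
#'   `n_high`, `pct_high`, `p_value` (NA for the reference category).
#' @export
tabulate_labels <- function(labels, meta, by) {
  stopifnot(inherits(labels, "smme_labels"))
  m <- merge(as.data.frame(labels), meta, by = "prediction_id")
  if (!by %in% names(m)) {
    if (by == "season" && "date" %in% names(m)) {
      m$season <- season_from_date(m$date)
    } else {
      stop("unknown grouping variable '", by, "'")
    }
  }
  g <- factor(m[[by]])
  tab <- table(g, m$label)
  cats <- rownames(tab)
  n_low <- tab[, "low"]; n_high <- tab[, "high"]
  p <- rep(NA_real_, length(cats))
  for (k in seq_along(cats)[-1L]) {
    counts <- rbind(c(n_high[1L], n_low[1L]), c(n_high[k], n_low[k]))
    if (all(rowSums(counts) > 0))
      p[k] <- suppressWarnings(stats::prop.test(counts)$p.value)
  }
  out <- data.frame(category = cats,
                    n_low = as.integer(n_low),
                    pct_low = 100 * as.integer(n_low) / sum(n_low),
                    n_high = as.integer(n_high),
                    pct_high = 100 * as.integer(n_high) / sum(n_high),
                    p_value = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
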