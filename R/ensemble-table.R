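#' Construct an ensemble prediction table
#'
#' An ensemble table holds one exposure prediction per row and one ensemble
#' replicate per column.  Each cell is a realization (in ppb) of the true
#' exposure for that prediction, drawn from the dosimetry system formed by
#' the ensemble of fitted exposure models.
#'
#' @param values numeric matrix of exposure realizations; rows are
#'   predictions, columns are ensemble replicates.
#' @param prediction_ids character vector of unique prediction identifiers,
#'   one per row.  Defaults to existing rownames, or `"p1"`, `"p2"`, ...
#' @return An object of class `ensemble_table`: a list with elements
#'   `prediction_ids`, `values` (the matrix, with ids as rownames) and
#'   `n_ens` (replicate count).
#' @examples
#' et <- ensemble_table(matrix(rnorm(12, 30, 2), nrow = 3))
#' et$n_ens
#' @export
ensemble_table <- function(values, prediction_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("ensemble values must be numeric")
  if (is.null(prediction_ids)) {
    prediction_ids <- rownames(values)
    if (is.null(prediction_ids))
      prediction_ids <- paste0("p", seq_len(nrow(values)))
  }
  prediction_ids <- as.character(prediction_ids)
  if (length(prediction_ids) != nrow(values))
    stop("length of prediction_ids (", length(prediction_ids),
         ") does not match row count (", nrow(values), ")")
  if (anyDuplicated(prediction_ids))
    stop("duplicate prediction_ids: ",
         paste(unique(prediction_ids[duplicated(prediction_ids)]),
               collapse = ", "))
  if (ncol(values) < 2L)
    stop("n_ens >= 2 required: across-replicate variance and covariance ",
         "are undefined with ", ncol(values), " replicate(s)")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite ensemble value at row ", bad[1L],
         " (id ", prediction_ids[bad[1L]], "), column ", bad[2L])
  }
  rownames(values) <- prediction_ids
  structure(
    list(prediction_ids = prediction_ids,
         values = values,
         n_ens = ncol(values)),
    class = "ensemble_table")
}

#' @export
print.ensemble_table <- function(x, ...) {
  cat("Ensemble prediction table\n")
  cat("  predictions:", nrow(x$values), "\n")
  cat("  replicates: ", x$n_ens, "\n")
  cat("  value range:", format(min(x$values), digits = 4), "to",
      format(max(x$values), digits = 4), "ppb\n")
  invisible(x)
}

#' @export
dim.ensemble_table <- function(x) dim(x$values)

#' Subset an ensemble table by prediction id or row index
#'
#' @param x an [ensemble_table()].
#' @param ids character vector of prediction ids, or integer row indices.
#' @return An `ensemble_table` restricted to the requested predictions.
#' @export
subset_ensemble_table <- function(x, ids) {
  stopifnot(inherits(x, "ensemble_table"))
  if (is.character(ids)) {
    miss <- setdiff(ids, x$prediction_ids)
    if (length(miss))
      stop("unknown prediction ids: ", paste(utils::head(miss, 5), collapse = ", "))
    idx <- match(ids, x$prediction_ids)
  } else {
    idx <- as.integer(ids)
  }
  ensemble_table(x$values[idx, , drop = FALSE], x$prediction_ids[idx])
}

#' Read an ensemble table from CSV
#'
#' Expected layout: a header row, first column `prediction_id`, remaining
#' columns one per ensemble replicate (e.g. `ens_001`, ..., `ens_120`).
#' Values are exposure realizations in ppb, stored as decimal text.
#'
#' @param path path to a CSV file.
#' @return An [ensemble_table()].
#' @export
read_ensemble_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("ensemble CSV needs an id column plus at least one replicate column")
  ids <- df[[1L]]
  num <- df[-1L]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(num),
                dimnames = list(ids, names(num)))
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | !nzchar(num[[j]]))
    if (length(bad))
      stop("non-numeric or missing value in '", path, "' at row ", bad[1L],
           " (id ", ids[bad[1L]], "), column '", names(num)[j], "'")
    mat[, j] <- v
  }
  ensemble_table(mat, ids)
}

#' Write an ensemble table to CSV
#'
#' Values are written at full precision (17 significant digits) so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x an [ensemble_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_table <- function(x, path) {
  stopifnot(inherits(x, "ensemble_table"))
  cn <- colnames(x$values)
  if (is.null(cn)) cn <- sprintf("ens_%03d", seq_len(x$n_ens))
  txt <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L)
  df <- data.frame(prediction_id = x$prediction_ids, txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("prediction_id", cn)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction metadata table from CSV
#'
#' @param path path to a CSV file with one row per prediction.  A
#'   `prediction_id` column is required; `x` and `y` (projected planar
#'   coordinates in meters), `date`, `period` and covariate columns are
#'   used by downstream analyses when present.
#' @return A `data.frame`.
#' @export
read_prediction_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"prediction_id" %in% names(df))
    stop("metadata CSV must contain a 'prediction_id' column")
  df$prediction_id <- as.character(df$prediction_id)
  if (anyDuplicated(df$prediction_id))
    stop("duplicate prediction_id values in metadata")
  df
}

#' Check that metadata matches an ensemble table
#'
#' Verifies the join invariants: every prediction in the table has exactly
#' one metadata row, coordinates are finite, and distance/density
#' covariates are non-negative.
#'
#' @param meta metadata `data.frame` with a `prediction_id` column.
#' @param table an [ensemble_table()].
#' @return `meta`, reordered to match the table's prediction order.
#' @export
validate_meta <- function(meta, table) {
  stopifnot(inherits(table, "ensemble_table"), is.data.frame(meta))
  miss <- setdiff(table$prediction_ids, meta$prediction_id)
  if (length(miss))
    stop(length(miss), " prediction id(s) missing from metadata, e.g. ",
         paste(utils::head(miss, 5), collapse = ", "))
  meta <- meta[match(table$prediction_ids, meta$prediction_id), , drop = FALSE]
  rownames(meta) <- NULL
  for (col in intersect(c("x", "y"), names(meta)))
    if (!all(is.finite(meta[[col]])))
      stop("non-finite values in coordinate column '", col, "'")
  nonneg <- grep("^(dist_|.*density)", names(meta), value = TRUE)
  for (col in nonneg)
    if (is.numeric(meta[[col]]) && any(meta[[col]] < 0, na.rm = TRUE))
      stop("negative values in column '", col, "' (distances and densities ",
           "must be >= 0)")
  meta
}

#' Specify a random subsample of predictions
#'
#' Analyses of pairwise covariance scale quadratically with the number of
#' predictions, so the decomposition is usually run on a random subset
#' (default 2500) and repeated on additional independent draws (default 11
#' in total) to confirm that the estimates are robust to the sampling.
#'
#' @param sample_size predictions per draw.
#' @param n_repeats number of independent draws.
#' @param seed integer seed for the sampling stream.
#' @param stratum optional named list `list(column =, value =)` restricting
#'   sampling to metadata rows where `column == value`.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_size = 2500, n_repeats = 11, seed = 1,
                        stratum = NULL) {
  stopifnot(sample_size >= 1, n_repeats >= 1)
  structure(list(sample_size = as.integer(sample_size),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 stratum = stratum),
            class = "sample_spec")
}

#' Draw seeded random subsamples of an ensemble table
#'
#' Draws `spec$n_repeats` independent samples without replacement.  All
#' repeats are drawn from a single random stream initialized from
#' `spec$seed`, so the same spec always reproduces the same samples and
#' repeat r depends only on the seed and r.
#'
#' @param table an [ensemble_table()].
#' @param meta metadata `data.frame` (see [validate_meta()]); may be `NULL`
#'   when no stratum filter is needed.
#' @param spec a [sample_spec()].
#' @return A list of length `n_repeats`; each element is a list with
#'   components `table` (subset `ensemble_table`) and `meta` (matching
#'   metadata rows, or `NULL`).
#' @export
subsample <- function(table, meta = NULL, spec = sample_spec()) {
  stopifnot(inherits(table, "ensemble_table"), inherits(spec, "sample_spec"))
  ids <- table$prediction_ids
  if (!is.null(meta)) meta <- validate_meta(meta, table)
  if (!is.null(spec$stratum)) {
    if (is.null(meta)) stop("stratum filter requires metadata")
    col <- spec$stratum$column
    if (!col %in% names(meta)) stop("unknown stratum column '", col, "'")
    keep <- meta[[col]] == spec$stratum$value
    ids <- ids[keep]
  }
  if (spec$sample_size > length(ids))
    stop("sample_size (", spec$sample_size, ") exceeds available ",
         "predictions (", length(ids), ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_repeats), function(r) {
    chosen <- sample(ids, spec$sample_size)
    list(table = subset_ensemble_table(table, chosen),
         meta = if (is.null(meta)) NULL
                else meta[match(chosen, meta$prediction_id), , drop = FALSE])
  })
}

#' Compare covariate distributions of a sample against its population
#'
#' Tabulates each variable into bins and reports counts and percentages
#' for the sample and the population side by side, plus the maximum
#' absolute percentage difference per variable — the check used to confirm
#' that a random subsample is representative before trusting the
#' decomposition estimated from it.
#'
#' @param sample_meta metadata rows of the sampled predictions.
#' @param population_meta metadata rows of the full prediction set.
#' @param variables character vector of column names to compare.
#' @param bins optional named list of explicit bin edges per numeric
#'   variable; by default, population quartiles are used.  Categorical
#'   variables are tabulated by level.
#' @return A `data.frame` with columns `variable`, `bin`, `n_sample`,
#'   `pct_sample`, `n_population`, `pct_population`, `abs_diff`, carrying
#'   a `max_abs_diff` attribute (named by variable).
#' @export
representativeness_report <- function(sample_meta, population_meta,
                                      variables, bins = NULL) {
  stopifnot(is.data.frame(sample_meta), is.data.frame(population_meta))
  rows <- list()
  for (v in variables) {
    if (!v %in% names(population_meta) || !v %in% names(sample_meta))
      stop("unknown variable '", v, "'")
    pv <- population_meta[[v]]
    sv <- sample_meta[[v]]
    if (is.numeric(pv)) {
      edges <- if (!is.null(bins) && v %in% names(bins)) bins[[v]]
               else unique(stats::quantile(pv, c(0, .25, .5, .75, 1)))
      edges[1L] <- min(edges[1L], min(pv), min(sv))
      edges[length(edges)] <- max(edges[length(edges)], max(pv), max(sv))
      pc <- cut(pv, edges, include.lowest = TRUE)
      sc <- cut(sv, edges, include.lowest = TRUE)
    } else {
      lev <- sort(unique(as.character(pv)))
      pc <- factor(as.character(pv), levels = lev)
      sc <- factor(as.character(sv), levels = lev)
    }
    tp <- table(pc); ts <- table(sc)
    rows[[v]] <- data.frame(
      variable = v, bin = names(tp),
      n_sample = as.integer(ts),
      pct_sample = 100 * as.integer(ts) / sum(ts),
      n_population = as.integer(tp),
      pct_population = 100 * as.integer(tp) / sum(tp),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$abs_diff <- abs(out$pct_sample - out$pct_population)
  md <- tapply(out$abs_diff, out$variable, max)[unique(out$variable)]
  attr(out, "max_abs_diff") <- stats::setNames(as.numeric(md), names(md))
  out
}
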