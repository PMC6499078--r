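#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a list.  All problems are collected and
#' reported together rather than failing at the first one.
#'
#' Recognized keys: `ensembles` and `meta` (input CSV paths; required
#' unless `simulate: n_pred` asks for a synthetic study), `sample`
#' (`size`, `repeats`), `percentile`, `strata`, `covariates`, `grid_n`,
#' `alpha`, `seed`, `outdir`.
#'
#' @param config a YAML file path or a named list.
#' @return A validated config list of class `run_config`, or an error
#'   listing every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(sample = list(size = 2500L, repeats = 11L),
                   percentile = 80, grid_n = 50, alpha = 5e-7,
                   seed = 1L, covariates = NULL, strata = NULL,
                   outdir = ".")
  for (k in names(defaults))
    if (!k %in% names(config)) config[[k]] <- defaults[[k]]
  if (is.null(config$sample$size)) config$sample$size <- 2500L
  if (is.null(config$sample$repeats)) config$sample$repeats <- 11L
  errors <- character()
  simulated <- !is.null(config$simulate)
  if (!simulated) {
    if (is.null(config$ensembles))
      errors <- c(errors, "missing required field 'ensembles' (CSV path)")
    else if (!file.exists(config$ensembles))
      errors <- c(errors, paste0("ensembles file not found: ", config$ensembles))
    if (is.null(config$meta))
      errors <- c(errors, "missing required field 'meta' (CSV path)")
    else if (!file.exists(config$meta))
      errors <- c(errors, paste0("meta file not found: ", config$meta))
  }
  if (config$percentile <= 0 || config$percentile >= 100)
    errors <- c(errors, "percentile must lie in (0, 100)")
  if (config$alpha <= 0 || config$alpha >= 1)
    errors <- c(errors, "alpha must lie in (0, 1)")
  if (config$sample$size < 1)
    errors <- c(errors, "sample size must be >= 1")
  if (config$sample$repeats < 1)
    errors <- c(errors, "sample repeats must be >= 1")
  if (config$grid_n < 2)
    errors <- c(errors, "grid_n must be >= 2")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(config) <- c("run_config", "list")
  config
}

#' Run the full SMME analysis pipeline
#'
#' Executes the whole chain on one dataset: subsample, SUMA
#' decomposition (with repeats), optional stratified decomposition,
#' high/low SMME labelling, group comparison and tabulation, spatial GAM
#' with odds-ratio surface and covariate odds ratios.  All tables are
#' written to `config$outdir` together with a machine-readable JSON
#' summary carrying full provenance (seed, package version, config
#' hash).
#'
#' @param config a [validate_config()]-accepted configuration (list or
#'   YAML path).
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `smme_report`: list with `components`,
#'   `spread`, `strata` (or `NULL`), `labels`, `comparison`,
#'   `tabulation`, `gam`, `surface`, `or_table`, `selection`, `provenance`.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), s, units = "secs"))))
    out
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_study,
                     c(config$simulate, list(seed = config$seed)))
      list(table = sim$table, meta = sim$meta)
    } else {
      tb <- read_ensemble_table(config$ensembles)
      mt <- validate_meta(read_prediction_meta(config$meta), tb)
      list(table = tb, meta = mt)
    }
  })

  spec <- sample_spec(min(config$sample$size, nrow(inputs$table$values)),
                      config$sample$repeats, config$seed)
  suma <- stage("decompose", run_suma(inputs$table, inputs$meta, spec))
  strata <- if (!is.null(config$strata))
    stage("stratify", stratified_suma(inputs$table, inputs$meta,
                                      config$strata, spec))

  first <- suma$samples[[1L]]
  labels <- stage("label", {
    pr <- pairwise_stats(first$table)
    dichotomize(mean_covariances(pr), config$percentile)
  })

  vars <- config$covariates %||%
    setdiff(names(first$meta)[vapply(first$meta, is.numeric, logical(1))],
            c("x", "y"))
  comparison <- stage("compare", compare_groups(labels, first$meta, vars))
  tab_by <- intersect(c("season", "period", "region"),
                      c(names(first$meta),
                        if ("date" %in% names(first$meta)) "season"))
  tabulation <- lapply(stats::setNames(tab_by, tab_by), function(b)
    tabulate_labels(labels, first$meta, b))

  gam <- stage("map", fit_smme_gam(labels, first$meta, config$covariates))
  surface <- stage("surface",
                   predict_surface(gam, grid_n = config$grid_n,
                                   alpha = config$alpha))
  or_table <- if (length(config$covariates))
    covariate_odds_ratios(gam)

  provenance <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("sumaerr")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    config_hash = .config_hash(config))

  report <- structure(
    list(components = suma$components, spread = suma$spread,
         strata = strata, labels = labels, comparison = comparison,
         tabulation = tabulation, gam = gam, surface = surface,
         or_table = or_table, provenance = provenance),
    class = "smme_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report bundle to disk
#'
#' Writes `components.csv` (component/value/SE/p rows), `labels.csv`,
#' `comparison.csv`, per-grouping `tabulation_*.csv`, `strata.csv` when
#' stratified, `surface.geojson`, `or_table.csv` when covariates were
#' modelled, and `summary.json` with every estimate plus provenance.
#'
#' @param report an `smme_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "smme_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  w(as.data.frame(report$components), "components.csv")
  w(as.data.frame(report$labels), "labels.csv")
  w(report$comparison, "comparison.csv")
  for (b in names(report$tabulation))
    w(report$tabulation[[b]], paste0("tabulation_", b, ".csv"))
  if (!is.null(report$strata)) w(report$strata$table, "strata.csv")
  if (!is.null(report$or_table)) w(report$or_table, "or_table.csv")
  write_surface_geojson(report$surface, file.path(outdir, "surface.geojson"))
  summary <- list(
    components = list(sigma_SM2 = report$components$sigma_SM2,
                      sigma_M2 = report$components$sigma_M2,
                      sigma_SA2 = report$components$sigma_SA2,
                      sigma_A2 = report$components$sigma_A2,
                      raw = as.list(report$components$raw),
                      truncated = as.list(report$components$truncated)),
    spread = report$spread,
    strata = if (!is.null(report$strata)) report$strata$table,
    labels = list(n_high = sum(report$labels$label == "high"),
                  n_low = sum(report$labels$label == "low"),
                  threshold = attr(report$labels, "threshold"),
                  percentile = attr(report$labels, "percentile")),
    gam = list(s_p_value = report$gam$s_p_value,
               or_range = attr(report$surface, "or_range"),
               n_flagged = attr(report$surface, "n_flagged"),
               alpha = attr(report$surface, "alpha")),
    or_table = report$or_table,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.smme_report <- function(x, ...) {
  cat("SMME analysis report\n====================\n\n")
  print(x$components)
  cat("\n")
  print(x$labels)
  cat("\n")
  print(x$gam)
  cat("\n")
  print(x$surface)
  invisible(x)
}
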