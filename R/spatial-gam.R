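#' Logistic GAM for the odds of high SMME over space
#'
#' Models the log-odds that a prediction carries high shared
#' multiplicative measurement error as a bivariate smooth of its planar
#' location plus optional parametric covariate terms:
#' `logit p(x, y) = s(x, y) + gamma' covariates`, with `low` as the
#' reference group.  The smooth is a penalized thin-plate regression
#' spline fitted with `mgcv`, with smoothness chosen by REML.
#'
#' @param labels an `smme_labels` object (see [dichotomize()]).
#' @param meta metadata with `prediction_id`, planar `x`, `y` in meters,
#'   and any covariate columns.
#' @param covariates character vector of metadata columns to include as
#'   parametric terms (numeric columns enter linearly; character/factor
#'   columns as factors).
#' @param k basis dimension of the spatial smooth.
#' @return An object of class `smme_gam`: list with the fitted `mgcv`
#'   model (`fit`), the model `data`, the covariate names, and two tests
#'   of the spatial term: `s_p_value`, the approximate Wald-type p-value
#'   of the smooth (well calibrated but conservative), and `lrt_p_value`,
#'   the deviance (likelihood-ratio) test against the same model without
#'   the smooth — the usual overall test of whether the odds of high SMME
#'   vary over space (slightly anticonservative at loose thresholds; use
#'   stringent ones).
#' @export
fit_smme_gam <- function(labels, meta, covariates = NULL, k = 30) {
  stopifnot(inherits(labels, "smme_labels"))
  d <- merge(as.data.frame(labels), meta, by = "prediction_id")
  if (!all(c("x", "y") %in% names(d)))
    stop("metadata must provide planar coordinates 'x' and 'y' (meters)")
  if (nrow(d) < 100L)
    stop("need at least 100 labelled predictions to fit the spatial model")
  d$high <- as.integer(d$label == "high")
  for (v in covariates) {
    if (!v %in% names(d)) stop("unknown covariate '", v, "'")
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  rhs <- paste(c(sprintf("s(x, y, k = %d)", k), covariates), collapse = " + ")
  fit <- try(mgcv::gam(stats::as.formula(paste("high ~", rhs)),
                       family = stats::binomial(), data = d,
                       method = "REML"), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("GAM fit failed: ", attr(fit, "condition")$message)
  if (!fit$converged)
    stop("GAM did not converge (possible separation); covariates: ",
         paste(covariates, collapse = ", "))
  st <- summary(fit)$s.table
  # overall test of the location term: deviance comparison against the
  # same model with the smooth removed
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit0 <- stats::glm(stats::as.formula(paste("high ~", rhs0)),
                     family = stats::binomial(), data = d)
  lrt <- stats::anova(fit0, fit, test = "Chisq")
  structure(list(fit = fit, data = d, covariates = covariates %||% character(),
                 k = k, s_p_value = unname(st[1L, "p-value"]),
                 lrt_p_value = lrt[2L, "Pr(>Chi)"]),
            class = "smme_gam")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.smme_gam <- function(x, ...) {
  cat("Logistic GAM for odds of high SMME\n")
  cat("  n =", nrow(x$data), " predictions;",
      sum(x$data$high), "high\n")
  cat("  spatial smooth: s(x, y), k =", x$k,
      "; approx. p =", format.pval(x$s_p_value),
      "; overall LRT p =", format.pval(x$lrt_p_value), "\n")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Representative covariate values used when predicting the spatial
# surface: median for numeric terms, most frequent level for factors.
.reference_covariates <- function(model) {
  out <- list()
  for (v in model$covariates) {
    col <- model$data[[v]]
    out[[v]] <- if (is.numeric(col)) stats::median(col)
                else factor(names(which.max(table(col))), levels = levels(col))
  }
  out
}

#' Predict the odds-ratio surface of high SMME on a spatial grid
#'
#' Evaluates the fitted model on an evenly spaced grid clipped to the
#' convex hull of the observed locations.  Each grid point's odds ratio
#' is relative to the sample-average predicted log-odds; a point is
#' flagged `hot` (or `cold`) when its pointwise `(1 - alpha)` z-interval
#' on the link scale lies entirely above (below) that reference.
#' Covariates, if any, are held at their sample median (numeric) or modal
#' level (factor), so the surface isolates the spatial term.
#'
#' @param model an `smme_gam`.
#' @param grid_n grid resolution per axis (default 50); alternatively
#'   give `spacing` in meters.
#' @param spacing optional grid spacing in meters (overrides `grid_n`).
#' @param alpha pointwise significance level for flagging; the default
#'   `5e-7` reflects a false-discovery-rate-style correction for the many
#'   grid points examined.
#' @return An object of class `smme_surface`: a `data.frame` with `x`,
#'   `y`, `or`, `se_link`, `flag` (`none`/`hot`/`cold`), with attributes
#'   `or_range`, `alpha`, `reference_logodds`, `n_flagged`.
#' @export
predict_surface <- function(model, grid_n = 50, spacing = NULL, alpha = 5e-7) {
  stopifnot(inherits(model, "smme_gam"))
  if (!is.null(spacing) && spacing <= 0) stop("grid spacing must be > 0")
  if (is.null(spacing) && grid_n < 2) stop("grid_n must be at least 2")
  d <- model$data
  xr <- range(d$x); yr <- range(d$y)
  xs <- if (!is.null(spacing)) seq(xr[1L], xr[2L], by = spacing)
        else seq(xr[1L], xr[2L], length.out = grid_n)
  ys <- if (!is.null(spacing)) seq(yr[1L], yr[2L], by = spacing)
        else seq(yr[1L], yr[2L], length.out = grid_n)
  grid <- expand.grid(x = xs, y = ys)
  hull <- grDevices::chull(d$x, d$y)
  bnd <- cbind(d$x[c(hull, hull[1L])], d$y[c(hull, hull[1L])])
  inside <- mgcv::in.out(bnd, as.matrix(grid))
  grid <- grid[inside, , drop = FALSE]
  for (v in names(.reference_covariates(model)))
    grid[[v]] <- .reference_covariates(model)[[v]]
  pr <- mgcv::predict.gam(model$fit, newdata = grid, type = "link",
                          se.fit = TRUE)
  eta0 <- mean(mgcv::predict.gam(model$fit, type = "link"))
  zc <- stats::qnorm(1 - alpha / 2)
  eta <- as.vector(pr$fit); se <- as.vector(pr$se.fit)
  flag <- rep("none", nrow(grid))
  flag[eta - zc * se > eta0] <- "hot"
  flag[eta + zc * se < eta0] <- "cold"
  out <- data.frame(x = grid$x, y = grid$y, or = exp(eta - eta0),
                    se_link = se, flag = factor(flag, c("none", "hot", "cold")),
                    stringsAsFactors = FALSE)
  attr(out, "or_range") <- range(out$or)
  attr(out, "alpha") <- alpha
  attr(out, "reference_logodds") <- eta0
  attr(out, "n_flagged") <- sum(flag != "none")
  class(out) <- c("smme_surface", "data.frame")
  out
}

#' @export
print.smme_surface <- function(x, ...) {
  orr <- attr(x, "or_range")
  cat("SMME odds-ratio surface:", nrow(x), "grid points inside hull\n")
  cat(sprintf("  OR range %.2f to %.2f; %d point(s) flagged at alpha = %g\n",
              orr[1L], orr[2L], attr(x, "n_flagged"), attr(x, "alpha")))
  invisible(x)
}

#' Iterative single-covariate selection for the spatial model
#'
#' Starting from the location-only model, each candidate covariate is
#' added in turn and its effect on the predicted odds-ratio surface is
#' measured.  A candidate is retained automatically when it changes the
#' OR range — the width (max - min) or either endpoint — by at least
#' `threshold` (default 10%) relative to the model without it.  The
#' change in the spatial pattern itself (flagged-area Jaccard overlap
#' between successive surfaces) is reported for review but never decides
#' retention on its own.
#'
#' Retained candidates accumulate: each subsequent candidate is judged
#' against the model containing all previously retained ones.
#'
#' @param labels an `smme_labels`.
#' @param meta metadata with coordinates and candidates.
#' @param candidates character vector of covariate names to try, in
#'   order.
#' @param threshold relative OR-range change required for retention.
#' @param grid_n,alpha,k passed to [predict_surface()] / [fit_smme_gam()].
#' @return An object of class `smme_selection`: list with `steps` (one
#'   row per candidate: OR range before/after, relative changes, Jaccard
#'   overlap of flagged sets, retained flag), `selected` (character
#'   vector), and `final_model` (an `smme_gam` with the selected
#'   covariates).
#' @export
select_covariates <- function(labels, meta, candidates, threshold = 0.10,
                              grid_n = 40, alpha = 5e-7, k = 30) {
  stopifnot(length(candidates) >= 1L)
  selected <- character()
  base_model <- fit_smme_gam(labels, meta, selected, k = k)
  base_surface <- predict_surface(base_model, grid_n = grid_n, alpha = alpha)
  steps <- list()
  for (cand in candidates) {
    m1 <- fit_smme_gam(labels, meta, c(selected, cand), k = k)
    s1 <- predict_surface(m1, grid_n = grid_n, alpha = alpha)
    r0 <- attr(base_surface, "or_range"); r1 <- attr(s1, "or_range")
    w0 <- diff(r0); w1 <- diff(r1)
    rel <- c(width = if (w0 > 0) abs(w1 - w0) / w0 else as.numeric(w1 > 0),
             min = abs(r1[1L] - r0[1L]) / r0[1L],
             max = abs(r1[2L] - r0[2L]) / r0[2L])
    f0 <- base_surface$flag != "none"; f1 <- s1$flag != "none"
    un <- sum(f0 | f1)
    jac <- if (un > 0) sum(f0 & f1) / un else NA_real_
    retain <- any(rel >= threshold)
    steps[[cand]] <- data.frame(
      candidate = cand, or_min_before = r0[1L], or_max_before = r0[2L],
      or_min_after = r1[1L], or_max_after = r1[2L],
      rel_change_width = rel[["width"]], rel_change_min = rel[["min"]],
      rel_change_max = rel[["max"]], flag_jaccard = jac,
      retained = retain, stringsAsFactors = FALSE)
    if (retain) {
      selected <- c(selected, cand)
      base_model <- m1
      base_surface <- s1
    }
  }
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  structure(list(steps = steps, selected = selected,
                 final_model = base_model, final_surface = base_surface,
                 threshold = threshold),
            class = "smme_selection")
}

#' @export
print.smme_selection <- function(x, ...) {
  cat("Iterative covariate selection (OR-range change >=",
      sprintf("%.0f%%", 100 * x$threshold), "retains)\n")
  print(transform(x$steps[, c("candidate", "rel_change_width",
                              "rel_change_min", "rel_change_max",
                              "retained")],
                  rel_change_width = signif(rel_change_width, 3),
                  rel_change_min = signif(rel_change_min, 3),
                  rel_change_max = signif(rel_change_max, 3)))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Covariate odds ratios from a fitted spatial model
#'
#' Continuous covariates are reported per interquartile-range increase
#' (`OR = exp(beta * IQR)`, with the IQR taken from the model data unless
#' supplied); categorical covariates are reported per level against the
#' reference level.  Confidence intervals are Wald 95% intervals.
#'
#' @param model an `smme_gam` with at least one covariate.
#' @param iqr optional named numeric vector of IQRs overriding the
#'   data-derived ones.
#' @return A `data.frame` with `term`, `scale` (e.g. `"per IQR = 5.89"`),
#'   `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
covariate_odds_ratios <- function(model, iqr = NULL) {
  stopifnot(inherits(model, "smme_gam"))
  if (!length(model$covariates)) stop("model has no parametric covariates")
  sm <- summary(model$fit)$p.table
  rows <- list()
  for (v in model$covariates) {
    col <- model$data[[v]]
    if (is.numeric(col)) {
      width <- if (!is.null(iqr) && v %in% names(iqr)) iqr[[v]]
               else unname(diff(stats::quantile(col, c(.25, .75))))
      if (!is.finite(width) || width <= 0)
        stop("IQR for continuous covariate '", v, "' must be > 0")
      b <- sm[v, "Estimate"]; se <- sm[v, "Std. Error"]
      rows[[v]] <- data.frame(
        term = v, scale = sprintf("per IQR = %.4g", width),
        or = exp(b * width),
        ci_low = exp((b - 1.96 * se) * width),
        ci_high = exp((b + 1.96 * se) * width),
        p_value = sm[v, "Pr(>|z|)"], stringsAsFactors = FALSE)
    } else {
      lev <- levels(col)
      for (l in lev[-1L]) {
        nm <- paste0(v, l)
        b <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]
        rows[[nm]] <- data.frame(
          term = nm, scale = sprintf("vs %s", lev[1L]),
          or = exp(b), ci_low = exp(b - 1.96 * se),
          ci_high = exp(b + 1.96 * se),
          p_value = sm[nm, "Pr(>|z|)"], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an odds-ratio surface as GeoJSON points
#'
#' @param surface an `smme_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(surface, path) {
  stopifnot(inherits(surface, "smme_surface"))
  features <- lapply(seq_len(nrow(surface)), function(k) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(surface$x[k], surface$y[k])),
         properties = list(or = surface$or[k],
                           se_link = surface$se_link[k],
                           flag = as.character(surface$flag[k])))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
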