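#' Closed-form ordinary least squares on complete pairs
#'
#' Core sums-of-squares OLS used by both the log-log scaling fits and the
#' high-frequency calibration. Returns slope, intercept, Pearson r, R^2,
#' slope standard error and residuals. Residual-free (exact) designs are
#' detected with a relative tolerance so that noise-free data behave as the
#' continuous limit.
#'
#' @keywords internal
#' @noRd
.ols <- function(x, y, min_n = 3) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) {
    stop(sprintf("at least %d complete pairs required (got %d)", min_n, n),
         call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: predictor is constant", call. = FALSE)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  sse <- max(syy - b * sxy, 0)
  if (syy > 0 && sse < 1e-12 * syy) sse <- 0   # numerically exact fit
  r <- if (syy == 0) 1 else sxy / sqrt(sxx * syy)
  r2 <- if (syy == 0) 1 else b * sxy / syy
  se <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  res <- y - (a + b * x)
  if (sse == 0) res[] <- 0
  list(n = n, slope = b, intercept = a, r = r, r2 = r2, se_slope = se,
       residuals = res, sse = sse, keep = keep,
       x = x, y = y, x_range = range(x))
}

#' Isometric slope expected for a trait class
#'
#' On log-log axes against a linear skull dimension, geometric similarity
#' predicts slope 3 for volumes, 2 for areas and 1 for lengths.
#'
#' @param trait Canonical trait name.
#' @return Expected slope (3, 2 or 1).
#' @export
expected_slope <- function(trait) {
  vapply(trait, function(t) {
    if (startsWith(t, "v_")) 3
    else if (startsWith(t, "a_")) 2
    else 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Log10-transform selected cohort measurements
#'
#' @param x An `ear_cohort`.
#' @param traits Character vector of measurement columns.
#' @return Numeric matrix of base-10 logarithms, one row per specimen
#'   (rownames are specimen ids); missing values propagate as `NA`.
#' @export
log10_transform <- function(x, traits) {
  stopifnot(inherits(x, "ear_cohort"))
  bad_cols <- setdiff(traits, names(x))
  if (length(bad_cols)) {
    stop("unknown trait(s): ", paste(bad_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- sapply(traits, function(t) {
    v <- x[[t]]
    neg <- which(!is.na(v) & v <= 0)
    if (length(neg)) {
      stop(sprintf("cannot log-transform non-positive value (trait '%s', specimen '%s')",
                   t, x$specimen_id[neg[1]]), call. = FALSE)
    }
    log10(v)
  })
  m <- matrix(m, nrow = nrow(x), dimnames = list(x$specimen_id, traits))
  m
}

#' Pairwise Pearson correlation matrix between ear traits and skull variables
#'
#' Correlations are computed over fit-role specimens only, on base-10
#' logarithms of all measurements except the dimensionless cephalic index,
#' which enters unlogged. Each cell uses pairwise-complete observations; a
#' cell with fewer than 3 complete pairs is reported as `NA` (undefined), not
#' zero. Per-cell sample sizes are attached as attribute `"n"`.
#'
#' @param x An `ear_cohort`.
#' @param ear_traits Trait columns (default the seven standard ear traits).
#' @param skull_vars Skull variables; `"cephalic_index"` is computed from
#'   `msw` and `cbl` if not already a column.
#' @return Matrix of r with rows = skull variables, cols = ear traits;
#'   attribute `"n"` holds the per-cell pair counts.
#' @export
pearson_matrix <- function(x,
                           ear_traits = c("v_cav", "v_mal", "v_inc", "v_stp",
                                          "v_lab", "a_tm", "a_fp"),
                           skull_vars = c("cbl", "msw", "iw",
                                          "cephalic_index")) {
  stopifnot(inherits(x, "ear_cohort"))
  fx <- fit_specimens(x)
  logs <- log10_transform(fx, ear_traits)
  skull <- sapply(skull_vars, function(v) {
    if (v == "cephalic_index") {
      ci <- if ("cephalic_index" %in% names(fx)) fx$cephalic_index
            else 100 * fx$msw / fx$cbl
      ci   # dimensionless: used raw, not logged
    } else {
      log10(fx[[v]])
    }
  })
  skull <- matrix(skull, nrow = nrow(fx),
                  dimnames = list(fx$specimen_id, skull_vars))
  r <- matrix(NA_real_, length(skull_vars), length(ear_traits),
              dimnames = list(skull_vars, ear_traits))
  nmat <- r
  for (i in seq_along(skull_vars)) {
    for (j in seq_along(ear_traits)) {
      ok <- stats::complete.cases(skull[, i], logs[, j])
      nmat[i, j] <- sum(ok)
      if (sum(ok) >= 3) {
        r[i, j] <- stats::cor(skull[ok, i], logs[ok, j])
      }
    }
  }
  attr(r, "n") <- nmat
  r
}

#' Fit a log-log scaling relationship and test it against isometry
#'
#' Ordinary least-squares regression of `y` (log10 trait) on `x` (log10 skull
#' metric): slope `b = Sxy/Sxx`, intercept `a = mean(y) - b*mean(x)`,
#' `R^2 = b*Sxy/Syy`, `se_b = sqrt((Syy - b*Sxy)/(n-2)/Sxx)`. The slope is
#' tested against the isometric expectation with a two-tailed Student-t
#' statistic `t = (b - expected)/se_b` on `n - 2` degrees of freedom. In the
#' residual-free degenerate case (`se_b = 0`) the p-value is defined as 1 if
#' the slope equals the expectation exactly and 0 otherwise (continuous
#' limit).
#'
#' @param x,y Numeric vectors of equal length (already log10-transformed);
#'   incomplete pairs are dropped.
#' @param expected Expected (isometric) slope for the trait class.
#' @param trait,predictor Labels carried into the result.
#' @param ids Optional specimen identifiers naming the residuals.
#' @return An object of class `loglog_fit` with fields `trait`, `predictor`,
#'   `n`, `slope`, `intercept`, `r`, `r2`, `se_slope`, `expected_slope`,
#'   `t_stat`, `p_value`, `residuals`, `sd_resid`, `x_range`.
#' @examples
#' f <- fit_loglog(1:5, c(1, 3, 2, 5, 4), expected = 3)
#' f$slope; f$r2; f$p_value
#' @export
fit_loglog <- function(x, y, expected, trait = "trait", predictor = "x",
                       ids = NULL) {
  stopifnot(length(x) == length(y))
  o <- .ols(x, y, min_n = 3)
  res <- o$residuals
  if (!is.null(ids)) names(res) <- ids[o$keep]
  sd_resid <- stats::sd(res)
  expected <- unname(expected)
  if (o$sse == 0) {
    t_stat <- NA_real_
    p <- if (abs(o$slope - expected) <= 1e-12 * max(1, abs(expected))) 1
         else 0
  } else {
    t_stat <- (o$slope - expected) / o$se_slope
    p <- 2 * stats::pt(-abs(t_stat), df = o$n - 2)
  }
  structure(list(trait = trait, predictor = predictor, n = o$n,
                 slope = o$slope, intercept = o$intercept,
                 r = o$r, r2 = o$r2, se_slope = o$se_slope,
                 expected_slope = expected, t_stat = t_stat, p_value = p,
                 residuals = res, sd_resid = sd_resid,
                 x_range = o$x_range),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("log10(%s) ~ log10(%s), n = %d\n", x$trait, x$predictor, x$n))
  cat(sprintf("  slope %.4f (se %.4f), intercept %.4f, R^2 %.3f\n",
              x$slope, x$se_slope, x$intercept, x$r2))
  cat(sprintf("  isometry test vs slope %g: t = %s, p = %.4g (%s allometry)\n",
              x$expected_slope,
              if (is.na(x$t_stat)) "NA" else sprintf("%.3f", x$t_stat),
              x$p_value,
              if (x$slope < x$expected_slope) "negative" else "positive"))
  invisible(x)
}

#' Standardized residuals and outlier flags for a scaling fit
#'
#' Each residual is divided by the sample standard deviation (n-1
#' denominator) of all fit residuals; specimens with |z| > `threshold`
#' (default 2) are flagged as outliers. If all residuals are zero, all z are
#' defined as 0 and nothing is flagged.
#'
#' @param fit A `loglog_fit`.
#' @param threshold Outlier flag threshold on |z|.
#' @return Data frame with columns `specimen`, `residual`, `z`, `outlier`.
#' @export
standardized_residuals <- function(fit, threshold = 2) {
  stopifnot(inherits(fit, "loglog_fit"))
  res <- fit$residuals
  z <- if (fit$sd_resid == 0) rep(0, length(res)) else res / fit$sd_resid
  data.frame(
    specimen = if (is.null(names(res))) as.character(seq_along(res))
               else names(res),
    residual = unname(res), z = unname(z),
    outlier = abs(unname(z)) > threshold,
    stringsAsFactors = FALSE
  )
}

#' Project a held-out specimen onto a fitted scaling relationship
#'
#' Computes the standardized deviation of a specimen that did not enter the
#' fit (e.g. a mongrel or wolf) from the regression line, using the fit's own
#' residual standard deviation: `z = (y0 - (a + b*x0)) / sd_resid`. The
#' held-out point does not perturb the fit. A warning is issued if `x0` lies
#' outside the fitted predictor range by more than 20% of that range.
#'
#' @param fit A `loglog_fit`.
#' @param x0 log10 predictor value of the held-out specimen.
#' @param y0 log10 trait value of the held-out specimen.
#' @return Standardized deviation z (NA with a warning if the fit has zero
#'   residual variance).
#' @export
project_specimen <- function(fit, x0, y0) {
  stopifnot(inherits(fit, "loglog_fit"))
  rng <- fit$x_range
  margin <- 0.2 * diff(rng)
  if (x0 < rng[1] - margin || x0 > rng[2] + margin) {
    warning(sprintf("x0 = %.4g lies well outside the fitted range [%.4g, %.4g]",
                    x0, rng[1], rng[2]), call. = FALSE)
  }
  if (fit$sd_resid == 0) {
    warning("fit has zero residual variance: projection z is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (y0 - (fit$intercept + fit$slope * x0)) / fit$sd_resid
}

#' Predict a trait value in natural units from a scaling fit
#'
#' Evaluates the fitted power law `10^(a + b*log10(cbl))` at a skull length,
#' returning the trait in its canonical unit (mm^3 for volumes, mm^2 for
#' areas).
#'
#' @param fit A `loglog_fit`.
#' @param cbl Skull metric value in mm (> 0).
#' @return Predicted trait value.
#' @export
predict_trait <- function(fit, cbl) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (any(cbl <= 0)) stop("cbl must be > 0", call. = FALSE)
  10^(fit$intercept + fit$slope * log10(cbl))
}

#' Fit all ear traits against a skull metric
#'
#' Runs [fit_loglog()] for each trait on fit-role specimens, with the
#' isometric expected slope for its class, dropping specimens missing that
#' trait (per-trait casewise deletion, never whole-specimen deletion).
#'
#' @param x An `ear_cohort`.
#' @param traits Trait columns (default [ear_traits()]).
#' @param predictor Skull metric column (default `"cbl"`).
#' @return Named list of `loglog_fit` objects, class `loglog_fit_list`.
#' @export
fit_cohort <- function(x, traits = ear_traits(), predictor = "cbl") {
  stopifnot(inherits(x, "ear_cohort"))
  fx <- fit_specimens(x)
  if (nrow(fx) < 3) {
    stop("at least 3 fit-role specimens are required", call. = FALSE)
  }
  lx <- log10_transform(fx, predictor)[, 1]
  fits <- lapply(traits, function(t) {
    ly <- log10_transform(fx, t)[, 1]
    fit_loglog(lx, ly, expected = expected_slope(t), trait = t,
               predictor = predictor, ids = fx$specimen_id)
  })
  names(fits) <- traits
  structure(fits, class = "loglog_fit_list")
}

#' Summarise a list of scaling fits as a regression table
#'
#' One row per trait: expected slope, measured slope, slope SE, intercept,
#' R^2, r, n, isometry-test t and p.
#'
#' @param object A `loglog_fit_list`.
#' @param ... Unused.
#' @return A data frame.
#' @export
summary.loglog_fit_list <- function(object, ...) {
  rows <- lapply(object, function(f) {
    data.frame(trait = f$trait, n = f$n,
               expected_slope = f$expected_slope,
               slope = f$slope, se_slope = f$se_slope,
               intercept = f$intercept, r = f$r, r2 = f$r2,
               t_stat = f$t_stat, p_value = f$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
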