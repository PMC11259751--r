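#' Options controlling a full cohort analysis
#'
#' @param predictor Skull metric used as the regression x-axis (default
#'   `"cbl"`).
#' @param traits Ear traits to fit (default [ear_traits()]).
#' @param skull_vars Variables for the correlation matrix.
#' @param outlier_threshold |z| threshold for outlier flags (default 2).
#' @param densities Ossicular [canid_densities()] table.
#' @param comparison_pair Character vector of two specimen ids for the
#'   low-frequency acoustic comparison (numerator first); `NULL` selects the
#'   largest- vs smallest-CBL specimens.
#' @param f_high_calibration Optional data frame with columns `mass_mg` and
#'   `f_high_khz` used to calibrate the high-frequency predictor; `NULL`
#'   omits f_high predictions.
#' @return A list of class `analysis_options`.
#' @export
analysis_options <- function(predictor = "cbl", traits = ear_traits(),
                             skull_vars = c("cbl", "msw", "iw",
                                            "cephalic_index"),
                             outlier_threshold = 2,
                             densities = canid_densities(),
                             comparison_pair = NULL,
                             f_high_calibration = NULL) {
  structure(list(predictor = predictor, traits = traits,
                 skull_vars = skull_vars,
                 outlier_threshold = outlier_threshold,
                 densities = densities,
                 comparison_pair = comparison_pair,
                 f_high_calibration = f_high_calibration),
            class = "analysis_options")
}

#' FNV-1a hash of a character scalar, as 8 hex digits
#' @keywords internal
#' @noRd
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full scaling and acoustics analysis on a cohort
#'
#' The end-to-end chain: derive morphometrics (masses, cephalic index, area
#' ratios), compute the Pearson correlation matrix between ear traits and
#' skull variables, fit every trait's log-log regression on the predictor
#' with an isometry test (fit-role specimens only), flag standardized-
#' residual outliers, project `role = "projected"` specimens (e.g. mongrel,
#' wolf) onto the fitted lines, and compute low-frequency acoustic gains for
#' a comparison pair plus, when a calibration is supplied, per-specimen
#' high-frequency limit predictions. Deterministic given cohort and options.
#' No multiple-testing correction is applied across the trait fits.
#'
#' @param x An `ear_cohort`.
#' @param options An [analysis_options()] list.
#' @return An object of class `ear_analysis_report` with fields
#'   `correlation_table`, `fits`, `regression_table`, `outliers`,
#'   `projections`, `acoustics`, `derived`, `provenance`.
#' @export
run_analysis <- function(x, options = analysis_options()) {
  stopifnot(inherits(x, "ear_cohort"), inherits(options, "analysis_options"))
  if (sum(x$role == "fit") < 3) {
    stop("pipeline error: fewer than 3 fit-role specimens", call. = FALSE)
  }
  dx <- derive_morphometrics(x, options$densities)
  corr <- pearson_matrix(dx, ear_traits = options$traits,
                         skull_vars = options$skull_vars)
  fits <- fit_cohort(dx, traits = options$traits,
                     predictor = options$predictor)
  reg_table <- summary(fits)

  out_rows <- list()
  for (t in names(fits)) {
    z <- standardized_residuals(fits[[t]], options$outlier_threshold)
    fl <- z[z$outlier, , drop = FALSE]
    if (nrow(fl)) {
      out_rows[[t]] <- data.frame(specimen = fl$specimen, trait = t,
                                  z = fl$z, stringsAsFactors = FALSE)
    }
  }
  outliers <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(specimen = character(), trait = character(), z = numeric())
  rownames(outliers) <- NULL

  proj <- dx[dx$role == "projected", , drop = FALSE]
  proj_rows <- list()
  if (nrow(proj)) {
    for (t in names(fits)) {
      for (i in seq_len(nrow(proj))) {
        y0 <- proj[[t]][i]
        x0 <- proj[[options$predictor]][i]
        if (is.na(y0) || is.na(x0)) next
        zv <- suppressWarnings(
          project_specimen(fits[[t]], log10(x0), log10(y0)))
        proj_rows[[paste(t, i)]] <- data.frame(
          specimen = proj$specimen_id[i], trait = t, z = zv,
          stringsAsFactors = FALSE)
      }
    }
  }
  projections <- if (length(proj_rows)) do.call(rbind, proj_rows) else
    data.frame(specimen = character(), trait = character(), z = numeric())
  rownames(projections) <- NULL

  acoustics <- NULL
  pair <- options$comparison_pair
  if (is.null(pair)) {
    with_cbl <- dx[!is.na(dx$cbl), , drop = FALSE]
    pair <- c(with_cbl$specimen_id[which.max(with_cbl$cbl)],
              with_cbl$specimen_id[which.min(with_cbl$cbl)])
  }
  ia <- match(pair[1], dx$specimen_id)
  ib <- match(pair[2], dx$specimen_id)
  vals <- c(dx$v_cav[ia], dx$v_cav[ib], dx$a_tm[ia], dx$a_tm[ib])
  if (any(is.na(c(ia, ib))) || anyNA(vals)) {
    warning("acoustics section omitted: cavity volume or TM area missing ",
            "for the comparison pair", call. = FALSE)
  } else {
    lf <- low_freq_gain(vals[1], vals[2], vals[3], vals[4])
    acoustics <- list(comparison_pair = pair, low_freq = lf)
  }
  if (!is.null(options$f_high_calibration)) {
    cal <- options$f_high_calibration
    model <- calibrate_f_high(cal$mass_mg, cal$f_high_khz)
    ok <- !is.na(dx$mass_mal_mg) & !is.na(dx$mass_inc_mg)
    fh <- data.frame(specimen = dx$specimen_id[ok],
                     cbl = dx$cbl[ok],
                     total_ossicular_mass_mg =
                       dx$mass_mal_mg[ok] + dx$mass_inc_mg[ok],
                     f_high_khz = predict_f_high(model, dx$mass_mal_mg[ok],
                                                 dx$mass_inc_mg[ok]),
                     stringsAsFactors = FALSE)
    acoustics <- c(acoustics %||% list(),
                   list(f_high_model = model, f_high = fh))
  }

  provenance <- list(
    source = attr(x, "source") %||% "unknown",
    input_hash = .fnv1a(paste(utils::capture.output(
      utils::write.csv(as.data.frame(x), row.names = FALSE)),
      collapse = "\n")),
    n_specimens = nrow(x),
    n_fit = sum(x$role == "fit"),
    package_version = as.character(utils::packageVersion("earscaling")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(correlation_table = corr, fits = fits,
                 regression_table = reg_table, outliers = outliers,
                 projections = projections, acoustics = acoustics,
                 derived = dx, provenance = provenance),
            class = "ear_analysis_report")
}

#' @export
print.ear_analysis_report <- function(x, ...) {
  cat("== ear scaling analysis ==\n")
  cat(sprintf("source: %s (%d specimens, %d in fits)\n",
              x$provenance$source, x$provenance$n_specimens,
              x$provenance$n_fit))
  cat("\nregression table (log-log OLS, isometry test two-tailed):\n")
  print(x$regression_table, digits = 4)
  cat("\noutliers (|z| > threshold):\n")
  print(x$outliers, digits = 3)
  if (nrow(x$projections)) {
    cat("\nprojected specimens:\n")
    print(x$projections, digits = 3)
  }
  if (!is.null(x$acoustics$low_freq)) {
    cat(sprintf("\nlow-frequency gains (%s vs %s):\n",
                x$acoustics$comparison_pair[1],
                x$acoustics$comparison_pair[2]))
    print(x$acoustics$low_freq)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable JSON report at full precision and/or
#' delimiter-separated tables (regression table, correlation matrix,
#' outliers, projections), and optionally per-trait log-log scatter plots
#' with fitted lines as PNG files.
#'
#' @param report An `ear_analysis_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "csv", "png")`.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "csv")) {
  stopifnot(inherits(report, "ear_analysis_report"))
  unknown <- setdiff(formats, c("json", "csv", "png"))
  if (length(unknown)) {
    stop("unknown format(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    payload <- list(
      regression_table = report$regression_table,
      correlation_table = as.data.frame(as.table(report$correlation_table),
                                        stringsAsFactors = FALSE),
      outliers = report$outliers,
      projections = report$projections,
      acoustics = if (is.null(report$acoustics)) NULL else
        lapply(report$acoustics, function(el) {
          if (inherits(el, "low_freq_gain") || inherits(el, "f_high_model"))
            unclass(el) else el
        }),
      provenance = report$provenance
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    p1 <- file.path(dir, "regression_table.csv")
    utils::write.csv(report$regression_table, p1, row.names = FALSE)
    p2 <- file.path(dir, "correlation_table.csv")
    utils::write.csv(as.data.frame(report$correlation_table), p2)
    p3 <- file.path(dir, "outliers.csv")
    utils::write.csv(report$outliers, p3, row.names = FALSE)
    p4 <- file.path(dir, "projections.csv")
    utils::write.csv(report$projections, p4, row.names = FALSE)
    paths <- c(paths, p1, p2, p3, p4)
  }
  if ("png" %in% formats) {
    dx <- report$derived
    for (t in names(report$fits)) {
      f <- report$fits[[t]]
      p <- file.path(dir, sprintf("fit_%s.png", t))
      grDevices::png(p, width = 600, height = 600)
      fx <- fit_specimens(dx)
      keep <- !is.na(fx[[t]]) & !is.na(fx[[f$predictor]])
      plot(log10(fx[[f$predictor]][keep]), log10(fx[[t]][keep]),
           xlab = sprintf("log10(%s)", f$predictor),
           ylab = sprintf("log10(%s)", t),
           main = sprintf("%s: slope %.3f (isometric %g)", t, f$slope,
                          f$expected_slope), pch = 19)
      graphics::abline(f$intercept, f$slope, col = "steelblue")
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
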