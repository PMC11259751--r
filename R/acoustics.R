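#' Gain in decibels of a pressure- or velocity-like ratio
#'
#' `20 * log10(ratio)`, the convention under which a 14-fold compliance
#' (cavity-volume) ratio corresponds to an impedance reduction of nearly
#' 23 dB and a 6-fold velocity ratio to nearly 16 dB.
#'
#' @param ratio Positive dimensionless ratio.
#' @return Gain in dB.
#' @examples
#' db_gain(14)   # ~22.9 dB
#' @export
db_gain <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be > 0", call. = FALSE)
  20 * log10(ratio)
}

#' Low-frequency compliance-dominated gains between two middle ears
#'
#' At low frequencies middle-ear sound transmission is dominated by acoustic
#' compliance. If cavity compliance dominates, a specimen whose middle-ear
#' cavity volume is `V_a/V_b` times larger has acoustic impedance lower by
#' `20*log10(V_a/V_b)` dB. Treating the eardrum as a piston, its linear
#' velocity for a given sound pressure scales as the volume ratio divided by
#' the tympanic-membrane area ratio.
#'
#' @param v_a,v_b Middle-ear cavity volumes, mm^3 (specimen a is the
#'   numerator).
#' @param a_tm_a,a_tm_b Tympanic-membrane areas, mm^2.
#' @return An object of class `low_freq_gain`: `volume_ratio`,
#'   `impedance_gain_db`, `area_ratio_tm`, `velocity_gain_linear`,
#'   `velocity_gain_db`. The piston assumption is recorded in the
#'   `assumptions` field.
#' @examples
#' g <- low_freq_gain(4540, 320, 63.7, 27.7)
#' g$impedance_gain_db
#' @export
low_freq_gain <- function(v_a, v_b, a_tm_a, a_tm_b) {
  if (any(c(v_a, v_b, a_tm_a, a_tm_b) <= 0)) {
    stop("all volumes and areas must be > 0", call. = FALSE)
  }
  vr <- v_a / v_b
  ar <- a_tm_a / a_tm_b
  vg <- vr / ar
  structure(list(volume_ratio = vr,
                 impedance_gain_db = db_gain(vr),
                 area_ratio_tm = ar,
                 velocity_gain_linear = vg,
                 velocity_gain_db = db_gain(vg),
                 assumptions = "eardrum moves as a piston; cavity compliance dominates"),
            class = "low_freq_gain")
}

#' @export
print.low_freq_gain <- function(x, ...) {
  cat(sprintf("volume ratio %.3f -> impedance %.2f dB lower\n",
              x$volume_ratio, x$impedance_gain_db))
  cat(sprintf("TM area ratio %.3f -> eardrum velocity x%.3f (%.2f dB)\n",
              x$area_ratio_tm, x$velocity_gain_linear, x$velocity_gain_db))
  cat("assumptions:", x$assumptions, "\n")
  invisible(x)
}

#' Calibrate the cube-root high-frequency hearing model
#'
#' Across mammals the behavioural high-frequency hearing limit at 60 dB SPL
#' is approximately linear in the reciprocal of the cube root of combined
#' malleus + incus mass. This fits `f_high = beta0 + beta1 * m^(-1/3)` by
#' ordinary least squares to user-supplied calibration data (mass in mg,
#' limit in kHz).
#'
#' @param masses Combined malleus + incus masses, mg (> 0, at least 2
#'   distinct values).
#' @param f_highs High-frequency limits at 60 dB SPL, kHz (> 0).
#' @return An object of class `f_high_model`: `beta0` (kHz), `beta1`
#'   (kHz mg^(1/3)), `calibration_n`, `calibration_r2`.
#' @export
calibrate_f_high <- function(masses, f_highs) {
  if (any(masses <= 0)) stop("masses must be > 0", call. = FALSE)
  if (any(f_highs <= 0)) stop("f_highs must be > 0", call. = FALSE)
  o <- .ols(masses^(-1 / 3), f_highs, min_n = 2)
  structure(list(beta0 = o$intercept, beta1 = o$slope,
                 calibration_n = o$n, calibration_r2 = o$r2),
            class = "f_high_model")
}

#' Predict the high-frequency hearing limit from ossicular masses
#'
#' `f_high = beta0 + beta1 * (m_mal + m_inc)^(-1/3)`; with `beta1 > 0` the
#' prediction is strictly decreasing in total ossicular mass. A
#' non-positive prediction indicates extrapolation outside the calibrated
#' mass range and triggers a warning.
#'
#' @param model An `f_high_model`.
#' @param m_mal,m_inc Malleus and incus masses, mg (> 0).
#' @return Predicted limit in kHz.
#' @export
predict_f_high <- function(model, m_mal, m_inc) {
  stopifnot(inherits(model, "f_high_model"))
  if (any(m_mal <= 0) || any(m_inc <= 0)) {
    stop("ossicle masses must be > 0", call. = FALSE)
  }
  f <- model$beta0 + model$beta1 * (m_mal + m_inc)^(-1 / 3)
  if (any(f <= 0)) {
    warning("predicted f_high <= 0: outside the calibrated mass range",
            call. = FALSE)
  }
  f
}

#' Read an audiogram from a two-column delimited file
#'
#' @param path File with columns frequency (Hz) and threshold (dB SPL), one
#'   header row.
#' @param sep Field delimiter.
#' @return Data frame with columns `frequency_hz`, `threshold_db`.
#' @export
read_audiogram <- function(path, sep = ",") {
  d <- utils::read.csv(path, sep = sep)
  if (ncol(d) < 2) stop("audiogram file needs two columns", call. = FALSE)
  stats::setNames(d[, 1:2], c("frequency_hz", "threshold_db"))
}

#' Shift an audiogram by a gain and locate the low-frequency hearing limit
#'
#' Subtracts `gain_db` from all thresholds and returns the lowest frequency
#' at which the shifted curve reaches the criterion level, interpolating
#' linearly in (log10 frequency, dB) space along the low-frequency limb.
#' Used to ask where a breed's low-frequency limit would move if its larger
#' middle ear really delivered the predicted dB gain.
#'
#' @param audiogram Data frame with columns `frequency_hz` (strictly
#'   increasing) and `threshold_db`; at least 2 points spanning the
#'   criterion.
#' @param gain_db Gain in dB to subtract from all thresholds.
#' @param criterion Criterion level in dB SPL (default 60).
#' @return Crossing frequency in Hz.
#' @export
shift_lf_limit <- function(audiogram, gain_db, criterion = 60) {
  f <- audiogram$frequency_hz
  t <- audiogram$threshold_db
  if (length(f) < 2) stop("audiogram needs at least 2 points", call. = FALSE)
  if (any(diff(f) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  t <- t - gain_db
  below <- which(t <= criterion)
  if (!length(below)) {
    stop("shifted audiogram never crosses the criterion level",
         call. = FALSE)
  }
  i <- below[1]
  if (i == 1) return(f[1])
  # interpolate between the last point above and the first at/below criterion
  lf <- log10(f[i - 1]) + (t[i - 1] - criterion) / (t[i - 1] - t[i]) *
    (log10(f[i]) - log10(f[i - 1]))
  10^lf
}
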