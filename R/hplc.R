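#' Fit an HPLC calibration curve
#'
#' Ordinary least squares of peak area on standard concentration. Curves are
#' accepted only when R-squared exceeds 0.995 (the usual acceptance bound for
#' nucleotide standard series spanning 0.1-50 ug/mL) and the slope is
#' positive; otherwise the curve is returned flagged invalid.
#'
#' @param standards data.frame with columns `conc` (ug/mL) and `area`
#'   (detector signal), at least 3 distinct concentrations.
#' @param compound optional compound label attached to the curve.
#' @param r2_min acceptance bound on R-squared (exclusive).
#' @return A `calibration_curve`: list with slope, intercept, r_squared,
#'   range (ug/mL), compound, valid.
#' @export
fit_calibration <- function(standards, compound = NULL, r2_min = 0.995) {
  if (!all(c("conc", "area") %in% names(standards))) {
    stop("standards need columns 'conc' and 'area'")
  }
  if (length(unique(standards$conc)) < 3L) {
    stop("need at least 3 distinct standard concentrations")
  }
  fit <- stats::lm(area ~ conc, data = standards)
  r2 <- suppressWarnings(summary(fit))$r.squared
  slope <- unname(stats::coef(fit)["conc"])
  curve <- structure(list(
    compound = compound,
    slope = slope,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = r2,
    range = range(standards$conc),
    valid = isTRUE(r2 > r2_min) && slope > 0
  ), class = "calibration_curve")
  if (!curve$valid) {
    warning(sprintf("calibration curve%s flagged invalid (R^2 = %.4f, bound > %.3f)",
                    if (is.null(compound)) "" else paste0(" for ", compound),
                    r2, r2_min))
  }
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("HPLC calibration%s: area = %.6g * conc + %.6g (R^2 = %.5f, %s)\n",
              if (is.null(x$compound)) "" else paste0(" [", x$compound, "]"),
              x$slope, x$intercept, x$r_squared,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Inverse-predict concentration from peak area
#'
#' @param curve a `calibration_curve`.
#' @param area detector signal(s).
#' @return concentration(s) in ug/mL, floored at 0 (trace-level signals below
#'   the intercept warn rather than going negative). Predictions beyond 1.2x
#'   the calibrated range warn about extrapolation.
#' @export
concentration_from_area <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("degenerate calibration: zero slope")
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative inverse prediction(s) floored to 0")
    conc <- pmax(conc, 0)
  }
  if (any(conc > 1.2 * curve$range[2])) {
    warning("prediction(s) beyond 1.2x the calibrated range; extrapolating")
  }
  conc
}

#' Nucleotide content from an extraction record
#'
#' content (ug/g) = C x V / W, where C is the HPLC-determined extract
#' concentration (ug/mL), V the extract volume (mL) and W the sample mass (g).
#' Also returned on the canonical reporting scale, mg per 100 g (= ug/g x 0.1).
#'
#' @param conc_ug_ml C, ug/mL (>= 0).
#' @param volume_ml V, mL (> 0). Pooled extractions enter as one volume.
#' @param mass_g W, g (> 0).
#' @return data.frame with columns `ug_per_g` and `mg_per_100g`.
#' @export
nucleotide_content <- function(conc_ug_ml, volume_ml, mass_g) {
  if (any(mass_g <= 0)) stop("sample mass W must be positive")
  if (any(volume_ml <= 0)) stop("extract volume V must be positive")
  if (any(conc_ug_ml < 0)) stop("concentration C must be non-negative")
  ug_per_g <- conc_ug_ml * volume_ml / mass_g
  data.frame(ug_per_g = ug_per_g, mg_per_100g = ug_per_g * 0.1)
}
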