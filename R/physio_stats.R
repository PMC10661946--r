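#' Left-ventricular wall strain
#'
#' Relative systolic thickening of the left ventricular posterior wall,
#' a contractility index:
#' `strain = 100 * (thickness_systole - thickness_diastole) / thickness_systole`.
#' Diastolic thickness exceeding systolic gives a negative strain, returned
#' unclamped.
#'
#' @param thickness_systole_mm,thickness_diastole_mm wall thickness in mm.
#' @return strain percentage.
#' @export
lv_strain <- function(thickness_systole_mm, thickness_diastole_mm) {
  if (any(thickness_systole_mm <= 0))
    stop("systolic thickness must be positive")
  100 * (thickness_systole_mm - thickness_diastole_mm) / thickness_systole_mm
}

#' Heart-rate-corrected QRS duration
#'
#' `QRSc = QRS + 0.0125 * (1 - RR)`, all durations in seconds. At `RR = 1 s`
#' the correction vanishes.
#'
#' @param qrs_s QRS complex duration (s).
#' @param rr_s R-R interval (s), positive.
#' @return corrected duration in seconds.
#' @export
qrs_corrected <- function(qrs_s, rr_s) {
  if (any(rr_s <= 0)) stop("RR interval must be positive")
  qrs_s + 0.0125 * (1 - rr_s)
}

#' Heart-rate-corrected QT interval
#'
#' `QTc = QT + 0.0154 * (1 - RR)`, all durations in seconds.
#'
#' @param qt_s QT interval duration (s).
#' @param rr_s R-R interval (s), positive.
#' @return corrected duration in seconds.
#' @export
qt_corrected <- function(qt_s, rr_s) {
  if (any(rr_s <= 0)) stop("RR interval must be positive")
  qt_s + 0.0154 * (1 - rr_s)
}

#' Differential between two postnatal stages
#'
#' `Delta = P7 - P1` for magnitude parameters, or the percentage
#' differential `100 * (P7 - P1) / P1` for functional parameters.
#'
#' @param value_p1,value_p7 parameter values at the two stages.
#' @param mode `"absolute"` or `"percent"`.
#' @return the differential.
#' @export
stage_differential <- function(value_p1, value_p7,
                               mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (mode == "absolute") return(value_p7 - value_p1)
  if (any(value_p1 == 0))
    stop("percentage differential undefined for a zero baseline")
  100 * (value_p7 - value_p1) / value_p1
}

#' Pearson correlation report for a parameter pair
#'
#' Textbook Pearson correlation with a two-sided p-value from the t
#' transform on `n - 2` degrees of freedom, as used to relate pruning-event
#' counts to segment and bifurcation counts across volumes of interest.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param labels optional `c(name_x, name_y)` pair.
#' @return a `correlation_report` list: `pair`, `r`, `p_two_sided`, `n`.
#' @export
pearson_report <- function(x, y, labels = c("x", "y")) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(pair = labels, r = unname(ct$estimate),
                 p_two_sided = ct$p.value, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %s vs %s: r = %.3f, p = %.4g (n = %d)\n",
              x$pair[1], x$pair[2], x$r, x$p_two_sided, x$n))
  invisible(x)
}
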