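#' Platinum / iridium signal ratio
#'
#' Ratio of platinum counts to the iridium internal-standard counts for one
#' ICP-MS run row. The monitored Pt masses (194, 195, 196) are aggregated by
#' summation by default; a single-mass policy is available.
#'
#' @param row list or one-row data frame with fields `pt194`, `pt195`,
#'   `pt196`, `ir193` (counts).
#' @param policy `"sum"` (default) or one of `"194"`, `"195"`, `"196"`.
#' @return numeric ratio.
#' @export
signal_ratio <- function(row, policy = c("sum", "194", "195", "196")) {
  policy <- match.arg(policy)
  ir <- as.numeric(row[["ir193"]])
  if (any(!is.finite(ir)) || any(ir <= 0)) {
    abort("internal standard missing: ir193 counts must be > 0.")
  }
  pt <- switch(policy,
               sum = as.numeric(row[["pt194"]]) + as.numeric(row[["pt195"]]) +
                 as.numeric(row[["pt196"]]),
               as.numeric(row[[paste0("pt", policy)]]))
  if (any(pt < 0)) abort("Pt counts must be non-negative.")
  pt / ir
}

#' Add Pt/Ir signal ratios to a run table
#'
#' @param run ICP-MS run tibble with count columns `pt194`, `pt195`,
#'   `pt196`, `ir193`.
#' @inheritParams signal_ratio
#' @return `run` with a `ratio` column appended.
#' @export
add_signal_ratios <- function(run, policy = "sum") {
  run <- tibble::as_tibble(run)
  run$ratio <- signal_ratio(run, policy)
  run
}

#' 1/x^2-weighted linear calibration fit
#'
#' Weighted least squares of the Pt/Ir signal ratio on the nominal standard
#' concentration, with weights `1/x^2` (x = nominal ppb). The inverse-square
#' weighting equalizes *relative* error across a serial-dilution series
#' spanning decades, so the low standards are not swamped by the top ones.
#'
#' @param standards tibble with columns `nominal_ppb` (> 0) and `ratio`, one
#'   row per standard; at least two distinct levels.
#' @param force_zero_intercept fit through the origin if `TRUE`
#'   (default `FALSE`: the intercept is estimated).
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `weights`, `levels`, `residuals` (raw), `r_squared` (weighted), and the
#'   underlying `lm` fit.
#' @export
fit_calibration <- function(standards, force_zero_intercept = FALSE) {
  standards <- tibble::as_tibble(standards)
  stopifnot(all(c("nominal_ppb", "ratio") %in% names(standards)))
  x <- standards$nominal_ppb
  y <- standards$ratio
  if (any(x <= 0)) abort("standard concentrations must be > 0.")
  if (length(unique(x)) < 2) abort("rank deficient: need >= 2 distinct levels.")
  w <- 1 / x^2
  fit <- if (force_zero_intercept) lm(y ~ 0 + x, weights = w) else
    lm(y ~ x, weights = w)
  cf <- coef(fit)
  slope <- unname(cf[["x"]])
  intercept <- if (force_zero_intercept) 0 else unname(cf[["(Intercept)"]])
  wm <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * residuals(fit)^2) / sum(w * (y - wm)^2)
  structure(list(slope = slope, intercept = intercept, weights = w,
                 levels = sort(unique(x)), residuals = unname(residuals(fit)),
                 r_squared = r2, fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "1/x^2-weighted calibration: ratio = %.6g * ppb + %.6g (R2w = %.5f)\n",
    x$slope, x$intercept, x$r_squared))
  cat("levels (ppb):", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted ratio at a concentration
#'
#' @param fit a [fit_calibration()] result.
#' @param ppb concentration(s) in ppb.
#' @return predicted Pt/Ir ratio(s).
#' @export
predict_ratio <- function(fit, ppb) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$slope * ppb + fit$intercept
}

#' Back-calculate concentration from a signal ratio
#'
#' Inverts the calibration line: `ppb = (ratio - intercept) / slope`.
#' Estimates below the lowest standard are flagged; negative estimates are
#' reported as 0 ppb with a `clipped` flag (blanks legitimately scatter
#' around zero).
#'
#' @param fit a [fit_calibration()] result with non-zero slope.
#' @param ratio signal ratio(s).
#' @return tibble with `ratio`, `ppb`, `below_lowest_standard`, `clipped`.
#' @export
back_calculate <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) abort("zero slope: calibration cannot be inverted.")
  ppb <- (ratio - fit$intercept) / fit$slope
  clipped <- ppb < 0
  ppb[clipped] <- 0
  tibble::tibble(ratio = ratio, ppb = ppb,
                 below_lowest_standard = ppb < min(fit$levels),
                 clipped = clipped)
}

#' DNA-bound platinum fraction
#'
#' Percent of total intra-cellular platinum that is DNA-bound, with optional
#' per-sample normalization scales (e.g. cell number behind each extract).
#'
#' @param total,dna_bound back-calculated concentrations in ppb (vectors of
#'   equal length).
#' @param total_scale,dna_scale optional per-sample divisors applied to the
#'   respective concentrations before forming the fraction.
#' @return percent vector, `100 * (dna_bound/dna_scale) / (total/total_scale)`.
#' @export
dna_bound_fraction <- function(total, dna_bound, total_scale = 1,
                               dna_scale = 1) {
  if (length(total) != length(dna_bound)) {
    abort("`total` and `dna_bound` must have equal length.")
  }
  t_norm <- total / total_scale
  if (any(t_norm <= 0)) abort("total platinum must be > 0.")
  100 * (dna_bound / dna_scale) / t_norm
}
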