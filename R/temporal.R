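# Temporal (Suess-effect) correction: place modern diet-item measurements
# on the isotopic scale of a historical period before mixing-model fitting.

#' Temporal-correction configuration
#'
#' Two modes are supported. In `per_period_offsets` mode the carbon (and
#' optionally nitrogen) correction for each period is supplied directly in
#' per mil; the defaults carry the expected industrial-era Suess shifts for
#' the study's three periods (Period 1 +1.6 permil, Period 2 +0.3 permil,
#' Period 3 the modern reference at 0). In `reference_curve` mode a table of
#' atmospheric d13C anomalies by calendar year is interpolated linearly and
#' normalised so the correction at `reference_year` is zero. Sulfur is never
#' corrected: there is no evidence of temporal d34S drift.
#'
#' @param mode `"per_period_offsets"` or `"reference_curve"`.
#' @param d13C_offsets Named numeric vector, period -> permil offset.
#' @param d15N_offsets Named numeric vector, period -> permil offset
#'   (default all zero); each |offset| must not exceed `d15N_cap`.
#' @param curve Data.frame with columns `year` and `anomaly_permil`
#'   (required in curve mode; must cover the years queried).
#' @param reference_year Year at which the correction is zero (curve mode);
#'   defaults to the latest curve year.
#' @param d15N_cap Upper bound on |d15N offset| in permil (default 0.4, the
#'   maximum temporal diet shift the correction is meant to absorb).
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(mode = c("per_period_offsets", "reference_curve"),
                              d13C_offsets = c(period1 = 1.6, period2 = 0.3,
                                               period3 = 0),
                              d15N_offsets = NULL,
                              curve = NULL, reference_year = NULL,
                              d15N_cap = 0.4) {
  mode <- match.arg(mode)
  if (is.null(d15N_offsets))
    d15N_offsets <- setNames(rep(0, length(d13C_offsets)),
                             names(d13C_offsets))
  if (any(!is.finite(d13C_offsets)) || any(!is.finite(d15N_offsets)))
    stop("offsets must be finite")
  if (any(abs(d15N_offsets) > d15N_cap + 1e-12))
    stop("|d15N offset| exceeds the configured cap of ", d15N_cap,
         " permil")
  if (mode == "reference_curve") {
    if (is.null(curve) || !all(c("year", "anomaly_permil") %in% names(curve)))
      stop("curve mode needs a data.frame with year and anomaly_permil")
    curve <- curve[order(curve$year), , drop = FALSE]
    if (anyDuplicated(curve$year)) stop("curve years must be distinct")
    if (is.null(reference_year)) reference_year <- max(curve$year)
    if (reference_year < min(curve$year) || reference_year > max(curve$year))
      stop("reference_year outside curve coverage")
  }
  structure(list(mode = mode, d13C_offsets = d13C_offsets,
                 d15N_offsets = d15N_offsets, curve = curve,
                 reference_year = reference_year, d15N_cap = d15N_cap),
            class = "correction_config")
}

#' Suess-effect d13C offset for a calendar year or period
#'
#' Returns the per-mil amount by which modern d13C measurements must be
#' raised to sit on the isotopic scale of the queried year (offset mode:
#' the queried period). Under curve mode the correction is
#' `anomaly(reference_year) - anomaly(year)` with linear interpolation
#' between curve nodes, so it is zero at the reference year and
#' non-negative for earlier years on any monotone industrial-era curve.
#' Years outside the curve's coverage are an error; there is no
#' extrapolation.
#'
#' @param year Calendar year (curve mode, vectorised) or a period label
#'   present in the configured offsets (offset mode).
#' @param config A [correction_config()] object.
#' @return Offset in per mil.
#' @export
suess_offset <- function(year, config = correction_config()) {
  if (config$mode == "per_period_offsets") {
    off <- config$d13C_offsets[as.character(year)]
    if (anyNA(off)) stop("no configured d13C offset for period: ",
                         paste(year[is.na(off)], collapse = ", "))
    return(unname(off))
  }
  yr <- as.numeric(year)
  cv <- config$curve
  if (any(yr < min(cv$year)) || any(yr > max(cv$year)))
    stop("year outside reference-curve coverage; no extrapolation")
  anom <- stats::approx(cv$year, cv$anomaly_permil, xout = yr)$y
  ref <- stats::approx(cv$year, cv$anomaly_permil,
                       xout = config$reference_year)$y
  anom - ref
}

#' Correct pooled source groups onto a period's isotopic scale
#'
#' Adds the period's d13C offset (and any configured d15N offset) to every
#' group mean. Spreads (`omega`) and elemental concentrations (`q`) are
#' untouched — the correction is a pure mean shift — and d34S is never
#' corrected. Period 3 is the modern reference, so its correction is the
#' identity under the default configuration.
#'
#' @param groups A [source_groups()] object built from modern measurements.
#' @param period Period label (e.g. `"period1"`), or a calendar year in
#'   curve mode.
#' @param config A [correction_config()] object.
#' @return The corrected `source_groups` object, with attribute
#'   `correction` recording the applied offsets.
#' @export
correct_sources_for_period <- function(groups, period,
                                       config = correction_config()) {
  d13C_off <- suess_offset(period, config)
  d15N_off <- if (config$mode == "per_period_offsets") {
    off <- config$d15N_offsets[as.character(period)]
    if (is.na(off)) 0 else unname(off)
  } else 0
  out <- groups
  if ("d13C" %in% out$channels)
    out$mu[, "d13C"] <- out$mu[, "d13C"] + d13C_off
  if ("d15N" %in% out$channels)
    out$mu[, "d15N"] <- out$mu[, "d15N"] + d15N_off
  attr(out, "correction") <- list(period = period, d13C = d13C_off,
                                  d15N = d15N_off, d34S = 0,
                                  convention = "sources shifted onto the consumer period's scale")
  out
}
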