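#' Construct an SMA assay bottle record
#'
#' One serum bottle of a specific methanogenic activity assay: granule
#' biomass in buffer at a known volatile-solids mass, headspace pressure
#' logged in millivolts and converted to biogas volume through an
#' instrument-specific calibration slope and headspace correction factor,
#' with CH4 fraction of the biogas from gas chromatography.
#'
#' @param bottle_id identifier.
#' @param fraction_label sieve fraction the granules came from.
#' @param substrate one of `acetate`, `propionate`, `butyrate`, `H2CO2`,
#'   `control_none`, `control_N2CO2`.
#' @param vs_mass_g grams of volatile solids in the bottle (from in-bottle
#'   drying and ignition).
#' @param time_d time points, days, strictly increasing.
#' @param pressure_mV transducer signal per time point.  For soluble
#'   substrates this accumulates with biogas production; for `H2CO2` bottles
#'   it falls as headspace H2 is consumed.
#' @param ch4_fraction CH4 proportion of the biogas per time point, in
#'   `[0, 1]`.
#' @param calibration_mL_per_mV transducer calibration slope (> 0).
#' @param headspace_correction dimensionless multiplicative headspace
#'   correction factor.
#' @param headspace_volume_mL headspace volume (used only for reporting).
#' @param temperature_C incubation temperature; when non-`NULL`, measured gas
#'   volumes are converted to STP (0 degC, 1 atm) by the ideal gas law.
#'   `NULL` means volumes are already expressed at STP.
#' @return an object of class `sma_assay`.
#' @export
sma_assay <- function(bottle_id, fraction_label, substrate, vs_mass_g,
                      time_d, pressure_mV, ch4_fraction,
                      calibration_mL_per_mV = 1, headspace_correction = 1,
                      headspace_volume_mL = 50, temperature_C = NULL) {
  substrate <- match.arg(substrate,
    c("acetate", "propionate", "butyrate", "H2CO2", "control_none", "control_N2CO2"))
  if (vs_mass_g <= 0) stop("sma_assay: vs_mass_g must be > 0")
  if (is.unsorted(time_d, strictly = TRUE))
    stop("sma_assay: time points must be strictly increasing")
  if (length(pressure_mV) != length(time_d) ||
      length(ch4_fraction) != length(time_d))
    stop("sma_assay: series lengths differ")
  if (any(ch4_fraction < 0 | ch4_fraction > 1))
    stop("sma_assay: ch4_fraction must lie in [0, 1]")
  structure(list(bottle_id = bottle_id, fraction_label = fraction_label,
                 substrate = substrate, vs_mass_g = vs_mass_g,
                 time_d = time_d, pressure_mV = pressure_mV,
                 ch4_fraction = ch4_fraction,
                 calibration_mL_per_mV = calibration_mL_per_mV,
                 headspace_correction = headspace_correction,
                 headspace_volume_mL = headspace_volume_mL,
                 temperature_C = temperature_C),
            class = "sma_assay")
}

#' Convert a pressure signal to biogas volume
#'
#' @param signal_mV transducer signal (>= 0).
#' @param calibration_mL_per_mV calibration slope, mL per mV (> 0).
#' @param headspace_correction multiplicative headspace correction factor.
#' @return biogas volume, mL.
#' @export
pressure_to_volume <- function(signal_mV, calibration_mL_per_mV,
                               headspace_correction = 1) {
  if (any(calibration_mL_per_mV <= 0))
    stop("pressure_to_volume: calibration slope must be > 0")
  if (any(signal_mV < 0))
    stop("pressure_to_volume: negative pressure signal")
  signal_mV * calibration_mL_per_mV * headspace_correction
}

stp_factor <- function(temperature_C) {
  if (is.null(temperature_C)) 1 else 273.15 / (273.15 + temperature_C)
}

ch4_series <- function(assay) {
  vol <- pressure_to_volume(assay$pressure_mV, assay$calibration_mL_per_mV,
                            assay$headspace_correction)
  vol * assay$ch4_fraction * stp_factor(assay$temperature_C)
}

#' Cumulative background-corrected CH4 production
#'
#' CH4 volume (STP) per time point is biogas volume times CH4 fraction; the
#' no-substrate control's CH4 series is linearly interpolated onto the assay
#' grid and subtracted.  The net series is clamped to be non-decreasing from
#' zero (methane already produced cannot vanish).
#'
#' @param assay an [sma_assay()].
#' @param control the paired no-substrate control bottle, or `NULL` for no
#'   background correction.
#' @return data.frame with `time_d` and cumulative net `ch4_mL`.
#' @export
methane_accumulation <- function(assay, control = NULL) {
  ch4 <- ch4_series(assay)
  if (!is.null(control)) {
    if (min(control$time_d) > min(assay$time_d) + 1e-9 ||
        max(control$time_d) < max(assay$time_d) - 1e-9)
      stop("methane_accumulation: control series does not span the assay; refusing to extrapolate")
    bg <- stats::approx(control$time_d, ch4_series(control),
                        xout = assay$time_d)$y
    ch4 <- ch4 - bg
  }
  net <- cummax(pmax(ch4 - ch4[1], 0))
  data.frame(time_d = assay$time_d, ch4_mL = net)
}

max_slope_fit <- function(time_d, y, window = 4L) {
  n <- length(time_d)
  if (n < window)
    stop("sma_rate: need at least ", window, " time points")
  best <- list(slope = -Inf, r2 = 0, t_start = time_d[1], t_end = time_d[n])
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    tt <- time_d[idx]; yy <- y[idx]
    sxx <- sum((tt - mean(tt))^2)
    slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    syy <- sum((yy - mean(yy))^2)
    r2 <- if (syy > 0) (slope^2 * sxx) / syy else 0
    if (slope > best$slope)
      best <- list(slope = slope, r2 = r2, t_start = tt[1], t_end = tt[window])
  }
  best
}

#' Specific methanogenic activity for a soluble substrate
#'
#' The rate is the maximum slope of cumulative background-corrected CH4 over
#' a sliding window of `window` consecutive points (ordinary least squares),
#' normalised by the bottle's volatile-solids mass.  A net-negative slope is
#' clamped to zero with a warning.
#'
#' @param assay an [sma_assay()] with a soluble substrate.
#' @param control paired no-substrate control, or `NULL`.
#' @param window sliding-window width in points (default 4).
#' @return list of class `sma_result`: `rate_mL_gVS_d`, `r_squared`,
#'   `fit_window`, `background_corrected`, `clamped`.
#' @export
sma_rate <- function(assay, control = NULL, window = 4L) {
  stopifnot(inherits(assay, "sma_assay"))
  if (assay$substrate == "H2CO2")
    stop("sma_rate: use sma_rate_h2() for H2/CO2 bottles")
  acc <- methane_accumulation(assay, control)
  fit <- max_slope_fit(acc$time_d, acc$ch4_mL, window)
  rate <- fit$slope / assay$vs_mass_g
  clamped <- FALSE
  if (rate < 0) {
    warning("sma_rate: negative net rate clamped to 0 (bottle ", assay$bottle_id, ")")
    rate <- 0; clamped <- TRUE
  }
  structure(list(rate_mL_gVS_d = rate, r_squared = fit$r2,
                 fit_window = c(fit$t_start, fit$t_end),
                 background_corrected = !is.null(control), clamped = clamped,
                 bottle_id = assay$bottle_id, substrate = assay$substrate,
                 fraction_label = assay$fraction_label),
            class = "sma_result")
}

#' Specific methanogenic activity for H2/CO2 bottles
#'
#' Hydrogenotrophic methanogenesis consumes headspace H2; the pressure signal
#' falls.  The H2 consumption rate (mL STP per day, maximum sliding-window
#' slope of the consumed volume) is converted to a methane-equivalent rate by
#' the 4 H2 : 1 CH4 reaction stoichiometry (equal volumes at STP), then
#' normalised by volatile solids.
#'
#' @param assay an [sma_assay()] with substrate `H2CO2`.
#' @param control paired `control_N2CO2` bottle, or `NULL`.
#' @inheritParams sma_rate
#' @return an `sma_result` list.
#' @export
sma_rate_h2 <- function(assay, control = NULL, window = 4L) {
  stopifnot(inherits(assay, "sma_assay"))
  if (assay$substrate != "H2CO2")
    stop("sma_rate_h2: substrate must be H2CO2, got ", assay$substrate)
  consumed_vol <- function(a) {
    v <- pressure_to_volume(a$pressure_mV, a$calibration_mL_per_mV,
                            a$headspace_correction) * stp_factor(a$temperature_C)
    v[1] - v  # headspace volume lost = H2 consumed
  }
  h2 <- consumed_vol(assay)
  if (!is.null(control)) {
    if (min(control$time_d) > min(assay$time_d) + 1e-9 ||
        max(control$time_d) < max(assay$time_d) - 1e-9)
      stop("sma_rate_h2: control series does not span the assay")
    h2 <- h2 - stats::approx(control$time_d, consumed_vol(control),
                             xout = assay$time_d)$y
  }
  ch4_equiv <- cummax(pmax(h2, 0)) / 4  # 4:1 molar = 4:1 volumetric at STP
  fit <- max_slope_fit(assay$time_d, ch4_equiv, window)
  rate <- max(fit$slope, 0) / assay$vs_mass_g
  structure(list(rate_mL_gVS_d = rate, r_squared = fit$r2,
                 fit_window = c(fit$t_start, fit$t_end),
                 background_corrected = !is.null(control),
                 clamped = fit$slope < 0,
                 bottle_id = assay$bottle_id, substrate = assay$substrate,
                 fraction_label = assay$fraction_label),
            class = "sma_result")
}

#' Rate matrix over a set of assay bottles
#'
#' Pairs each substrate bottle with its fraction's control (`control_none`
#' for soluble substrates, `control_N2CO2` for H2/CO2) and tabulates mean
#' rates as a fraction x substrate matrix.
#'
#' @param assays list of [sma_assay()] objects.
#' @param window sliding-window width.
#' @return list with `rates` (fraction x substrate matrix) and `results`
#'   (per-bottle `sma_result`s).
#' @export
sma_rate_matrix <- function(assays, window = 4L) {
  is_ctrl <- vapply(assays, function(a)
    a$substrate %in% c("control_none", "control_N2CO2"), logical(1))
  controls <- assays[is_ctrl]
  find_ctrl <- function(fraction, type) {
    for (ct in controls)
      if (ct$fraction_label == fraction && ct$substrate == type) return(ct)
    NULL
  }
  results <- list()
  for (a in assays[!is_ctrl]) {
    res <- if (a$substrate == "H2CO2")
      sma_rate_h2(a, find_ctrl(a$fraction_label, "control_N2CO2"), window)
    else
      sma_rate(a, find_ctrl(a$fraction_label, "control_none"), window)
    results[[a$bottle_id]] <- res
  }
  fr <- sort(unique(vapply(results, `[[`, "", "fraction_label")))
  sub <- sort(unique(vapply(results, `[[`, "", "substrate")))
  rates <- matrix(NA_real_, length(fr), length(sub), dimnames = list(fr, sub))
  for (f in fr) for (s in sub) {
    r <- vapply(results, function(x)
      if (x$fraction_label == f && x$substrate == s) x$rate_mL_gVS_d else NA_real_,
      numeric(1))
    if (any(!is.na(r))) rates[f, s] <- mean(r, na.rm = TRUE)
  }
  list(rates = rates, results = results)
}
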