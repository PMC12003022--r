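#' Default sieve fraction scheme
#'
#' Ten diameter classes A-J used to sieve the granular sludge, half-open
#' `[lower, upper)` in mm.  Fraction A is everything below 0.20 mm; no
#' granules above 4.00 mm are expected.
#'
#' @return data.frame with columns `label`, `lower_mm`, `upper_mm`.
#' @export
default_fraction_scheme <- function() {
  data.frame(
    label = LETTERS[1:10],
    lower_mm = c(0, 0.20, 0.40, 0.60, 0.80, 1.00, 1.40, 1.80, 2.00, 3.15),
    upper_mm = c(0.20, 0.40, 0.60, 0.80, 1.00, 1.40, 1.80, 2.00, 3.15, 4.00),
    stringsAsFactors = FALSE)
}

validate_scheme <- function(scheme) {
  stopifnot(all(c("label", "lower_mm", "upper_mm") %in% names(scheme)))
  if (any(scheme$lower_mm >= scheme$upper_mm))
    stop("fraction scheme: lower bound must be < upper bound")
  if (is.unsorted(scheme$lower_mm, strictly = TRUE) ||
      any(scheme$upper_mm[-nrow(scheme)] > scheme$lower_mm[-1] + 1e-12))
    stop("fraction scheme: intervals must be ascending and non-overlapping")
  invisible(scheme)
}

#' Assign a diameter to a sieve fraction
#'
#' Half-open convention `[lower, upper)`: a granule exactly on a shared bound
#' belongs to the larger fraction.
#'
#' @param d diameter(s), mm.
#' @param scheme fraction scheme (default [default_fraction_scheme()]).
#' @return character vector of labels; `NA` for diameters at or above the top
#'   bound (out of scheme).
#' @export
assign_fraction <- function(d, scheme = default_fraction_scheme()) {
  validate_scheme(scheme)
  idx <- findInterval(d, c(scheme$lower_mm, scheme$upper_mm[nrow(scheme)]))
  out <- rep(NA_character_, length(d))
  ok <- idx >= 1L & idx <= nrow(scheme)
  out[ok] <- scheme$label[idx[ok]]
  out
}

#' Mid-point diameter of each fraction
#' @param scheme fraction scheme.
#' @return named numeric vector, mm.
#' @export
fraction_midpoints <- function(scheme = default_fraction_scheme()) {
  stats::setNames((scheme$lower_mm + scheme$upper_mm) / 2, scheme$label)
}

#' Settling velocity from a timed drop
#'
#' @param L settling distance, m (the drop column's marked 0.3 m by default).
#' @param t settling time, s.
#' @return velocity, m s^-1.
#' @export
settling_velocity <- function(L = 0.3, t) {
  if (any(L <= 0)) stop("settling_velocity: L must be > 0")
  if (any(t <= 0)) stop("settling_velocity: t must be > 0")
  L / t
}

#' Water density and dynamic viscosity at a temperature
#'
#' Density from the Kell (1975) polynomial for air-free water; viscosity from
#' the Vogel equation with coefficients fitted to tabulated values (1.002e-3
#' Pa s at 20 degC).  Valid 0-40 degC, the range met in a settling column.
#'
#' @param temperature_C water temperature, degC.
#' @return list with `density_kg_m3`, `viscosity_Pa_s`.
#' @export
water_properties <- function(temperature_C = 20) {
  t <- temperature_C
  if (any(t <= 0) || any(t >= 40))
    stop("water_properties: temperature must be in (0, 40) degC")
  rho <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
            46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
            280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
  mu <- 2.414e-5 * 10^(247.8 / (t + 273.15 - 140))
  list(density_kg_m3 = rho, viscosity_Pa_s = mu)
}

#' Particle density from Stokes' law
#'
#' Inverts the terminal-velocity relation for a small sphere in laminar flow:
#' `rho_p = rho_f + 18 mu v / (g d^2)`.  A particle Reynolds number above 1
#' means the laminar assumption is stretched; the estimate is still returned,
#' with a warning recorded in the `reynolds`/`laminar` fields.
#'
#' @param d diameter, mm.
#' @param v settling velocity, m s^-1.
#' @param rho_f fluid density, kg m^-3.
#' @param mu dynamic viscosity, Pa s.
#' @param g gravitational acceleration, m s^-2.
#' @param warn warn when Re > 1 (default TRUE).
#' @return data.frame with `density_kg_m3`, `reynolds`, `laminar`.
#' @export
stokes_density <- function(d, v, rho_f = 998.2, mu = 1.002e-3, g = 9.81,
                           warn = TRUE) {
  if (any(d <= 0)) stop("stokes_density: diameter must be > 0")
  if (any(v < 0)) stop("stokes_density: velocity must be >= 0")
  d_m <- d / 1000
  rho_p <- rho_f + 18 * mu * v / (g * d_m^2)
  re <- rho_f * v * d_m / mu
  if (warn && any(re > 1))
    warning(sprintf("stokes_density: %d estimate(s) outside the laminar regime (Re > 1)",
                    sum(re > 1)))
  data.frame(density_kg_m3 = rho_p, reynolds = re, laminar = re <= 1)
}

#' Stokes terminal velocity (algebraic inverse of [stokes_density()])
#'
#' @param rho_p particle density, kg m^-3.
#' @inheritParams stokes_density
#' @return velocity, m s^-1.
#' @export
stokes_velocity <- function(rho_p, d, rho_f = 998.2, mu = 1.002e-3, g = 9.81) {
  if (any(d <= 0)) stop("stokes_velocity: diameter must be > 0")
  d_m <- d / 1000
  g * d_m^2 * (rho_p - rho_f) / (18 * mu)
}

#' Solids fractions from loss-on-ignition masses
#'
#' @param wet wet mass, g.
#' @param dry mass after drying, g.
#' @param ash mass after ignition, g.
#' @return data.frame with `ts` (dry/wet), `vs` ((dry-ash)/wet) and
#'   `vs_of_ts` ((dry-ash)/dry), all as fractions.
#' @export
solids_fractions <- function(wet, dry, ash) {
  if (any(ash < 0) || any(dry < ash) || any(wet < dry))
    stop("solids_fractions: need wet >= dry >= ash >= 0")
  if (any(wet <= 0)) stop("solids_fractions: wet mass must be > 0")
  data.frame(ts = dry / wet, vs = (dry - ash) / wet,
             vs_of_ts = ifelse(dry > 0, (dry - ash) / dry, NA_real_))
}

#' EPS component proportions
#'
#' Converts measured concentrations (mg per g VS) of the three assayed
#' extracellular-polymer components into compositional proportions.
#'
#' @param protein,hls,polysaccharide concentrations, any common unit.
#' @return data.frame with columns `protein`, `hls`, `polysaccharide`
#'   summing to 1 row-wise.
#' @export
eps_proportions <- function(protein, hls, polysaccharide) {
  m <- cbind(protein = protein, hls = hls, polysaccharide = polysaccharide)
  if (any(m < 0)) stop("eps_proportions: concentrations must be >= 0")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("eps_proportions: all-zero composition is undefined")
  as.data.frame(m / tot)
}

#' Process a table of granule drop-column measurements
#'
#' @param granules data.frame with columns `granule_id`, `diameter_mm`,
#'   `time_s`, optionally `temp_C` (default 20) and `distance_m`
#'   (default 0.3).
#' @param scheme fraction scheme for label assignment.
#' @return the input augmented with `fraction`, `velocity_m_s`,
#'   `density_kg_m3`, `reynolds`, `laminar`.
#' @export
granule_densities <- function(granules, scheme = default_fraction_scheme()) {
  req <- c("granule_id", "diameter_mm", "time_s")
  miss <- setdiff(req, names(granules))
  if (length(miss)) stop("granule_densities: missing column(s): ",
                         paste(miss, collapse = ", "))
  temp <- if ("temp_C" %in% names(granules)) granules$temp_C else 20
  L <- if ("distance_m" %in% names(granules)) granules$distance_m else 0.3
  wp <- water_properties(temp)
  v <- settling_velocity(L, granules$time_s)
  dens <- stokes_density(granules$diameter_mm, v,
                         rho_f = wp$density_kg_m3, mu = wp$viscosity_Pa_s,
                         warn = FALSE)
  cbind(granules,
        fraction = assign_fraction(granules$diameter_mm, scheme),
        velocity_m_s = v, dens)
}
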