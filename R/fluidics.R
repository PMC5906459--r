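#' Inlet tube geometry
#'
#' The default is the short, narrow-bore delivery tube used to minimise the
#' switching delay: 22 cm of 250 um inner-diameter tubing, holding about
#' 11 uL.
#'
#' @param length_cm Tube length in centimetres.
#' @param inner_diameter_um Inner diameter in micrometres.
#' @return Object of class `tube_spec`.
#' @export
tube_spec <- function(length_cm = 22, inner_diameter_um = 250) {
  stopifnot(length_cm >= 0, inner_diameter_um > 0)
  structure(list(length_cm = length_cm, inner_diameter_um = inner_diameter_um),
            class = "tube_spec")
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("<tube_spec> %g cm x %g um ID (%.1f uL)\n",
              x$length_cm, x$inner_diameter_um, tube_volume(x)))
  invisible(x)
}

#' Volumetric flow settings
#'
#' @param flowrate_ul_s Volumetric flowrate in uL/s (default 2, the working
#'   hydrostatic flowrate).
#' @param diffusivity_m2_s Solute molecular diffusivity in m^2/s; the default
#'   4.25e-10 is a literature value for fluorescein in water.
#' @return Object of class `flow_spec`.
#' @export
flow_spec <- function(flowrate_ul_s = 2, diffusivity_m2_s = 4.25e-10) {
  stopifnot(flowrate_ul_s >= 0, diffusivity_m2_s > 0)
  structure(list(flowrate_ul_s = flowrate_ul_s,
                 diffusivity_m2_s = diffusivity_m2_s),
            class = "flow_spec")
}

#' Inlet tube volume
#'
#' @param tube A `tube_spec`.
#' @return Volume in uL (`pi * (ID/2)^2 * length`).
#' @examples
#' tube_volume(tube_spec())  # ~10.8 uL, i.e. "about 11 uL"
#' @export
tube_volume <- function(tube) {
  radius_cm <- tube$inner_diameter_um / 2 * 1e-4
  pi * radius_cm^2 * tube$length_cm * 1e3  # cm^3 -> uL
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Mean axial flow velocity in the tube
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec` with flowrate > 0.
#' @return Velocity in m/s.
#' @export
tube_velocity <- function(tube, flow) {
  a <- tube$inner_diameter_um / 2 * 1e-6
  q <- flow$flowrate_ul_s * 1e-9  # m^3/s
  q / (pi * a^2)
}

#' Effective axial dispersion coefficient
#'
#' Classical Taylor-Aris dispersion in laminar tube flow:
#' `K = D + a^2 U^2 / (48 D)` with tube radius `a`, mean velocity `U`, and
#' molecular diffusivity `D`. With `dispersion = FALSE` only molecular
#' diffusion (`K = D`) acts, which in the `D -> 0` limit gives plug flow.
#'
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec`.
#' @param dispersion Include the shear-enhanced term?
#' @return K in m^2/s.
#' @export
dispersion_coefficient <- function(tube, flow, dispersion = TRUE) {
  d <- flow$diffusivity_m2_s
  if (!dispersion) return(d)
  a <- tube$inner_diameter_um / 2 * 1e-6
  u <- tube_velocity(tube, flow)
  d + a^2 * u^2 / (48 * d)
}

#' Validity check for the Taylor-Aris regime
#'
#' Taylor's analysis assumes the solute samples the tube cross-section many
#' times during transit, i.e. the radial diffusion time `a^2/D` is short
#' compared with the residence time `L/U`. The returned ratio
#' `(a^2/D)/(L/U)` should be well below 1; values near or above 1 mean the
#' closed-form breakthrough curve is only an approximation of the true
#' dispersing front.
#'
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec`.
#' @return List with `radial_time_s`, `transit_time_s`, `ratio`, and
#'   `marginal` (TRUE when ratio > 0.1).
#' @export
dispersion_regime <- function(tube, flow) {
  a <- tube$inner_diameter_um / 2 * 1e-6
  u <- tube_velocity(tube, flow)
  radial <- a^2 / flow$diffusivity_m2_s
  transit <- (tube$length_cm * 1e-2) / u
  list(radial_time_s = radial, transit_time_s = transit,
       ratio = radial / transit, marginal = radial / transit > 0.1)
}

#' Breakthrough of a new fluid at the tube exit
#'
#' After a well switch the new fluid must flush the old fluid from the inlet
#' tube. The front spreads by Taylor-Aris dispersion, so the exit
#' concentration of the new fluid follows
#' `c(t) = 1/2 * erfc((L - U t) / (2 sqrt(K t)))`,
#' a sigmoidal rise centred at one tube-volume of flow (where it is exactly
#' 0.5) and approaching 1 as `t -> Inf`.
#'
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec`; flowrate must be > 0.
#' @param time_s Time(s) since the switch, seconds (>= 0).
#' @param dispersion Include the Taylor shear term in `K`? `FALSE` keeps
#'   molecular diffusion only.
#' @param warn_regime Warn when the Taylor-Aris validity ratio is marginal
#'   (see [dispersion_regime()]).
#' @return Fraction(s) of new fluid at the tube exit, in `[0, 1]`.
#' @examples
#' tb <- tube_spec(); fl <- flow_spec()
#' breakthrough(tb, fl, tube_volume(tb) / 2)   # one tube volume -> 0.5
#' @export
breakthrough <- function(tube, flow, time_s, dispersion = TRUE,
                         warn_regime = FALSE) {
  if (flow$flowrate_ul_s <= 0) stop("flowrate must be > 0", call. = FALSE)
  stopifnot(all(time_s >= 0))
  if (warn_regime) {
    reg <- dispersion_regime(tube, flow)
    if (reg$marginal) {
      warning(sprintf(
        "Taylor-Aris regime marginal: radial diffusion time / transit time = %.2f",
        reg$ratio), call. = FALSE)
    }
  }
  l <- tube$length_cm * 1e-2
  u <- tube_velocity(tube, flow)
  k <- dispersion_coefficient(tube, flow, dispersion)
  out <- numeric(length(time_s))
  pos <- time_s > 0
  out[pos] <- 0.5 * erfc((l - u * time_s[pos]) / (2 * sqrt(k * time_s[pos])))
  pmin(pmax(out, 0), 1)
}

#' Tube volumes of flow needed to reach a completeness threshold
#'
#' Root-finds the smallest time at which the breakthrough fraction reaches
#' `threshold` and expresses it in units of one tube volume of flow
#' (`tube_volume / flowrate`). At the default settings the switch is 99.9%
#' complete within about 4.5 tube volumes, consistent with the working rule
#' that about 5 tube volumes (~30 s at 2 uL/s) replace the prior fluid.
#'
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec`.
#' @param threshold Completeness in (0.5, 1).
#' @param dispersion Passed to [breakthrough()].
#' @return Number of tube volumes (dimensionless, >= 1).
#' @export
volumes_to_completeness <- function(tube, flow, threshold = 0.999,
                                    dispersion = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold >= 1) {
    stop("threshold must be in (0.5, 1)", call. = FALSE)
  }
  tv <- tube_volume(tube) / flow$flowrate_ul_s  # s per tube volume
  f <- function(n) breakthrough(tube, flow, n * tv, dispersion) - threshold
  upper <- 2
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, lower = 1e-9, upper = upper, tol = 1e-10)$root
}

#' Well-to-well carryover model
#'
#' Carryover is modelled as a calibrated residual fraction of the previous
#' well's solute per switch, not derived from the ideal dispersion tail: the
#' measured residual (~0.32% at a 30 s fill delay) exceeds what the
#' closed-form Taylor-Aris tail predicts, so the residual is an empirical
#' parameter. Each tubing wash step reduces it by a further factor `r`
#' (default one order of magnitude).
#'
#' @param f Residual fraction per switch, in `[0, 1)`; default 0.0032.
#' @param r Per-wash reduction factor in `(0, 1]`; default 0.1.
#' @param f_sd Switch-to-switch standard deviation of the residual fraction
#'   (default 4.7e-4, i.e. 0.047% in percent units).
#' @return Object of class `carryover_model`.
#' @export
carryover_model <- function(f = 0.0032, r = 0.1, f_sd = 4.7e-4) {
  stopifnot(f >= 0, f < 1, r > 0, r <= 1, f_sd >= 0)
  structure(list(f = f, r = r, f_sd = f_sd), class = "carryover_model")
}

#' Expected carryover percentage after wash steps
#'
#' @param model A `carryover_model`.
#' @param washes Number of sequential tubing wash steps (>= 0).
#' @return Percent carryover: `100 * f * r^washes`.
#' @examples
#' carryover_after_washes(carryover_model(), 0)  # 0.32%
#' carryover_after_washes(carryover_model(), 2)  # < 0.02%
#' @export
carryover_after_washes <- function(model, washes) {
  stopifnot(all(washes >= 0), all(washes == round(washes)))
  100 * model$f * model$r^washes
}

#' Backpressure reservoir configuration
#'
#' A reservoir elevated a few centimetres above the plate's fluid surface
#' supplies the small hydrostatic pressure that counteracts capillary
#' pressure at the open tube tip while the tube is raised.
#'
#' @param reservoir_height_cm Height of the reservoir fluid surface above
#'   the plate fluid surface, cm.
#' @param capillary_setpoint_pa Capillary pressure to balance, Pa (default
#'   200 Pa, about 2 cm of water).
#' @param tolerance_pa Acceptable deviation, Pa (> 0).
#' @param fluid_density_kg_m3 Fluid density (default water).
#' @return Object of class `backpressure_config`.
#' @export
backpressure_config <- function(reservoir_height_cm = 2,
                                capillary_setpoint_pa = 200,
                                tolerance_pa = 20,
                                fluid_density_kg_m3 = 1000) {
  stopifnot(tolerance_pa > 0, fluid_density_kg_m3 > 0)
  structure(list(reservoir_height_cm = reservoir_height_cm,
                 capillary_setpoint_pa = capillary_setpoint_pa,
                 tolerance_pa = tolerance_pa,
                 fluid_density_kg_m3 = fluid_density_kg_m3),
            class = "backpressure_config")
}

#' Classify the backpressure balance
#'
#' Compares the hydrostatic pressure `rho * g * h` with the capillary
#' setpoint window. Below the window a raised tube draws in an air bubble
#' (`bubble_risk`); above it, backward flow pushes a droplet out of the tube
#' tip (`droplet_risk`); within it the tube can lift out of a well safely
#' (`balanced`).
#'
#' @param cfg A `backpressure_config`.
#' @return One of `"bubble_risk"`, `"balanced"`, `"droplet_risk"`, with the
#'   hydrostatic pressure in attribute `"pressure_pa"`.
#' @export
backpressure_state <- function(cfg) {
  g <- 9.80665
  p <- cfg$fluid_density_kg_m3 * g * cfg$reservoir_height_cm * 1e-2
  state <- if (p < cfg$capillary_setpoint_pa - cfg$tolerance_pa) {
    "bubble_risk"
  } else if (p > cfg$capillary_setpoint_pa + cfg$tolerance_pa) {
    "droplet_risk"
  } else {
    "balanced"
  }
  structure(state, pressure_pa = p)
}

#' Export a breakthrough curve as CSV
#'
#' @param tube,flow Tube and flow specs.
#' @param times_s Numeric vector of times.
#' @param path Output CSV path (columns `time_s,fraction`).
#' @return The path, invisibly.
#' @export
write_breakthrough_csv <- function(tube, flow, times_s, path) {
  df <- data.frame(time_s = times_s,
                   fraction = breakthrough(tube, flow, times_s))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
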