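with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Carryover scan generator preset
#'
#' Emulates the fluorescence readout of the alternating dye/water assay: a
#' camera baseline offset, a dye plateau, per-switch residual carryover
#' drawn around the model's residual fraction, and per-frame read noise.
#' The noise default is small because the readout is a 25 x 25 pixel
#' ROI-averaged intensity.
#'
#' @param model A `carryover_model`.
#' @param dye_intensity,baseline_intensity Mean ROI intensities (a.u.) of a
#'   dye well and of the camera baseline; dye must exceed baseline.
#' @param noise_sd Per-frame Gaussian noise on the ROI mean, a.u.
#' @param frames_per_well Frames recorded per well (15 s at 10 fps).
#' @param roi ROI size in pixels, `c(width, height)`.
#' @return Object of class `carryover_preset`.
#' @export
carryover_preset <- function(model = carryover_model(),
                             dye_intensity = 1100, baseline_intensity = 100,
                             noise_sd = 0.5, frames_per_well = 150,
                             roi = c(25, 25)) {
  stopifnot(dye_intensity > baseline_intensity, baseline_intensity >= 0,
            noise_sd >= 0, frames_per_well >= 1)
  structure(list(model = model, dye_intensity = dye_intensity,
                 baseline_intensity = baseline_intensity,
                 noise_sd = noise_sd,
                 frames_per_well = as.integer(frames_per_well), roi = roi),
            class = "carryover_preset")
}

#' Generate a synthetic carryover plate scan
#'
#' Walks the scan order: dye wells read at the dye intensity; each
#' buffer well immediately following a dye well reads
#' `baseline + residual * (dye - baseline)` with the residual fraction
#' drawn per switch as `Normal(f, f_sd)` truncated at zero; other buffer
#' wells read at baseline. Gaussian read noise is added per frame, and a
#' pre-scan dark recording (camera baseline, no fluid delivered) is
#' included for baseline subtraction.
#'
#' @param map A `plate_map` (e.g. from [carryover_assay_map()]).
#' @param preset A `carryover_preset`.
#' @param order Scan order (defaults to the map's own order).
#' @param dye,buffer Fluid names in the map.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `well_scan`: list with `frames`
#'   (data.frame `well,frame,intensity` in scan order), `dark` (pre-scan
#'   camera baseline frames), plus the map, order, fluid roles and preset.
#' @export
gen_carryover_scan <- function(map, preset = carryover_preset(),
                               order = map$order, dye = "fluorescein",
                               buffer = "water", seed = NULL) {
  if (is.null(order)) stop("map carries no scan order", call. = FALSE)
  fl <- map$assignments$fluid[match(order, map$assignments$well)]
  if (anyNA(fl)) stop("order contains wells missing from the map", call. = FALSE)
  m <- preset$model
  span <- preset$dye_intensity - preset$baseline_intensity
  with_seed(seed, {
    true_val <- numeric(length(order))
    for (i in seq_along(order)) {
      true_val[i] <- if (fl[i] == dye) {
        preset$dye_intensity
      } else if (i > 1L && fl[i - 1L] == dye) {
        resid <- max(0, stats::rnorm(1, m$f, m$f_sd))
        preset$baseline_intensity + resid * span
      } else {
        preset$baseline_intensity
      }
    }
    nf <- preset$frames_per_well
    frames <- data.frame(
      well = rep(order, each = nf),
      frame = rep(seq_len(nf), times = length(order)),
      intensity = rep(true_val, each = nf) +
        stats::rnorm(length(order) * nf, 0, preset$noise_sd),
      stringsAsFactors = FALSE)
    dark <- preset$baseline_intensity +
      stats::rnorm(nf, 0, preset$noise_sd)
    structure(list(frames = frames, dark = dark, map = map, order = order,
                   dye = dye, buffer = buffer, preset = preset),
              class = "well_scan")
  })
}

#' @export
print.well_scan <- function(x, ...) {
  cat(sprintf("<well_scan> %d wells x %d frames (dye '%s' / buffer '%s')\n",
              length(x$order), x$preset$frames_per_well, x$dye, x$buffer))
  invisible(x)
}

#' Render one well of a scan as a small image stack
#'
#' Builds the image-path fixture: each frame is a `height x width` field at
#' half the camera baseline with a bright ROI block carrying the well's
#' frame intensity. Intensities are scaled by `full_scale` into `[0, 1]`.
#'
#' @param scan A `well_scan`.
#' @param well Well id.
#' @param width,height Frame size in pixels.
#' @param full_scale Intensity corresponding to 1.0 (default 4096, a 12-bit
#'   camera).
#' @return 3D array `height x width x frames`.
#' @export
scan_to_stack <- function(scan, well, width = 64, height = 64,
                          full_scale = 4096) {
  vals <- scan$frames$intensity[scan$frames$well == well]
  if (length(vals) == 0L) stop("well ", well, " not in scan", call. = FALSE)
  roi_w <- scan$preset$roi[1]; roi_h <- scan$preset$roi[2]
  r0 <- floor((height - roi_h) / 2) + 1L
  c0 <- floor((width - roi_w) / 2) + 1L
  arr <- array(scan$preset$baseline_intensity / 2 / full_scale,
               dim = c(height, width, length(vals)))
  for (k in seq_along(vals)) {
    arr[r0:(r0 + roi_h - 1L), c0:(c0 + roi_w - 1L), k] <- vals[k] / full_scale
  }
  arr
}

#' Neuron response preset for the dose-response generator
#'
#' Parameterises a Hill-type concentration response with pulse-wise
#' adaptation and double-exponential trace kinetics. Defaults emulate the
#' two chemosensory neuron classes: AWA responds from low diacetyl
#' concentrations (EC50 1.15 uM) and does not adapt across pulses; ASH is a
#' high-threshold responder (EC50 1.15 mM, steep Hill slope) that adapts
#' rapidly (each pulse half the previous). The optional `coupling`
#' coefficient (off by default) suppresses this neuron's amplitude in
#' proportion to the other neuron's fractional activation, producing the
#' negative AWA-ASH correlation at high concentrations; enable it (e.g.
#' `coupling = 0.3` on AWA) to emulate that cross-neuron feedback.
#'
#' @param name `"AWA"` or `"ASH"` (selects defaults), or any label with all
#'   parameters given.
#' @param r_max Saturating response amplitude, dF/F0 units.
#' @param ec50 Half-maximal concentration, molar.
#' @param hill Hill coefficient (> 0).
#' @param adaptation Multiplicative amplitude factor per successive pulse,
#'   in (0, 1].
#' @param coupling Cross-suppression coefficient in `[0, 1)` (0 = none).
#' @param noise_sd Additive Gaussian noise on dF/F0 per sample.
#' @param tau_rise_s,tau_decay_s Kinetic time constants, seconds.
#' @return Object of class `neuron_preset`.
#' @export
neuron_preset <- function(name = c("AWA", "ASH"), r_max = NULL, ec50 = NULL,
                          hill = NULL, adaptation = NULL, coupling = NULL,
                          noise_sd = 0.05, tau_rise_s = 1, tau_decay_s = 5) {
  name <- match.arg(name)
  defaults <- list(
    AWA = list(r_max = 1.0, ec50 = 1.15e-6, hill = 1.5, adaptation = 1.0,
               coupling = 0.0),
    ASH = list(r_max = 1.0, ec50 = 1.15e-3, hill = 3.0, adaptation = 0.5,
               coupling = 0.0))[[name]]
  p <- list(name = name,
            r_max = if (is.null(r_max)) defaults$r_max else r_max,
            ec50 = if (is.null(ec50)) defaults$ec50 else ec50,
            hill = if (is.null(hill)) defaults$hill else hill,
            adaptation = if (is.null(adaptation)) defaults$adaptation else adaptation,
            coupling = if (is.null(coupling)) defaults$coupling else coupling,
            noise_sd = noise_sd, tau_rise_s = tau_rise_s,
            tau_decay_s = tau_decay_s)
  stopifnot(p$r_max > 0, p$ec50 > 0, p$hill > 0,
            p$adaptation > 0, p$adaptation <= 1, p$noise_sd >= 0,
            p$coupling >= 0, p$coupling < 1,
            p$tau_rise_s > 0, p$tau_decay_s > p$tau_rise_s)
  structure(p, class = "neuron_preset")
}

hill_fraction <- function(conc, ec50, hill) {
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

# unit-peak difference-of-exponentials response kernel
pulse_kernel <- function(t_rel, tau_r, tau_d) {
  tpk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  gmax <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  out <- numeric(length(t_rel))
  pos <- t_rel > 0
  out[pos] <- (exp(-t_rel[pos] / tau_d) - exp(-t_rel[pos] / tau_r)) / gmax
  out
}

#' Generate a synthetic dose-response trace set
#'
#' Per animal, concentration and pulse, a raw-fluorescence trace is built as
#' `F0 * (1 + response + noise)` where the response is the unit-peak
#' double-exponential kernel scaled by
#' `r_max * Hill(conc) * adaptation^(pulse-1)` and a per-animal lognormal
#' amplitude factor; each neuron's amplitude is additionally reduced by
#' `coupling * (other neuron's Hill fraction)`. Concentrations are delivered
#' in increasing order, buffer (0) first, as in the automated run.
#'
#' @param awa,ash `neuron_preset`s.
#' @param n_animals Animals per neuron type (default 18).
#' @param concentrations Molar concentrations (default buffer + the 7-step
#'   10-fold diacetyl series from 11.5 nM to 11.5 mM, increasing).
#' @param pulses Odor pulses per concentration (default 4, once per minute).
#' @param fps Sampling rate (default 10).
#' @param trace_s Acquisition length per pulse, seconds (default 30).
#' @param stim_onset_s,stim_duration_s Pulse onset within the acquisition
#'   and its duration.
#' @param f0 Baseline fluorescence, a.u.
#' @param animal_sd Lognormal sigma of the per-animal amplitude factor.
#' @param seed Integer seed.
#' @return Object of class `trace_set`: data.frame
#'   `neuron,animal,conc,pulse,time_s,f` with sampling/stimulus metadata in
#'   attributes.
#' @export
gen_dose_response <- function(awa = neuron_preset("AWA"),
                              ash = neuron_preset("ASH"),
                              n_animals = 18,
                              concentrations = c(0, rev(dilution_series(11.5e-3, 10, 7))),
                              pulses = 4, fps = 10, trace_s = 30,
                              stim_onset_s = 5, stim_duration_s = 10,
                              f0 = 100, animal_sd = 0.2, seed = NULL) {
  stopifnot(n_animals >= 1, pulses >= 1)
  time_s <- seq(0, trace_s, by = 1 / fps)
  presets <- list(AWA = awa, ASH = ash)
  with_seed(seed, {
    rows <- vector("list", 2L * n_animals * length(concentrations) * pulses)
    ri <- 0L
    for (nm in names(presets)) {
      p <- presets[[nm]]
      other <- presets[[setdiff(names(presets), nm)]]
      amp_animal <- stats::rlnorm(n_animals, 0, animal_sd)
      for (a in seq_len(n_animals)) {
        for (ci in seq_along(concentrations)) {
          conc <- concentrations[ci]
          h <- hill_fraction(conc, p$ec50, p$hill)
          h_other <- hill_fraction(conc, other$ec50, other$hill)
          for (pl in seq_len(pulses)) {
            # cross-suppression follows the other neuron's pulse response,
            # including its adaptation
            amp <- p$r_max * h * p$adaptation^(pl - 1) *
              (1 - p$coupling * h_other * other$adaptation^(pl - 1)) *
              amp_animal[a]
            resp <- amp * pulse_kernel(time_s - stim_onset_s,
                                       p$tau_rise_s, p$tau_decay_s)
            f <- f0 * (1 + resp + stats::rnorm(length(time_s), 0, p$noise_sd))
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              neuron = nm, animal = a, conc = conc, pulse = pl,
              time_s = time_s, f = f, stringsAsFactors = FALSE)
          }
        }
      }
    }
    ts <- do.call(rbind, rows)
    structure(ts, class = c("trace_set", "data.frame"),
              fps = fps, stim_onset_s = stim_onset_s,
              stim_duration_s = stim_duration_s, f0 = f0,
              presets = presets)
  })
}

#' Screen generator preset
#'
#' Per-solvent multiplicative suppression of the optogenetically evoked
#' peak response, at each tested concentration; 1 means no effect. The
#' defaults make isopropanol, methanol and acetonitrile suppressors at both
#' 1% and 5%, and ethanol at 5% only, on a baseline peak of 1 dF/F0.
#'
#' @param baseline_peak Evoked control peak, dF/F0.
#' @param suppression data.frame `solvent,concentration,factor`; solvents or
#'   concentrations absent from the table default to factor 1.
#' @param recovery Suppression is transient (responses recover in the next
#'   control well); recorded for provenance, the generator emits
#'   per-well peaks.
#' @param animal_sd Lognormal sigma of the per-animal response factor.
#' @param noise_sd Additive Gaussian noise per peak, dF/F0.
#' @return Object of class `screen_preset`.
#' @export
screen_preset <- function(baseline_peak = 1.0,
                          suppression = default_suppression(),
                          recovery = TRUE, animal_sd = 0.2,
                          noise_sd = 0.05) {
  stopifnot(baseline_peak > 0, animal_sd >= 0, noise_sd >= 0,
            all(suppression$factor >= 0), all(suppression$factor <= 1))
  structure(list(baseline_peak = baseline_peak, suppression = suppression,
                 recovery = isTRUE(recovery), animal_sd = animal_sd,
                 noise_sd = noise_sd),
            class = "screen_preset")
}

#' @rdname screen_preset
#' @export
default_suppression <- function() {
  data.frame(
    solvent = rep(c("isopropanol", "methanol", "acetonitrile", "ethanol"),
                  each = 2),
    concentration = rep(c(1, 5), 4),
    factor = c(0.40, 0.25, 0.45, 0.30, 0.50, 0.30, 1.00, 0.55),
    stringsAsFactors = FALSE)
}

suppression_factor <- function(preset, fluid, conc) {
  s <- preset$suppression
  i <- which(s$solvent == fluid & s$concentration == conc)
  if (length(i) == 1L) s$factor[i] else 1.0
}

#' Generate synthetic screen peak responses
#'
#' One evoked peak per animal and well along the screen delivery sequence:
#' `baseline_peak * suppression(fluid, conc) * animal_factor + noise`.
#' Control (buffer) wells have suppression 1. With 20 animals and the
#' 57-well sequence this yields 1,140 peaks.
#'
#' @param preset A `screen_preset`.
#' @param map A `plate_map` from [screen_map()] (its `order` is the delivery
#'   sequence).
#' @param n_animals Number of animals (default 20).
#' @param control Control fluid name.
#' @param seed Integer seed.
#' @return Object of class `screen_peaks`: data.frame
#'   `animal,well,fluid,concentration,peak`, with the map in an attribute.
#' @export
gen_screen <- function(preset = screen_preset(),
                       map = screen_map(default_solvents()),
                       n_animals = 20, control = "buffer", seed = NULL) {
  stopifnot(n_animals >= 1)
  if (is.null(map$order)) stop("map carries no delivery order", call. = FALSE)
  asg <- map$assignments[match(map$order, map$assignments$well), ]
  with_seed(seed, {
    amp <- stats::rlnorm(n_animals, 0, preset$animal_sd)
    n_wells <- nrow(asg)
    df <- data.frame(
      animal = rep(seq_len(n_animals), each = n_wells),
      well = rep(asg$well, times = n_animals),
      fluid = rep(asg$fluid, times = n_animals),
      concentration = rep(asg$concentration, times = n_animals),
      stringsAsFactors = FALSE)
    fac <- mapply(function(fl, cc) {
      if (fl == control) 1.0 else suppression_factor(preset, fl, cc)
    }, df$fluid, ifelse(is.na(df$concentration), 0, df$concentration))
    df$peak <- preset$baseline_peak * fac * amp[df$animal] +
      stats::rnorm(nrow(df), 0, preset$noise_sd)
    structure(df, class = c("screen_peaks", "data.frame"),
              map = map, control = control, preset = preset)
  })
}

#' Generate a synthetic staining intensity time-course
#'
#' Emulates the per-minute mean fluorescence of the device during the
#' automated staining run: flat background until the phalloidin incubation,
#' then, `onset_min` minutes into phalloidin exposure, a saturating
#' exponential rise to `background + plateau`.
#'
#' @param timeline Compiled staining `timeline` (must contain a phalloidin
#'   step).
#' @param onset_min Lag between phalloidin exposure start and the intensity
#'   rise, minutes (default 15).
#' @param plateau Intensity rise above background at saturation, a.u.
#' @param background Background intensity, a.u.
#' @param tau_min Rise time constant, minutes.
#' @param noise_sd Gaussian noise per sample, a.u.
#' @param n_minutes Number of samples at 1 frame/min (default 90).
#' @param seed Integer seed.
#' @return Object of class `staining_series`: data.frame
#'   `minute,intensity` (samples at the end of each minute).
#' @export
gen_staining_timecourse <- function(timeline, onset_min = 15, plateau = 100,
                                    background = 10, tau_min = 5,
                                    noise_sd = 1, n_minutes = 90,
                                    seed = NULL) {
  steps <- timeline$steps
  ph <- grep("phalloidin", steps$fluid, ignore.case = TRUE)
  if (length(ph) == 0L) stop("timeline contains no phalloidin step", call. = FALSE)
  t_phal_min <- steps$exposure_start_s[ph[1]] / 60
  minute <- seq_len(n_minutes)
  rise_from <- t_phal_min + onset_min
  mean_i <- ifelse(minute <= rise_from, background,
                   background + plateau * (1 - exp(-(minute - rise_from) / tau_min)))
  with_seed(seed, {
    df <- data.frame(minute = minute,
                     intensity = mean_i + stats::rnorm(n_minutes, 0, noise_sd))
    structure(df, class = c("staining_series", "data.frame"),
              phalloidin_start_min = t_phal_min, onset_min = onset_min,
              background = background, plateau = plateau)
  })
}

#' Write / read a trace set as CSV
#'
#' Long format `neuron,animal,conc,pulse,time_s,f` with sampling metadata in
#' a commented header line.
#'
#' @param ts A `trace_set`.
#' @param path File path.
#' @return The path (write) or a `trace_set` (read).
#' @export
write_trace_set <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%g stim_onset_s=%g stim_duration_s=%g",
                     attr(ts, "fps"), attr(ts, "stim_onset_s"),
                     attr(ts, "stim_duration_s")), con)
  utils::write.csv(as.data.frame(ts), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(df, class = c("trace_set", "data.frame"),
            fps = meta[1], stim_onset_s = meta[2], stim_duration_s = meta[3])
}
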