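#' Transition timing profile
#'
#' Durations of the seven phases of a well-to-well transfer, in order:
#' close the outlet valve, open the backpressure valve, raise the inlet
#' tube, move the plate, lower the tube, close the backpressure valve,
#' reopen the outlet valve. The defaults total 1.95 s for an adjacent-well
#' move, matching the under-2-second mechanical transfer; the plate-move
#' phase scales with the Chebyshev well distance.
#'
#' @param t_close_out,t_open_bp,t_raise,t_move_per_well,t_lower,t_close_bp,t_open_out
#'   Phase durations in seconds (all >= 0); `t_move_per_well` is per well of
#'   travel distance.
#' @return Object of class `timing_profile`.
#' @export
timing_profile <- function(t_close_out = 0.2, t_open_bp = 0.1, t_raise = 0.5,
                           t_move_per_well = 0.35, t_lower = 0.5,
                           t_close_bp = 0.1, t_open_out = 0.2) {
  p <- list(t_close_out = t_close_out, t_open_bp = t_open_bp,
            t_raise = t_raise, t_move_per_well = t_move_per_well,
            t_lower = t_lower, t_close_bp = t_close_bp,
            t_open_out = t_open_out)
  stopifnot(all(unlist(p) >= 0))
  structure(p, class = "timing_profile")
}

well_distance <- function(from, to) {
  if (is.null(from)) return(1)
  a <- parse_well(from); b <- parse_well(to)
  max(abs(a$row - b$row), abs(a$col - b$col))
}

timeline_event <- function(time_s, actor, action, detail = NA_character_) {
  data.frame(time_s = time_s, actor = actor, action = action,
             detail = detail, stringsAsFactors = FALSE)
}

#' Valve/servo/plate choreography of one well-to-well transfer
#'
#' Emits the seven ordered events of a transfer: the outlet valve closes
#' (stopping device flow so no bubble is drawn in), the backpressure valve
#' opens (balancing capillary pressure at the raised tube tip), the servo
#' raises the tube, the plate moves, the tube lowers into the new well, the
#' backpressure valve closes, and the outlet valve reopens so the new fluid
#' begins to flow.
#'
#' @param from_well Well id the tube leaves, or `NULL` when starting from
#'   the homed state.
#' @param to_well Destination well id.
#' @param profile A `timing_profile`.
#' @param t0 Start time in seconds.
#' @return A `timeline` fragment with 7 events; its `duration_s` is the sum
#'   of the phase durations.
#' @export
transition_sequence <- function(from_well, to_well, profile = timing_profile(),
                                t0 = 0) {
  move_s <- profile$t_move_per_well * well_distance(from_well, to_well)
  durs <- c(profile$t_close_out, profile$t_open_bp, profile$t_raise,
            move_s, profile$t_lower, profile$t_close_bp, profile$t_open_out)
  starts <- t0 + cumsum(c(0, durs[-7]))
  ev <- rbind(
    timeline_event(starts[1], "out_valve", "close"),
    timeline_event(starts[2], "bp_valve", "open"),
    timeline_event(starts[3], "servo", "raise"),
    timeline_event(starts[4], "plate", "move", to_well),
    timeline_event(starts[5], "servo", "lower"),
    timeline_event(starts[6], "bp_valve", "close"),
    timeline_event(starts[7], "out_valve", "open")
  )
  new_timeline(ev, steps = NULL, duration_s = sum(durs))
}

#' Stimulus pulse train specification
#'
#' @param channel `"odor-valve"` or `"red-light"`.
#' @param onset_s Onset of the first pulse relative to fill-delay
#'   completion, seconds.
#' @param duration_s Pulse duration, seconds.
#' @param period_s Pulse period, seconds.
#' @param count Number of pulses.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(channel = c("odor-valve", "red-light"),
                          onset_s = 0, duration_s = 10, period_s = 60,
                          count = 1) {
  channel <- match.arg(channel)
  stopifnot(onset_s >= 0, duration_s >= 0, period_s >= 0, count >= 1)
  structure(list(channel = channel, onset_s = onset_s,
                 duration_s = duration_s, period_s = period_s,
                 count = as.integer(count)),
            class = "stimulus_spec")
}

#' Image acquisition specification
#'
#' @param fps Frames per second.
#' @param duration_s Acquisition length per bout, seconds.
#' @param excitation_pulse_ms Excitation light pulse per frame, ms.
#' @param onset_s Start of the first bout relative to fill-delay completion.
#' @param period_s,count Bout period and count (defaults follow the paired
#'   stimulus when compiled).
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fps = 10, duration_s = 30,
                             excitation_pulse_ms = 10, onset_s = 0,
                             period_s = NULL, count = NULL) {
  stopifnot(fps > 0, duration_s >= 0, excitation_pulse_ms >= 0, onset_s >= 0)
  structure(list(fps = fps, duration_s = duration_s,
                 excitation_pulse_ms = excitation_pulse_ms,
                 onset_s = onset_s, period_s = period_s, count = count),
            class = "acquisition_spec")
}

#' One fluid-exposure step of a protocol
#'
#' A step delivers the fluid of one well for `duration_s` after a
#' `fill_delay_s` flush of the inlet tube. Steps of 30 minutes or longer
#' default to paused flow (both valves closed after the fill) so that wells
#' do not run empty and reagents are conserved; this is overridable.
#'
#' @param well Well id to draw from.
#' @param duration_s Fluid exposure duration after the fill delay, seconds.
#' @param fill_delay_s Tube flush time before the exposure counts, seconds
#'   (default 30, about 5 tube volumes at 2 uL/s).
#' @param fluid Optional fluid name (checked against the plate map when
#'   compiled).
#' @param pause_flow `NULL` for the automatic >= 30 min rule, or a logical.
#' @param stimulus Optional `stimulus_spec`.
#' @param acquisition Optional `acquisition_spec`.
#' @return Object of class `protocol_step`.
#' @export
protocol_step <- function(well, duration_s, fill_delay_s = 30, fluid = NULL,
                          pause_flow = NULL, stimulus = NULL,
                          acquisition = NULL) {
  stopifnot(duration_s >= 0, fill_delay_s >= 0)
  if (is.null(pause_flow)) pause_flow <- duration_s >= 1800
  structure(list(well = toupper(well), duration_s = duration_s,
                 fill_delay_s = fill_delay_s, fluid = fluid,
                 pause_flow = isTRUE(pause_flow), stimulus = stimulus,
                 acquisition = acquisition),
            class = "protocol_step")
}

new_timeline <- function(events, steps, duration_s, map = NULL) {
  events <- events[order(events$time_s, seq_len(nrow(events))), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, steps = steps, duration_s = duration_s,
                 map = map),
            class = "timeline")
}

#' @export
print.timeline <- function(x, ...) {
  n_steps <- if (is.null(x$steps)) 0L else nrow(x$steps)
  cat(sprintf("<timeline> %d events, %d fluid steps, %.1f s (%.2f min) total\n",
              nrow(x$events), n_steps, x$duration_s, x$duration_s / 60))
  invisible(x)
}

#' @export
as.data.frame.timeline <- function(x, ...) x$events

schedule_bouts <- function(t0, onset_s, period_s, count, duration_s,
                           actor, on_action, off_action, detail) {
  ev <- NULL
  for (k in seq_len(count)) {
    start <- t0 + onset_s + (k - 1) * period_s
    ev <- rbind(ev,
                timeline_event(start, actor, on_action, detail),
                timeline_event(start + duration_s, actor, off_action, detail))
  }
  ev
}

#' Compile a per-well protocol into a timed event stream
#'
#' Concatenates, for every step: the well-to-well transition choreography,
#' the fill delay (tube flush under flow), any stimulus pulses and camera
#' acquisitions (scheduled relative to fill-delay completion), and the fluid
#' exposure itself, either under continuous flow or with both valves closed
#' when the step pauses flow. Compilation is deterministic and validates the
#' per-well volume budget `flowrate * (fill_delay + flowing time)` against
#' the loaded volume in the plate map.
#'
#' @param map A `plate_map` assigning fluids to wells.
#' @param steps List of `protocol_step`s.
#' @param flow A `flow_spec` (for the volume budget).
#' @param profile A `timing_profile`.
#' @return A `timeline`: ordered events, a per-step summary table, and the
#'   exact total duration (sum of transition, fill-delay and exposure
#'   durations).
#' @export
compile_protocol <- function(map, steps, flow = flow_spec(),
                             profile = timing_profile()) {
  if (length(steps) == 0L) {
    empty <- timeline_event(numeric(0), character(0), character(0),
                            character(0))
    return(new_timeline(empty, steps = NULL, duration_s = 0, map = map))
  }
  stopifnot(all(vapply(steps, inherits, TRUE, "protocol_step")))
  events <- NULL
  step_rows <- NULL
  drawn_ul <- stats::setNames(rep(0, nrow(map$assignments)),
                              map$assignments$well)
  t <- 0
  prev <- NULL
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    row <- match(s$well, map$assignments$well)
    if (is.na(row)) {
      stop("step ", i, ": well ", s$well, " is not assigned in the plate map",
           call. = FALSE)
    }
    if (!is.null(s$fluid) && !identical(s$fluid, map$assignments$fluid[row])) {
      stop("step ", i, ": well ", s$well, " holds '",
           map$assignments$fluid[row], "', not '", s$fluid, "'",
           call. = FALSE)
    }
    tr <- transition_sequence(prev, s$well, profile, t0 = t)
    events <- rbind(events, tr$events)
    t <- t + tr$duration_s
    fill_end <- t + s$fill_delay_s
    flowing_s <- s$fill_delay_s + if (s$pause_flow) 0 else s$duration_s
    need_ul <- flow$flowrate_ul_s * flowing_s
    drawn_ul[s$well] <- drawn_ul[s$well] + need_ul
    if (drawn_ul[s$well] > map$assignments$volume_ul[row] + 1e-9) {
      stop("step ", i, ": volume overdraw in well ", s$well, " (needs ",
           round(drawn_ul[s$well], 1), " uL, loaded ",
           map$assignments$volume_ul[row], " uL)", call. = FALSE)
    }
    if (!is.null(s$stimulus)) {
      st <- s$stimulus
      events <- rbind(events, schedule_bouts(
        fill_end, st$onset_s, st$period_s, st$count, st$duration_s,
        "stim", "pulse_on", "pulse_off", st$channel))
    }
    if (!is.null(s$acquisition)) {
      a <- s$acquisition
      period <- a$period_s
      count <- a$count
      if (is.null(period)) {
        period <- if (!is.null(s$stimulus)) s$stimulus$period_s else 0
      }
      if (is.null(count)) {
        count <- if (!is.null(s$stimulus)) s$stimulus$count else 1L
      }
      events <- rbind(events, schedule_bouts(
        fill_end, a$onset_s, period, count, a$duration_s,
        "camera", "acquire_start", "acquire_stop",
        sprintf("%g fps, %g ms excitation", a$fps, a$excitation_pulse_ms)))
    }
    if (s$pause_flow) {
      events <- rbind(events,
                      timeline_event(fill_end, "out_valve", "close", "pause flow"),
                      timeline_event(fill_end, "bp_valve", "close", "pause flow"),
                      timeline_event(fill_end + s$duration_s, "out_valve",
                                     "open", "resume flow"))
    }
    exposure_start <- fill_end
    t <- fill_end + s$duration_s
    step_rows <- rbind(step_rows, data.frame(
      step = i, well = s$well, fluid = map$assignments$fluid[row],
      fill_start_s = fill_end - s$fill_delay_s,
      exposure_start_s = exposure_start, exposure_end_s = t,
      duration_s = s$duration_s, fill_delay_s = s$fill_delay_s,
      paused = s$pause_flow, drawn_ul = need_ul,
      stringsAsFactors = FALSE))
    prev <- s$well
  }
  new_timeline(events, step_rows, duration_s = t, map = map)
}

#' Fill delay for a complete fluid switch
#'
#' Time for `k_volumes` tube volumes to flow: the working rule of thumb is
#' about 5 tube volumes (about 27 s for the default 10.8 uL tube at 2 uL/s,
#' programmed as 30 s in practice).
#'
#' @param tube A `tube_spec`.
#' @param flow A `flow_spec` with flowrate > 0.
#' @param k_volumes Number of tube volumes (default 5).
#' @return Duration in seconds.
#' @export
fill_delay_for <- function(tube, flow, k_volumes = 5) {
  if (flow$flowrate_ul_s <= 0) stop("flowrate must be > 0", call. = FALSE)
  stopifnot(k_volumes >= 0)
  k_volumes * tube_volume(tube) / flow$flowrate_ul_s
}

#' Continuous-flow time budget of one well
#'
#' @param well_volume_ul Loaded volume, uL.
#' @param flow A `flow_spec` with flowrate > 0.
#' @return Minutes of continuous flow (a 2 mL deep well at 2 uL/s lasts
#'   about 17 min).
#' @export
well_flow_budget <- function(well_volume_ul, flow = flow_spec()) {
  if (flow$flowrate_ul_s <= 0) stop("flowrate must be > 0", call. = FALSE)
  stopifnot(well_volume_ul >= 0)
  well_volume_ul / flow$flowrate_ul_s / 60
}

#' Validate a compiled timeline
#'
#' Scans the event stream, tracking valve and servo states, and reports
#' violations of the safety invariants: the outlet valve must never be open
#' while the servo is raised (which would draw an air bubble into the open
#' tube), and no well may be overdrawn beyond its loaded volume.
#'
#' @param timeline A `timeline`.
#' @return data.frame of violations (`time_s`, `type`, `message`); zero rows
#'   means the timeline is valid.
#' @export
validate_timeline <- function(timeline) {
  ev <- timeline$events
  violations <- data.frame(time_s = numeric(0), type = character(0),
                           message = character(0), stringsAsFactors = FALSE)
  servo_raised <- TRUE   # homed state
  out_open <- FALSE
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$actor == "servo") servo_raised <- e$action == "raise"
    if (e$actor == "out_valve") out_open <- e$action == "open"
    if (servo_raised && out_open) {
      violations <- rbind(violations, data.frame(
        time_s = e$time_s, type = "valve_safety",
        message = "outlet valve open while servo raised (bubble ingestion risk)",
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(timeline$steps) && !is.null(timeline$map)) {
    drawn <- tapply(timeline$steps$drawn_ul, timeline$steps$well, sum)
    loaded <- timeline$map$assignments$volume_ul[
      match(names(drawn), timeline$map$assignments$well)]
    over <- which(drawn > loaded + 1e-9)
    for (j in over) {
      violations <- rbind(violations, data.frame(
        time_s = NA_real_, type = "volume_overdraw",
        message = sprintf("well %s: %.1f uL drawn of %.1f uL loaded",
                          names(drawn)[j], drawn[j], loaded[j]),
        stringsAsFactors = FALSE))
    }
  }
  violations
}

#' The ten-step cell fixation and staining protocol
#'
#' Builds the plate map (solutions in wells A1-A10 of a deep 96-well plate,
#' 2 mL each) and step list of the automated staining procedure: 30 s PBS
#' wash, 10 min fixation in 4% PFA, 30 s PBS, 10 min permeabilisation in
#' 0.25% Triton X-100, 30 s PBS, 30 min blocking in 1% BSA, 30 min f-actin
#' staining with AF488-phalloidin, 30 s PBS, 3 min Hoechst nuclear
#' counterstain, and a final 30 s PBS wash. Summed fluid exposure is
#' 85.5 min; the two 30-min incubations pause flow. The first step has no
#' fill delay: the inlet tube is pre-filled with the first solution by a
#' backpressure-driven reverse fill before it is lowered into well A1.
#'
#' @param fill_delay_s Tube switch delay programmed per well change
#'   (default 30 s).
#' @return List with `map` (a `plate_map`) and `steps` (list of
#'   `protocol_step`s).
#' @export
staining_protocol <- function(fill_delay_s = 30) {
  fluids <- c("PBS", "PFA-4%", "PBS", "TritonX100-0.25%", "PBS", "BSA-1%",
              "phalloidin-AF488", "PBS", "Hoechst-33342", "PBS")
  durations_s <- c(30, 600, 30, 600, 30, 1800, 1800, 30, 180, 30)
  plate <- plate_spec("96-deep")
  wells <- well_id(1, 1:10)
  df <- data.frame(well = wells, fluid = fluids,
                   concentration = NA_real_, volume_ul = 2000,
                   stringsAsFactors = FALSE)
  map <- new_plate_map(plate, df)
  map$order <- wells
  fills <- c(0, rep(fill_delay_s, 9))
  steps <- mapply(function(w, f, d, fd) {
    protocol_step(w, duration_s = d, fill_delay_s = fd, fluid = f)
  }, wells, fluids, durations_s, fills, SIMPLIFY = FALSE)
  list(map = map, steps = unname(steps))
}

#' A dose-response exposure step
#'
#' One well of an odor dose-response run: a 45 s fill delay, then four 10 s
#' odor pulses once per minute, each with a 30 s acquisition at 10 fps.
#'
#' @param well Well id.
#' @param pulses,pulse_s,period_s Stimulus count, duration and period.
#' @param fill_delay_s Fill delay (default 45 s).
#' @param acq_s,fps Acquisition bout length and frame rate.
#' @return A `protocol_step` of duration `pulses * period_s`.
#' @export
dose_response_step <- function(well, pulses = 4, pulse_s = 10, period_s = 60,
                               fill_delay_s = 45, acq_s = 30, fps = 10) {
  protocol_step(
    well, duration_s = pulses * period_s, fill_delay_s = fill_delay_s,
    stimulus = stimulus_spec("odor-valve", onset_s = 0, duration_s = pulse_s,
                             period_s = period_s, count = pulses),
    acquisition = acquisition_spec(fps = fps, duration_s = acq_s))
}

#' Total fluid exposure time of a compiled timeline
#' @param timeline A `timeline`.
#' @return Summed step exposure durations, minutes.
#' @export
exposure_minutes <- function(timeline) {
  if (is.null(timeline$steps)) return(0)
  sum(timeline$steps$duration_s) / 60
}

#' Export a timeline
#'
#' `write_timeline_csv` writes the flat event log
#' (`time_s,actor,action,detail`); `timeline_to_json` serialises events,
#' step table and total duration.
#'
#' @param timeline A `timeline`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(timeline$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeline_csv
#' @export
timeline_to_json <- function(timeline, path) {
  jsonlite::write_json(
    list(duration_s = timeline$duration_s, steps = timeline$steps,
         events = timeline$events),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Serial command stream for a timeline's plate moves
#'
#' @param timeline A `timeline`.
#' @return Command string (lowered move per plate-move event).
#' @export
timeline_commands <- function(timeline) {
  moves <- timeline$events[timeline$events$actor == "plate", "detail"]
  if (length(moves) == 0L) return("")
  commands_for_order(moves)
}
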