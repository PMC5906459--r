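#' ROI mean intensity of an image stack
#'
#' Averages a subset of frames (by default the first, middle and last, to
#' reduce noise) and returns the mean over a rectangular region of
#' interest.
#'
#' @param stack 3D array `rows x cols x frames` (or a matrix, treated as one
#'   frame).
#' @param roi Integer vector `c(row0, col0, height, width)`, 1-based; `NULL`
#'   uses the whole frame.
#' @param frame_picks `"first-middle-last"` (default) or `"all"`, or an
#'   integer vector of frame indices.
#' @return Mean intensity (a.u.) over the ROI of the averaged frames.
#' @examples
#' st <- array(rep(c(10, 20, 30, 40, 50), each = 4), dim = c(2, 2, 5))
#' roi_mean_intensity(st)  # frames 1,3,5 -> 30
#' @export
roi_mean_intensity <- function(stack, roi = NULL,
                               frame_picks = "first-middle-last") {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  nf <- dim(stack)[3]
  picks <- if (is.numeric(frame_picks)) {
    as.integer(frame_picks)
  } else if (identical(frame_picks, "all")) {
    seq_len(nf)
  } else if (identical(frame_picks, "first-middle-last")) {
    unique(c(1L, as.integer(ceiling(nf / 2)), nf))
  } else {
    stop("unknown frame_picks", call. = FALSE)
  }
  if (any(picks < 1L | picks > nf)) stop("frame pick out of range", call. = FALSE)
  if (is.null(roi)) roi <- c(1L, 1L, dim(stack)[1], dim(stack)[2])
  r <- roi[1]:(roi[1] + roi[3] - 1L)
  cc <- roi[2]:(roi[2] + roi[4] - 1L)
  if (min(r) < 1L || max(r) > dim(stack)[1] ||
      min(cc) < 1L || max(cc) > dim(stack)[2]) {
    stop("ROI out of frame bounds", call. = FALSE)
  }
  avg <- apply(stack[, , picks, drop = FALSE], c(1, 2), mean)
  mean(avg[r, cc])
}

#' Per-well intensities of a scan
#'
#' Reduces each well's frame series to one value by averaging the first,
#' middle and last frames, the convention used to reduce read noise.
#'
#' @param scan A `well_scan`.
#' @return Named numeric vector (one value per well, in scan order) with
#'   the pre-scan camera baseline (mean of all dark frames, since the dark
#'   recording is not motion-limited) in attribute `"baseline"`.
#' @export
scan_well_intensities <- function(scan) {
  fml <- function(v) mean(v[unique(c(1L, ceiling(length(v) / 2), length(v)))])
  vals <- vapply(scan$order, function(w) {
    fml(scan$frames$intensity[scan$frames$well == w])
  }, numeric(1))
  structure(vals, baseline = mean(scan$dark))
}

#' Well-to-well carryover table
#'
#' For every buffer well that immediately follows a dye well along the scan
#' order, the percent carryover is the baseline-corrected buffer intensity
#' relative to the baseline-corrected intensity of the preceding dye well:
#' `100 * (I_buffer - I_0) / (I_dye - I_0)`.
#'
#' @param intensities Named per-well intensities (a.u.), e.g. from
#'   [scan_well_intensities()].
#' @param map A `plate_map` giving each well's fluid.
#' @param order Scan order (defaults to the map's order).
#' @param baseline Camera baseline: a numeric intensity, or a well id whose
#'   intensity is used.
#' @param dye,buffer Fluid names.
#' @return Object of class `carryover_table`: data.frame
#'   `well,prev_dye_well,percent` with `mean` and `sd` attributes.
#' @examples
#' iv <- c(A1 = 1100, A2 = 103.2)
#' # directly: 100 * (103.2 - 100) / (1100 - 100) = 0.32
#' @export
carryover_table <- function(intensities, map, order = map$order,
                            baseline, dye = "fluorescein", buffer = "water") {
  if (is.null(order)) stop("no scan order available", call. = FALSE)
  base <- if (is.character(baseline)) {
    if (!baseline %in% names(intensities)) {
      stop("baseline well ", baseline, " has no intensity", call. = FALSE)
    }
    intensities[[baseline]]
  } else {
    as.numeric(baseline)
  }
  fl <- map$assignments$fluid[match(order, map$assignments$well)]
  rows <- NULL
  for (i in seq_along(order)[-1]) {
    if (fl[i] == buffer && fl[i - 1] == dye) {
      i_dye <- intensities[[order[i - 1]]]
      i_buf <- intensities[[order[i]]]
      if (i_dye <= base) {
        stop("prior dye well ", order[i - 1],
             " is not above baseline; carryover undefined", call. = FALSE)
      }
      rows <- rbind(rows, data.frame(
        well = order[i], prev_dye_well = order[i - 1],
        percent = 100 * (i_buf - base) / (i_dye - base),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) rows <- data.frame(well = character(0),
                                        prev_dye_well = character(0),
                                        percent = numeric(0))
  structure(rows, class = c("carryover_table", "data.frame"),
            mean = mean(rows$percent), sd = stats::sd(rows$percent))
}

#' @export
print.carryover_table <- function(x, ...) {
  cat(sprintf("<carryover_table> %d dye-to-buffer switches: %.3f%% +/- %.3f%% S.D.\n",
              nrow(x), attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

#' End-to-end carryover analysis of a synthetic scan
#'
#' @param scan A `well_scan`.
#' @return A `carryover_table` (baseline from the pre-scan dark recording).
#' @export
analyze_carryover <- function(scan) {
  iv <- scan_well_intensities(scan)
  carryover_table(iv, scan$map, scan$order,
                  baseline = attr(iv, "baseline"),
                  dye = scan$dye, buffer = scan$buffer)
}

#' Normalised fluorescence change (dF/F0)
#'
#' `(F - F0) / F0` with `F0` the mean fluorescence over a pre-stimulus
#' window (by default the final 2 s before stimulus onset).
#'
#' @param f Raw fluorescence series.
#' @param time_s Sample times (same length as `f`).
#' @param stim_onset_s Stimulus onset, seconds.
#' @param f0_window_s Width of the pre-stimulus baseline window, seconds.
#' @return dF/F0 series.
#' @export
dff <- function(f, time_s, stim_onset_s, f0_window_s = 2) {
  stopifnot(length(f) == length(time_s), f0_window_s > 0)
  in_win <- time_s >= stim_onset_s - f0_window_s & time_s < stim_onset_s
  if (!any(in_win)) stop("empty F0 window before stimulus onset", call. = FALSE)
  f0 <- mean(f[in_win])
  if (f0 <= 0) stop("non-positive F0; cannot normalise", call. = FALSE)
  (f - f0) / f0
}

#' Peak dF/F0 response to a stimulus
#'
#' Maximum of the series within `[onset, onset + duration + post_window]`.
#'
#' @param dff_series dF/F0 values.
#' @param time_s Sample times.
#' @param stim_onset_s,stim_duration_s Stimulus onset and duration, seconds.
#' @param post_window_s Extra window after stimulus offset (default 5 s).
#' @return Peak value.
#' @export
peak_response <- function(dff_series, time_s, stim_onset_s, stim_duration_s,
                          post_window_s = 5) {
  stopifnot(length(dff_series) == length(time_s))
  in_win <- time_s >= stim_onset_s &
    time_s <= stim_onset_s + stim_duration_s + post_window_s
  if (!any(in_win)) stop("empty peak window", call. = FALSE)
  max(dff_series[in_win])
}

boxcar <- function(x, k) {
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Peak responses of every trace in a trace set
#'
#' Applies [dff()] then [peak_response()] to each
#' (neuron, animal, concentration, pulse) trace. Before the peak is taken
#' the dF/F0 series is smoothed with a short boxcar (default 0.5 s) so
#' that the window maximum reads the calcium transient rather than the
#' extreme of the frame noise.
#'
#' @param ts A `trace_set` (raw fluorescence).
#' @param f0_window_s,post_window_s Analysis windows (seconds).
#' @param smooth_s Boxcar width in seconds (0 disables smoothing).
#' @return data.frame `neuron,animal,conc,pulse,peak`.
#' @export
trace_peaks <- function(ts, f0_window_s = 2, post_window_s = 5,
                        smooth_s = 0.5) {
  onset <- attr(ts, "stim_onset_s")
  dur <- attr(ts, "stim_duration_s")
  fps <- attr(ts, "fps")
  k <- max(1L, as.integer(round(smooth_s * fps)))
  df <- as.data.frame(ts)
  key <- interaction(df$neuron, df$animal, df$conc, df$pulse, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    d <- boxcar(dff(g$f, g$time_s, onset, f0_window_s), k)
    data.frame(neuron = g$neuron[1], animal = g$animal[1],
               conc = g$conc[1], pulse = g$pulse[1],
               peak = peak_response(d, g$time_s, onset, dur, post_window_s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$neuron, out$animal, out$conc, out$pulse), ]
}

#' Staining time-course summary
#'
#' Segments a per-minute intensity series by the fluid-exposure steps of a
#' compiled staining timeline and estimates the phalloidin onset lag: the
#' first minute at or after phalloidin exposure start whose intensity
#' exceeds the pre-phalloidin background mean by more than three background
#' standard deviations, expressed relative to phalloidin exposure start.
#'
#' @param series A `staining_series` (columns `minute`, `intensity`).
#' @param timeline The compiled staining `timeline`.
#' @return List of class `staining_summary`: `segments` (per-step mean
#'   intensity), `onset_min` (estimated lag, `NA` if never exceeded),
#'   `background_mean`, `background_sd`.
#' @export
staining_curve <- function(series, timeline) {
  steps <- timeline$steps
  if (is.null(steps) || nrow(steps) == 0L) {
    stop("timeline has no fluid steps", call. = FALSE)
  }
  if (max(series$minute) < steps$exposure_start_s[nrow(steps)] / 60) {
    stop("intensity series is shorter than the timeline", call. = FALSE)
  }
  seg <- do.call(rbind, lapply(seq_len(nrow(steps)), function(i) {
    lo <- steps$exposure_start_s[i] / 60
    hi <- steps$exposure_end_s[i] / 60
    in_step <- series$minute > lo & series$minute <= hi
    data.frame(step = i, fluid = steps$fluid[i],
               start_min = lo, end_min = hi,
               mean_intensity = if (any(in_step))
                 mean(series$intensity[in_step]) else NA_real_,
               n_samples = sum(in_step), stringsAsFactors = FALSE)
  }))
  ph <- grep("phalloidin", steps$fluid, ignore.case = TRUE)
  if (length(ph) == 0L) stop("timeline contains no phalloidin step", call. = FALSE)
  t_phal <- steps$exposure_start_s[ph[1]] / 60
  pre <- series$intensity[series$minute <= t_phal]
  bg_mean <- mean(pre); bg_sd <- stats::sd(pre)
  post <- series[series$minute >= t_phal, ]
  hit <- which(post$intensity > bg_mean + 3 * bg_sd)
  onset <- if (length(hit) == 0L) NA_real_ else post$minute[hit[1]] - t_phal
  structure(list(segments = seg, onset_min = onset,
                 background_mean = bg_mean, background_sd = bg_sd,
                 phalloidin_start_min = t_phal),
            class = "staining_summary")
}

#' @export
print.staining_summary <- function(x, ...) {
  cat(sprintf("<staining_summary> %d steps; phalloidin onset lag: %s min\n",
              nrow(x$segments),
              if (is.na(x$onset_min)) "none detected" else
                sprintf("%.0f", x$onset_min)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Write a carryover table as CSV
#' @param tab A `carryover_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_carryover_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
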