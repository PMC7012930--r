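#' Build a visual stimulation protocol
#'
#' Constructs the event schedule used by both the synthetic-data generator
#' and the trace-processing stages. Four protocol kinds are supported:
#'
#' * `"drifting-grating"`: full-field sinusoidal gratings drifting in
#'   `directions` at temporal frequencies `tfs`, each presented `n_trials`
#'   times for `drift_s` seconds with `gray_s` seconds of gray screen after
#'   each presentation. Condition order is pseudorandomized per trial block,
#'   deterministically from `order_seed`.
#' * `"flash-spot"`: static spots of `spot_diameters` (micrometers) flashed
#'   for `flash_s` seconds, used for ON/OFF classification.
#' * `"retinotopy-bar"`: a bar sweeping periodically across the visual field
#'   along one axis; `sweep_extent_deg` and `sweep_speed_deg_per_s` set the
#'   sweep frequency (`sweep_speed_deg_per_s / sweep_extent_deg`).
#' * `"isoi-grating"`: episodic gratings for intrinsic-signal imaging,
#'   stationary for `stationary_s` then drifting for `motion_s` (a 20-s
#'   cycle by default, i.e. a 0.05-Hz stimulus frequency).
#'
#' @param kind one of `"drifting-grating"`, `"flash-spot"`,
#'   `"retinotopy-bar"`, `"isoi-grating"`.
#' @param directions stimulus motion directions in degrees. 0 deg denotes
#'   posterior (temporal-to-nasal) motion; angles increase counter-clockwise
#'   in screen coordinates.
#' @param tfs temporal frequencies in Hz.
#' @param spatial_frequency grating spatial frequency in cycles per degree.
#' @param n_trials trials per condition.
#' @param drift_s,gray_s drift and gray-screen durations in seconds.
#' @param frame_rate acquisition frame rate in Hz.
#' @param pre_s leading stimulus-free gray period in seconds (used for
#'   baseline estimation downstream).
#' @param spot_diameters flash-spot diameters in micrometers.
#' @param flash_s flash duration in seconds (flash-spot only).
#' @param off_window_s duration of the post-flash window used for OFF
#'   responses, in seconds.
#' @param sweep_extent_deg swept visual-field extent in degrees
#'   (retinotopy-bar only).
#' @param sweep_speed_deg_per_s bar speed in degrees per second.
#' @param n_sweeps number of sweep periods recorded per direction.
#' @param stationary_s,motion_s stationary/moving durations in seconds
#'   (isoi-grating only).
#' @param order_seed integer seed controlling the pseudorandomized event
#'   order; the order is a deterministic function of this value.
#'
#' @return An object of class `stim_protocol`: a list with the call
#'   parameters and an `events` data frame whose rows tile stimulus time
#'   without overlap. For grating kinds the events carry
#'   `(onset_s, onset_frame, direction, tf, trial)`; for flash spots
#'   `(onset_s, onset_frame, spot_diameter, trial)`.
#' @examples
#' p <- make_stimulus_protocol("drifting-grating")
#' nrow(p$events)  # 12 directions x 4 TFs x 6 trials = 288
#' @export
make_stimulus_protocol <- function(kind = c("drifting-grating", "flash-spot",
                                            "retinotopy-bar", "isoi-grating"),
                                   directions = NULL,
                                   tfs = c(0.3, 0.75, 1.2, 1.8),
                                   spatial_frequency = 0.03,
                                   n_trials = NULL,
                                   drift_s = 3, gray_s = 3,
                                   frame_rate = NULL,
                                   pre_s = NULL,
                                   spot_diameters = c(50, 100, 200, 400, 800),
                                   flash_s = 2, off_window_s = 2,
                                   sweep_extent_deg = 134.46,
                                   sweep_speed_deg_per_s = 9,
                                   n_sweeps = 10,
                                   stationary_s = 10, motion_s = 10,
                                   order_seed = 1L) {
  kind <- match.arg(kind)
  proto <- switch(kind,
    "drifting-grating" = {
      if (is.null(directions)) directions <- seq(0, 330, by = 30)
      if (is.null(n_trials)) n_trials <- 6L
      if (is.null(frame_rate)) frame_rate <- 30.9
      if (is.null(pre_s)) pre_s <- 12
      check_directions(directions)
      if (length(tfs) == 0L) stop("'tfs' must be non-empty", call. = FALSE)
      if (any(tfs <= 0)) stop("'tfs' must be positive", call. = FALSE)
      if (drift_s <= 0) stop("'drift_s' must be > 0", call. = FALSE)
      conds <- expand.grid(direction = directions, tf = tfs,
                           KEEP.OUT.ATTRS = FALSE)
      ev <- pseudorandom_events(conds, n_trials, order_seed)
      ev$onset_s <- pre_s + (seq_len(nrow(ev)) - 1L) * (drift_s + gray_s)
      list(events = ev, directions = sort(unique(directions)), tfs = sort(tfs),
           n_trials = n_trials, drift_s = drift_s, gray_s = gray_s)
    },
    "flash-spot" = {
      if (is.null(n_trials)) n_trials <- 3L
      if (is.null(frame_rate)) frame_rate <- 8
      if (is.null(pre_s)) pre_s <- 12
      if (length(spot_diameters) == 0L) {
        stop("'spot_diameters' must be non-empty", call. = FALSE)
      }
      conds <- data.frame(spot_diameter = spot_diameters)
      ev <- pseudorandom_events(conds, n_trials, order_seed)
      ev$onset_s <- pre_s + (seq_len(nrow(ev)) - 1L) * (flash_s + gray_s)
      list(events = ev, spot_diameters = sort(unique(spot_diameters)),
           n_trials = n_trials, flash_s = flash_s, gray_s = gray_s,
           off_window_s = off_window_s)
    },
    "retinotopy-bar" = {
      if (is.null(frame_rate)) frame_rate <- 6
      if (is.null(pre_s)) pre_s <- 0
      if (any(sweep_extent_deg <= 0) || sweep_speed_deg_per_s <= 0) {
        stop("sweep extent and speed must be > 0", call. = FALSE)
      }
      f <- stimulus_frequency(sweep_extent_deg, sweep_speed_deg_per_s)
      list(events = data.frame(sweep = seq_len(n_sweeps)),
           sweep_extent_deg = sweep_extent_deg,
           sweep_speed_deg_per_s = sweep_speed_deg_per_s,
           sweep_freq_hz = f, n_sweeps = n_sweeps)
    },
    "isoi-grating" = {
      if (is.null(directions)) directions <- c(0, 90, 180, 270)
      if (is.null(n_trials)) n_trials <- 5L
      if (is.null(frame_rate)) frame_rate <- 6
      if (is.null(pre_s)) pre_s <- 10
      check_directions(directions)
      list(events = data.frame(cycle = seq_len(n_trials)),
           directions = directions, tfs = tfs, n_trials = n_trials,
           stationary_s = stationary_s, motion_s = motion_s,
           stim_freq_hz = 1 / (stationary_s + motion_s))
    }
  )
  if (frame_rate <= 0) stop("'frame_rate' must be > 0", call. = FALSE)
  proto$kind <- kind
  proto$frame_rate <- frame_rate
  proto$pre_s <- pre_s
  proto$spatial_frequency <- spatial_frequency
  proto$order_seed <- as.integer(order_seed)
  if (!is.null(proto$events$onset_s)) {
    proto$events$onset_frame <- floor(proto$events$onset_s * frame_rate) + 1L
  }
  class(proto) <- "stim_protocol"
  proto
}

check_directions <- function(directions) {
  if (length(directions) == 0L) {
    stop("'directions' must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(wrap_deg(directions))) {
    stop("'directions' must be distinct modulo 360", call. = FALSE)
  }
  invisible(directions)
}

# One pseudorandom permutation of the condition set per trial block.
pseudorandom_events <- function(conds, n_trials, order_seed) {
  blocks <- with_seed(order_seed, {
    lapply(seq_len(n_trials), function(tr) {
      b <- conds[sample.int(nrow(conds)), , drop = FALSE]
      b$trial <- tr
      b
    })
  })
  ev <- do.call(rbind, blocks)
  rownames(ev) <- NULL
  ev$event <- seq_len(nrow(ev))
  ev
}

#' Convenience protocols matching the cortical and retinal recordings
#'
#' `cortical_grating_protocol()` is the 12-direction, 4-TF, 6-trial
#' drifting-grating schedule sampled at 30.9 Hz; `retinal_grating_protocol()`
#' is the 8-direction, 4-TF, 3-trial variant used for isolated retinas;
#' `flash_spot_protocol()` presents 2-s static spots of five diameters
#' (50-800 um).
#'
#' @param order_seed integer seed for the pseudorandomized event order.
#' @param ... further arguments passed to [make_stimulus_protocol()].
#' @return A `stim_protocol` object.
#' @export
cortical_grating_protocol <- function(order_seed = 1L, ...) {
  make_stimulus_protocol("drifting-grating", order_seed = order_seed, ...)
}

#' @rdname cortical_grating_protocol
#' @export
retinal_grating_protocol <- function(order_seed = 1L, ...) {
  make_stimulus_protocol("drifting-grating",
                         directions = seq(0, 315, by = 45), n_trials = 3L,
                         frame_rate = 8, order_seed = order_seed, ...)
}

#' @rdname cortical_grating_protocol
#' @export
flash_spot_protocol <- function(order_seed = 1L, ...) {
  make_stimulus_protocol("flash-spot", order_seed = order_seed, ...)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", x$kind, "\n")
  cat("  frame rate:", x$frame_rate, "Hz\n")
  if (!is.null(x$directions)) {
    cat("  directions:", paste(x$directions, collapse = ", "), "deg\n")
  }
  if (!is.null(x$tfs)) cat("  TFs:", paste(x$tfs, collapse = ", "), "Hz\n")
  if (!is.null(x$spot_diameters)) {
    cat("  spot diameters:", paste(x$spot_diameters, collapse = ", "), "um\n")
  }
  if (!is.null(x$sweep_freq_hz)) {
    cat("  sweep frequency:", signif(x$sweep_freq_hz, 3), "Hz\n")
  }
  if (!is.null(x$events) && nrow(x$events)) {
    cat("  events:", nrow(x$events), "\n")
  }
  invisible(x)
}

#' Total duration in seconds of a protocol's recording
#' @param protocol a `stim_protocol`.
#' @param post_s trailing gray period appended after the last event.
#' @return duration in seconds.
#' @export
protocol_duration_s <- function(protocol, post_s = 6) {
  stopifnot(inherits(protocol, "stim_protocol"))
  switch(protocol$kind,
    "drifting-grating" = protocol$pre_s +
      nrow(protocol$events) * (protocol$drift_s + protocol$gray_s) + post_s,
    "flash-spot" = protocol$pre_s +
      nrow(protocol$events) * (protocol$flash_s + protocol$gray_s) + post_s,
    "retinotopy-bar" = protocol$n_sweeps / protocol$sweep_freq_hz,
    "isoi-grating" = protocol$pre_s +
      protocol$n_trials * (protocol$stationary_s + protocol$motion_s)
  )
}

#' Sweep frequency of a periodic mapping stimulus
#'
#' A bar traversing `extent_deg` degrees of visual field at
#' `speed_deg_per_s` deg/s completes `speed/extent` sweeps per second.
#' With the screen geometry used here (134.46 deg azimuth, 102.75 deg
#' elevation, 9 deg/s) this gives approximately 0.067 and 0.088 Hz.
#'
#' @param extent_deg swept extent in degrees (> 0).
#' @param speed_deg_per_s sweep speed in degrees per second (> 0).
#' @return frequency in Hz.
#' @examples
#' stimulus_frequency(134.46, 9)
#' @export
stimulus_frequency <- function(extent_deg, speed_deg_per_s) {
  if (any(extent_deg <= 0) || any(speed_deg_per_s <= 0)) {
    stop("extent and speed must be > 0", call. = FALSE)
  }
  speed_deg_per_s / extent_deg
}

#' Logical mask of stimulus-free frames for a protocol
#'
#' Marks frames outside every stimulus window (drift or flash periods),
#' i.e. the gray-screen and pre-stimulus segments. Used for the
#' mean + 2 SD responsiveness threshold of retinal recordings.
#'
#' @param protocol a `stim_protocol` of kind drifting-grating or flash-spot.
#' @param n_frames trace length in frames.
#' @return logical vector of length `n_frames`, `TRUE` where no stimulus
#'   was on screen.
#' @export
stimulus_free_mask <- function(protocol, n_frames) {
  stopifnot(inherits(protocol, "stim_protocol"))
  dur <- switch(protocol$kind,
    "drifting-grating" = protocol$drift_s,
    "flash-spot" = protocol$flash_s,
    stop("no event windows for kind ", protocol$kind, call. = FALSE))
  mask <- rep(TRUE, n_frames)
  len <- floor(dur * protocol$frame_rate)
  for (onset in protocol$events$onset_frame) {
    idx <- onset:min(n_frames, onset + len - 1L)
    mask[idx] <- FALSE
  }
  mask
}
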