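#' Synthesize a calcium-imaging recording from ground truth
#'
#' Builds per-ROI raw fluorescence traces for a drifting-grating or
#' flash-spot protocol. For each event the cell's noiseless expected
#' dF/F0 amplitude (see [expected_amplitude()]) drives a boxcar that is
#' convolved with a single-exponential calcium-indicator kernel (decay
#' time `tau`, GCaMP6f-like). The evoked fractional change multiplies an
#' instantaneous baseline `baseline_f * (1 + drift)`, where the drift is
#' a sum of slow sinusoids (periods > 120 s) that the percentile baseline
#' filter must remove, and white Gaussian noise of standard deviation
#' `noise_sd` (same arbitrary units as `baseline_f`) is added:
#' `raw(t) = F0(t) * (1 + y(t)) + noise(t)`.
#'
#' For flash spots the ON drive spans the illumination and the OFF drive
#' the `off_window_s` after it, with amplitudes `A*(1+bal)/2` and
#' `A*(1-bal)/2` so the cell's ON-OFF index equals `onoff_balance`.
#'
#' @param truth a `tuning_truth` table from [sample_population()].
#' @param protocol a drifting-grating or flash-spot [make_stimulus_protocol()].
#' @param seed integer seed.
#' @param tau calcium-indicator decay time constant in seconds.
#' @param drift_amp peak fractional amplitude of the slow baseline drift.
#' @param drift_periods_s periods of the drift sinusoids in seconds
#'   (all > 120 s).
#' @return An object of class `synthetic_recording`: list with `traces`
#'   (frames x cells matrix, arbitrary units), `frame_rate`, `events`,
#'   `truth`, `protocol`, and `f0_true` (the noiseless baseline time
#'   series common up to each cell's `baseline_f` scale; frames x cells).
#' @export
synthesize_recording <- function(truth, protocol, seed = 1L, tau = 0.6,
                                 drift_amp = 0.03,
                                 drift_periods_s = c(137, 211, 307)) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!protocol$kind %in% c("drifting-grating", "flash-spot")) {
    stop("protocol kind must be drifting-grating or flash-spot",
         call. = FALSE)
  }
  if (nrow(truth) == 0L) stop("empty population", call. = FALSE)
  if (any(drift_periods_s <= 120)) {
    stop("drift periods must exceed 120 s", call. = FALSE)
  }
  fr <- protocol$frame_rate
  n_frames <- ceiling(protocol_duration_s(protocol) * fr)
  tt <- (seq_len(n_frames) - 1) / fr
  alpha <- exp(-1 / (tau * fr))
  with_seed(seed, {
    drift <- rep(0, n_frames)
    if (drift_amp > 0) {
      ph <- stats::runif(length(drift_periods_s), 0, 2 * pi)
      for (k in seq_along(drift_periods_s)) {
        drift <- drift + sin(2 * pi * tt / drift_periods_s[k] + ph[k])
      }
      drift <- drift * drift_amp / length(drift_periods_s)
    }
    traces <- matrix(0, n_frames, nrow(truth))
    f0 <- matrix(0, n_frames, nrow(truth))
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, , drop = FALSE]
      x <- event_drive(row, protocol, n_frames)
      y <- as.numeric(stats::filter(x * (1 - alpha), alpha,
                                    method = "recursive"))
      f0i <- row$baseline_f * (1 + drift)
      tr <- f0i * (1 + y)
      if (row$noise_sd > 0) {
        tr <- tr + stats::rnorm(n_frames, 0, row$noise_sd)
      }
      traces[, i] <- tr
      f0[, i] <- f0i
    }
    colnames(traces) <- truth$cell_id
    colnames(f0) <- truth$cell_id
    structure(list(traces = traces, frame_rate = fr,
                   events = protocol$events, truth = truth,
                   protocol = protocol, f0_true = f0, tau = tau),
              class = "synthetic_recording")
  })
}

# Per-cell noiseless drive vector (expected dF/F0 level per frame).
event_drive <- function(row, protocol, n_frames) {
  x <- rep(0, n_frames)
  fr <- protocol$frame_rate
  ev <- protocol$events
  if (protocol$kind == "drifting-grating") {
    len <- floor(protocol$drift_s * fr)
    for (k in seq_len(nrow(ev))) {
      amp <- expected_amplitude(row, ev$direction[k], ev$tf[k])[1, 1]
      idx <- ev$onset_frame[k]:min(n_frames, ev$onset_frame[k] + len - 1L)
      x[idx] <- x[idx] + amp
    }
  } else {
    # ON-OFF cells respond transiently at light onset and offset; the
    # drive is normalized so the noiseless dF/F0 peak equals the nominal
    # amplitude after the calcium kernel.
    tr_len <- max(1L, floor(min(0.3, protocol$flash_s) * fr))
    flash_len <- floor(protocol$flash_s * fr)
    alpha <- exp(-1 / (0.6 * fr))
    norm <- 1 / (1 - alpha^tr_len)
    a_on <- norm * row$amp_base * (1 + row$onoff_balance) / 2
    a_off <- norm * row$amp_base * (1 - row$onoff_balance) / 2
    for (k in seq_len(nrow(ev))) {
      o <- ev$onset_frame[k]
      idx_on <- o:min(n_frames, o + tr_len - 1L)
      o2 <- o + flash_len
      idx_off <- o2:min(n_frames, o2 + tr_len - 1L)
      x[idx_on] <- x[idx_on] + a_on
      x[idx_off] <- x[idx_off] + a_off
    }
  }
  x
}

#' Closed-form pipeline attack factor of the calcium kernel
#'
#' At zero noise the trial amplitude recovered downstream (mean of the
#' largest 50% of dF/F0 samples in the drift window, at the downsampled
#' rate) equals the plateau amplitude times this factor, which accounts
#' for the exponential onset `1 - exp(-t / tau)` of the indicator kernel.
#'
#' @param protocol a drifting-grating `stim_protocol`.
#' @param tau kernel decay constant in seconds.
#' @param target_rate the downsampled rate used for amplitude extraction.
#' @return scalar in (0, 1\].
#' @export
kernel_attack_factor <- function(protocol, tau = 0.6, target_rate = 15.4) {
  factor <- max(1L, round(protocol$frame_rate / target_rate))
  ds_rate <- protocol$frame_rate / factor
  n <- floor(protocol$drift_s * ds_rate)
  t_i <- (seq_len(n) - 0.5) / ds_rate
  rise <- 1 - exp(-t_i / tau)
  top <- sort(rise, decreasing = TRUE)[seq_len(ceiling(n / 2))]
  mean(top)
}

#' Rectangular six-area layout emulating mouse visual cortex
#'
#' A synthetic arrangement of one large area (V1 by construction: the
#' largest) and five higher visual areas, each a rectangle with a linear
#' retinotopic gradient. `sign` flips the azimuth gradient, producing the
#' mirror-image polarity that the visual-field sign map detects.
#' Rectangles are separated by unresponsive gaps.
#'
#' @param dims image size in pixels (rows, cols).
#' @param pixel_mm pixel size in millimeters.
#' @param deg_per_px retinotopic gradient magnitude in degrees per pixel.
#' @return A `retinotopy_map_spec`: list with `dims`, `pixel_mm`, and an
#'   `areas` list of `(name, rows, cols, sign)`.
#' @export
hva_layout_spec <- function(dims = c(96, 96), pixel_mm = 0.02,
                            deg_per_px = 1.2) {
  areas <- list(
    list(name = "V1", rows = 30:89, cols = 6:45,  sign = +1),
    list(name = "LM", rows = 66:89, cols = 54:77, sign = -1),
    list(name = "AL", rows = 36:57, cols = 54:73, sign = +1),
    list(name = "RL", rows = 10:27, cols = 50:69, sign = -1),
    list(name = "AM", rows = 4:21,  cols = 24:43, sign = -1),
    list(name = "PM", rows = 4:25,  cols = 74:93, sign = +1)
  )
  structure(list(dims = dims, pixel_mm = pixel_mm,
                 deg_per_px = deg_per_px, areas = areas),
            class = "retinotopy_map_spec")
}

# Ground-truth azimuth/elevation/sign maps for a layout spec.
layout_truth_maps <- function(map_spec) {
  ny <- map_spec$dims[1]; nx <- map_spec$dims[2]
  az <- matrix(NA_real_, ny, nx)
  el <- matrix(NA_real_, ny, nx)
  sgn <- matrix(0, ny, nx)
  cent <- lapply(map_spec$areas, function(a) {
    rc <- mean(a$rows); cc <- mean(a$cols)
    az[a$rows, a$cols] <<- outer(rep(1, length(a$rows)),
                                 (a$cols - cc) * map_spec$deg_per_px * a$sign)
    el[a$rows, a$cols] <<- outer((a$rows - rc) * map_spec$deg_per_px,
                                 rep(1, length(a$cols)))
    sgn[a$rows, a$cols] <<- a$sign
    data.frame(name = a$name, centroid_row = rc, centroid_col = cc,
               n_px = length(a$rows) * length(a$cols), sign = a$sign)
  })
  list(azimuth = az, elevation = el, sign = sgn, mask = !is.na(az),
       areas = do.call(rbind, cent))
}

#' Synthesize intrinsic-signal retinotopy stacks
#'
#' Produces forward- and reverse-sweep pixel time-course stacks for both
#' axes. Every responsive pixel oscillates at the sweep frequency with a
#' phase that is an affine function of its retinotopic coordinate
#' (`phase = 2*pi*coord/extent`), plus a hemodynamic delay `delay_s`
#' identical in both sweep directions -- the assumption the
#' delay-subtraction method requires. The recording spans an integer
#' number of sweep periods so the stimulus frequency falls exactly on a
#' DFT bin.
#'
#' @param map_spec a [hva_layout_spec()] (or compatible list).
#' @param protocol a retinotopy-bar protocol; its `sweep_extent_deg` may be
#'   length 2 `(azimuth, elevation)`.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param delay_s hemodynamic delay in seconds.
#' @param noise_sd per-frame Gaussian noise, units of `baseline`.
#' @param amp fractional response amplitude of responsive pixels.
#' @param baseline mean pixel intensity in arbitrary units.
#' @return list with `stacks` (named list of `pixel_stack` objects:
#'   `azimuth_forward`, `azimuth_reverse`, `elevation_forward`,
#'   `elevation_reverse`), ground-`truth` maps (degrees), the sweep
#'   frequencies, `delay_s`, and `map_spec`.
#' @export
synthesize_retinotopy_stack <- function(map_spec, protocol, seed = 1L,
                                        delay_s = 0, noise_sd = 0,
                                        amp = 0.1, baseline = 1) {
  stopifnot(inherits(protocol, "stim_protocol"),
            protocol$kind == "retinotopy-bar")
  ext <- protocol$sweep_extent_deg
  if (length(ext) == 1L) ext <- c(azimuth = ext, elevation = ext)
  truth <- layout_truth_maps(map_spec)
  coord_rng <- range(c(truth$azimuth, truth$elevation), na.rm = TRUE)
  if (max(abs(coord_rng)) >= min(ext) / 2) {
    stop("retinotopic coordinates exceed half the sweep extent",
         call. = FALSE)
  }
  fr <- protocol$frame_rate
  make_pair <- function(coord_map, extent) {
    f_nom <- stimulus_frequency(extent, protocol$sweep_speed_deg_per_s)
    n_frames <- round(protocol$n_sweeps * fr / f_nom)
    f_used <- protocol$n_sweeps * fr / n_frames
    tt <- (seq_len(n_frames) - 1) / fr
    phi <- 2 * pi * coord_map / extent
    phi[is.na(phi)] <- 0
    a_map <- ifelse(truth$mask, amp, 0)
    phd <- 2 * pi * f_used * delay_s
    one <- function(sign_phi) {
      wt <- 2 * pi * f_used * tt
      m <- baseline * (1 + as.vector(a_map) *
                         cos(outer(sign_phi * as.vector(phi) + phd, wt, "+")))
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      pixel_stack(array(m, dim = c(nrow(coord_map), ncol(coord_map),
                                   n_frames)),
                  fr, stim_freq_hz = f_used)
    }
    list(forward = one(+1), reverse = one(-1), freq = f_used)
  }
  with_seed(seed, {
    az <- make_pair(truth$azimuth, ext[[1]])
    el <- make_pair(truth$elevation, ext[[2]])
    list(stacks = list(azimuth_forward = az$forward,
                       azimuth_reverse = az$reverse,
                       elevation_forward = el$forward,
                       elevation_reverse = el$reverse),
         truth = truth, sweep_freq_hz = c(azimuth = az$freq,
                                          elevation = el$freq),
         sweep_extent_deg = ext, delay_s = delay_s, map_spec = map_spec)
  })
}

#' Synthesize an episodic-grating intrinsic-signal stack
#'
#' Pixels inside responsive areas oscillate at the stimulus frequency
#' (1 / cycle period; 0.05 Hz for the default 10 s stationary + 10 s
#' motion cycle) with fractional amplitude proportional to the assigned
#' per-area strength. A `pre_s` baseline segment precedes the stimulus
#' for normalization downstream.
#'
#' @param map_spec a [hva_layout_spec()].
#' @param protocol an isoi-grating protocol.
#' @param strengths named numeric vector, response strength per area name
#'   (missing areas default to 0); must be non-negative.
#' @param seed integer seed (used when `noise_sd > 0`).
#' @param noise_sd per-frame Gaussian noise, units of `baseline`.
#' @param baseline mean pixel intensity in arbitrary units.
#' @return a `pixel_stack` with attributes `pre_s` and `stim_freq_hz`.
#' @export
synthesize_isoi_grating_stack <- function(map_spec, protocol, strengths,
                                          seed = 1L, noise_sd = 0,
                                          baseline = 1) {
  stopifnot(inherits(protocol, "stim_protocol"),
            protocol$kind == "isoi-grating")
  if (any(strengths < 0)) stop("strengths must be >= 0", call. = FALSE)
  fr <- protocol$frame_rate
  f <- protocol$stim_freq_hz
  pre_n <- round(protocol$pre_s * fr)
  stim_n <- round(protocol$n_trials * (protocol$stationary_s +
                                         protocol$motion_s) * fr)
  n_frames <- pre_n + stim_n
  ny <- map_spec$dims[1]; nx <- map_spec$dims[2]
  smap <- matrix(0, ny, nx)
  for (a in map_spec$areas) {
    s <- if (a$name %in% names(strengths)) strengths[[a$name]] else 0
    smap[a$rows, a$cols] <- s
  }
  tt <- (seq_len(stim_n) - 1) / fr
  mod <- 0.5 * (1 - cos(2 * pi * f * tt))
  with_seed(seed, {
    dat <- array(baseline, dim = c(ny, nx, n_frames))
    for (k in seq_len(stim_n)) {
      dat[, , pre_n + k] <- baseline * (1 + smap * mod[k])
    }
    if (noise_sd > 0) dat <- dat + stats::rnorm(length(dat), 0, noise_sd)
    out <- pixel_stack(dat, fr, stim_freq_hz = f)
    attr(out, "pre_s") <- protocol$pre_s
    out
  })
}

#' Pixel time-course stack container
#'
#' @param data numeric array `rows x cols x frames`.
#' @param frame_rate acquisition rate in Hz.
#' @param stim_freq_hz nominal stimulus frequency, if known.
#' @return object of class `pixel_stack`.
#' @export
pixel_stack <- function(data, frame_rate, stim_freq_hz = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, frame_rate > 0)
  structure(list(data = data, frame_rate = frame_rate,
                 stim_freq_hz = stim_freq_hz), class = "pixel_stack")
}
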