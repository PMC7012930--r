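#' Baseline fluorescence F0 from a raw trace
#'
#' The baseline is a rolling 10th-percentile over a 60-s window followed
#' by a zero-phase (forward-backward) low-pass Butterworth filter at
#' 0.01 Hz, order 2. The rolling window is truncated at the trace
#' boundaries (no padding is fabricated); before the Butterworth stage
#' the percentile series is edge-reflected so the filter start-up
#' transient does not distort the trace ends. The output is floored at a
#' small positive epsilon on the scale of the trace so it can divide a
#' dF/F0 computation.
#'
#' For long multi-ROI recordings `stride` evaluates the percentile on a
#' regular subgrid and linearly interpolates between evaluations; the
#' subsequent 0.01-Hz low-pass (100-s timescale) makes a one-second
#' stride numerically indistinguishable from the exact filter.
#'
#' @param raw_trace numeric fluorescence trace (arbitrary units).
#' @param frame_rate acquisition rate in Hz.
#' @param window_s percentile window length in seconds.
#' @param prob percentile (0.1 = 10th).
#' @param cutoff_hz Butterworth low-pass cutoff in Hz.
#' @param stride evaluation stride in frames (1 = every frame).
#' @return numeric baseline series, same length as `raw_trace`.
#' @export
compute_baseline_f0 <- function(raw_trace, frame_rate, window_s = 60,
                                prob = 0.1, cutoff_hz = 0.01, stride = 1L) {
  stop_if_not_finite(raw_trace, "raw_trace")
  n <- length(raw_trace)
  win <- round(window_s * frame_rate)
  if (n < win) {
    stop("trace shorter than the percentile window (", window_s, " s)",
         call. = FALSE)
  }
  half <- win %/% 2
  centers <- unique(c(seq(1L, n, by = as.integer(stride)), n))
  pc <- vapply(centers, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::quantile(raw_trace[lo:hi], prob, names = FALSE, type = 7)
  }, numeric(1))
  base <- if (length(centers) == n) pc else
    stats::approx(centers, pc, xout = seq_len(n))$y
  base <- lowpass_zero_phase(base, frame_rate, cutoff_hz)
  eps <- 1e-3 * stats::median(abs(raw_trace))
  if (eps <= 0) eps <- 1e-8
  pmax(base, eps)
}

# Order-2 Butterworth low-pass, applied forward-backward after reflecting
# the trace ends (pad ~1.5 filter time constants, capped at n - 1).
lowpass_zero_phase <- function(x, frame_rate, cutoff_hz) {
  w <- cutoff_hz / (frame_rate / 2)
  if (w >= 1) stop("cutoff at or above Nyquist", call. = FALSE)
  bf <- signal::butter(2, w, type = "low")
  n <- length(x)
  m0 <- mean(x)  # filter the deviation: zero-IC transients scale with it
  x <- x - m0
  p <- min(n - 1L, round(1.5 * frame_rate / cutoff_hz))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)] + m0
}

#' Baseline-normalized fluorescence (dF/F0)
#'
#' @param raw_trace raw fluorescence.
#' @param baseline baseline series from [compute_baseline_f0()]; must be
#'   strictly positive and of equal length.
#' @param frame_rate acquisition rate in Hz.
#' @return object of class `dff_trace`: list with `values`
#'   (dimensionless dF/F0), `frame_rate`, and `baseline_f0`.
#' @export
compute_dff <- function(raw_trace, baseline, frame_rate) {
  if (length(raw_trace) != length(baseline)) {
    stop("trace and baseline lengths differ", call. = FALSE)
  }
  if (any(baseline <= 0)) {
    stop("baseline must be strictly positive", call. = FALSE)
  }
  structure(list(values = (raw_trace - baseline) / baseline,
                 frame_rate = frame_rate, baseline_f0 = baseline),
            class = "dff_trace")
}

#' Downsample a dF/F0 trace by block averaging
#'
#' Decimates by the integer factor closest to `frame_rate / target_rate`
#' (default 30.9 to 15.4 Hz, factor 2), averaging consecutive blocks of
#' samples; a trailing partial block is dropped.
#'
#' @param dff a `dff_trace`.
#' @param target_rate requested rate in Hz (must be positive and not
#'   above the source rate).
#' @return a `dff_trace` at the achieved rate `frame_rate / factor`.
#' @export
downsample_trace <- function(dff, target_rate = 15.4) {
  stopifnot(inherits(dff, "dff_trace"))
  if (target_rate <= 0) stop("'target_rate' must be > 0", call. = FALSE)
  if (target_rate > dff$frame_rate) {
    stop("'target_rate' exceeds the source rate", call. = FALSE)
  }
  factor <- max(1L, round(dff$frame_rate / target_rate))
  n <- length(dff$values) %/% factor
  vals <- colMeans(matrix(dff$values[seq_len(n * factor)], nrow = factor))
  structure(list(values = vals, frame_rate = dff$frame_rate / factor,
                 baseline_f0 = NULL),
            class = "dff_trace")
}

#' Trial response amplitude from a stimulus window
#'
#' Sorts all dF/F0 samples inside the stimulus window and returns the
#' mean of the larger 50% (the top `ceiling(n/2)` samples, so an odd
#' window is never empty).
#'
#' @param dff a `dff_trace` (typically downsampled).
#' @param onset_s window onset in seconds from trace start.
#' @param duration_s window duration in seconds.
#' @return scalar amplitude in dF/F0 units.
#' @export
trial_response_amplitude <- function(dff, onset_s, duration_s = 3) {
  stopifnot(inherits(dff, "dff_trace"))
  rate <- dff$frame_rate
  start <- floor(onset_s * rate) + 1L
  len <- floor(duration_s * rate)
  if (len < 1L) stop("empty stimulus window", call. = FALSE)
  if (start < 1L || start + len - 1L > length(dff$values)) {
    stop("stimulus window outside the trace", call. = FALSE)
  }
  w <- dff$values[start:(start + len - 1L)]
  k <- ceiling(length(w) / 2)
  mean(sort(w, decreasing = TRUE)[seq_len(k)])
}

#' Assemble a tuning curve from trial responses
#'
#' @param trial_responses data frame with columns `direction`, `tf`,
#'   `trial`, `amplitude` (and optionally `cell_id`). Every
#'   (direction, tf) combination must have the same number of trials.
#' @return object of class `tuning_curve`: `directions` (sorted
#'   ascending), `tfs` (sorted), `mean` (directions x TFs matrix of
#'   trial-mean amplitudes), `trials` (directions x TFs x trials array),
#'   `n_trials`, `cell_id`.
#' @export
build_tuning_curve <- function(trial_responses) {
  req <- c("direction", "tf", "trial", "amplitude")
  if (!all(req %in% names(trial_responses))) {
    stop("need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  dirs <- sort(unique(trial_responses$direction))
  tfs <- sort(unique(trial_responses$tf))
  cnt <- table(factor(trial_responses$direction, levels = dirs),
               factor(trial_responses$tf, levels = tfs))
  if (length(unique(as.vector(cnt))) != 1L || any(cnt == 0L)) {
    bad <- which(cnt != max(cnt), arr.ind = TRUE)
    stop("unbalanced trials; missing/short conditions: ",
         paste(sprintf("(%s deg, %s Hz)", dirs[bad[, 1]], tfs[bad[, 2]]),
               collapse = " "), call. = FALSE)
  }
  nt <- as.vector(cnt)[1]
  arr <- array(NA_real_, dim = c(length(dirs), length(tfs), nt))
  for (r in seq_len(nrow(trial_responses))) {
    i <- match(trial_responses$direction[r], dirs)
    j <- match(trial_responses$tf[r], tfs)
    k <- trial_responses$trial[r]
    arr[i, j, k] <- trial_responses$amplitude[r]
  }
  if (anyNA(arr)) stop("trial indices must be 1..n_trials per condition",
                       call. = FALSE)
  cid <- if ("cell_id" %in% names(trial_responses)) {
    as.character(trial_responses$cell_id[1])
  } else NA_character_
  new_tuning_curve(cid, dirs, tfs, arr)
}

new_tuning_curve <- function(cell_id, directions, tfs, trials) {
  m <- apply(trials, c(1, 2), mean)
  dimnames(m) <- list(as.character(directions), as.character(tfs))
  structure(list(cell_id = cell_id, directions = directions, tfs = tfs,
                 mean = m, trials = trials, n_trials = dim(trials)[3]),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("<tuning_curve>", x$cell_id, "-", length(x$directions), "directions x",
      length(x$tfs), "TFs x", x$n_trials, "trials\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' Visual responsiveness of a cell
#'
#' Cortical mode: responsive if the preferred-direction trial-mean
#' amplitude (the maximum over directions at each TF) exceeds
#' `threshold` (default 0.06 dF/F0) in at least one TF. Retinal mode:
#' responsive if any single-trial amplitude exceeds the cell's
#' dF/F0 mean + 2 SD, computed over the stimulus-free samples of the
#' trace (see [stimulus_free_mask()]); pass the cell's full dF/F0 trace
#' via `dff`.
#'
#' @param curve a `tuning_curve`.
#' @param mode `"cortical"` or `"retinal"`.
#' @param threshold cortical amplitude gate in dF/F0 units.
#' @param dff `dff_trace` of the cell (retinal mode).
#' @param baseline_mask logical frame mask of stimulus-free samples
#'   (retinal mode); defaults to the whole trace when omitted.
#' @return list with `responsive` (logical) and `threshold` (the value
#'   actually applied).
#' @export
classify_responsive <- function(curve, mode = c("cortical", "retinal"),
                                threshold = 0.06, dff = NULL,
                                baseline_mask = NULL) {
  stopifnot(inherits(curve, "tuning_curve"))
  mode <- match.arg(mode)
  if (mode == "cortical") {
    best <- max(apply(curve$mean, 2, max))
    list(responsive = best > threshold, threshold = threshold)
  } else {
    if (is.null(dff)) {
      stop("retinal mode needs the cell's dF/F0 trace", call. = FALSE)
    }
    v <- dff$values
    if (!is.null(baseline_mask)) v <- v[baseline_mask]
    thr <- mean(v) + 2 * stats::sd(v)
    list(responsive = any(curve$trials > thr), threshold = thr)
  }
}

#' Full trace-processing pipeline for one recording
#'
#' For each ROI: percentile/Butterworth baseline, dF/F0, downsampling to
#' `target_rate`, per-event trial amplitudes, tuning-curve assembly and
#' the responsiveness gate.
#'
#' @param rec a [synthesize_recording()] result, or a compatible list
#'   with `traces` (frames x cells), `frame_rate`, and `protocol`.
#' @param mode responsiveness mode, `"cortical"` or `"retinal"`.
#' @param target_rate amplitude-extraction rate in Hz.
#' @param baseline_stride stride (frames) for the percentile filter;
#'   defaults to ~1 s.
#' @param use_true_f0 use the generator's noiseless baseline instead of
#'   estimating it (diagnostic).
#' @return list with `curves` (list of `tuning_curve`) and `responsive`
#'   (logical vector).
#' @export
process_recording <- function(rec, mode = c("cortical", "retinal"),
                              target_rate = 15.4,
                              baseline_stride = NULL,
                              use_true_f0 = FALSE) {
  mode <- match.arg(mode)
  proto <- rec$protocol
  stopifnot(proto$kind == "drifting-grating")
  fr <- rec$frame_rate
  if (is.null(baseline_stride)) baseline_stride <- max(1L, round(fr))
  nc <- ncol(rec$traces)
  curves <- vector("list", nc)
  responsive <- logical(nc)
  mask <- NULL
  for (i in seq_len(nc)) {
    raw <- rec$traces[, i]
    f0 <- if (use_true_f0) rec$f0_true[, i] else
      compute_baseline_f0(raw, fr, stride = baseline_stride)
    dff <- compute_dff(raw, f0, fr)
    ds <- downsample_trace(dff, target_rate)
    ev <- proto$events
    amps <- vapply(seq_len(nrow(ev)), function(k) {
      trial_response_amplitude(ds, ev$onset_s[k], proto$drift_s)
    }, numeric(1))
    tr <- data.frame(cell_id = colnames(rec$traces)[i],
                     direction = ev$direction, tf = ev$tf,
                     trial = ev$trial, amplitude = amps)
    curves[[i]] <- build_tuning_curve(tr)
    if (mode == "cortical") {
      responsive[i] <- classify_responsive(curves[[i]], "cortical")$responsive
    } else {
      if (is.null(mask)) mask <- stimulus_free_mask(proto, length(dff$values))
      responsive[i] <- classify_responsive(curves[[i]], "retinal", dff = dff,
                                           baseline_mask = mask)$responsive
    }
  }
  names(curves) <- colnames(rec$traces)
  list(curves = curves, responsive = responsive)
}

#' Peak ON and OFF responses to flash spots
#'
#' For each spot diameter, the ON response is the peak dF/F0 during the
#' illumination and the OFF response the peak during the
#' `off_window_s` after it, each averaged across trials.
#'
#' @param dff a `dff_trace`.
#' @param protocol a flash-spot `stim_protocol`.
#' @return data frame with `spot_diameter`, `r_on`, `r_off`.
#' @export
flash_peak_responses <- function(dff, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"),
            protocol$kind == "flash-spot")
  rate <- dff$frame_rate
  on_len <- floor(protocol$flash_s * rate)
  off_len <- floor(protocol$off_window_s * rate)
  ev <- protocol$events
  peaks <- lapply(seq_len(nrow(ev)), function(k) {
    o <- floor(ev$onset_s[k] * rate) + 1L
    c(on = max(dff$values[o:(o + on_len - 1L)]),
      off = max(dff$values[(o + on_len):(o + on_len + off_len - 1L)]))
  })
  pk <- do.call(rbind, peaks)
  agg <- stats::aggregate(pk, by = list(spot_diameter = ev$spot_diameter),
                          FUN = mean)
  data.frame(spot_diameter = agg$spot_diameter, r_on = agg$on,
             r_off = agg$off)
}
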