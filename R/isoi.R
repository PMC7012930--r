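#' Fourier phase and magnitude maps at the stimulus frequency
#'
#' For every pixel, the complex DFT coefficient at the bin nearest
#' `stim_freq` is computed from its time course; the map of phases
#' (wrapped to \[-pi, pi)) and amplitudes (2/N-scaled moduli) is
#' returned. A pixel following `cos(2*pi*f*t + psi)` yields phase `psi`.
#'
#' @param stack a [pixel_stack()].
#' @param stim_freq stimulus frequency in Hz; must be below Nyquist.
#' @return list with `phase` and `magnitude` matrices and `bin_freq`,
#'   the exact frequency of the DFT bin used.
#' @export
fourier_component_map <- function(stack, stim_freq = NULL) {
  stopifnot(inherits(stack, "pixel_stack"))
  if (is.null(stim_freq)) stim_freq <- stack$stim_freq_hz
  if (is.null(stim_freq)) stop("stimulus frequency unknown", call. = FALSE)
  fr <- stack$frame_rate
  if (stim_freq >= fr / 2) {
    stop("stimulus frequency at or above Nyquist", call. = FALSE)
  }
  d <- dim(stack$data)
  nt <- d[3]
  k <- round(stim_freq * nt / fr)
  if (k < 1) stop("recording too short to resolve the stimulus frequency",
                  call. = FALSE)
  basis <- exp(-2i * pi * k * (seq_len(nt) - 1) / nt)
  m <- matrix(stack$data, d[1] * d[2], nt)
  coef <- as.vector(m %*% basis)
  list(phase = matrix(wrap_pi(Arg(coef)), d[1], d[2]),
       magnitude = matrix(Mod(coef) * 2 / nt, d[1], d[2]),
       bin_freq = k * fr / nt)
}

#' Hemodynamic-delay subtraction of opposing sweep phase maps
#'
#' With opposing sweeps the measured phases are
#' `phi_fwd = theta + delta` and `phi_rev = -theta + delta`, where
#' `theta` encodes retinotopy and `delta` is the hemodynamic delay
#' common to both. The delay is the circular half-sum, resolved by
#' picking the half-sum candidate closest to zero (assumes
#' |delta| < a quarter stimulus period), and the retinotopic phase is
#' `phi_fwd - delta`, which keeps the full \[-pi, pi) range.
#'
#' @param phase_forward,phase_reverse phase matrices on the same grid.
#' @return list with `phase` (retinotopic phase map) and `delay`
#'   (per-pixel delay phase map), both in \[-pi, pi).
#' @export
delay_corrected_retinotopy <- function(phase_forward, phase_reverse) {
  if (!identical(dim(phase_forward), dim(phase_reverse))) {
    stop("phase maps must share one pixel grid", call. = FALSE)
  }
  s <- wrap_pi(phase_forward + phase_reverse)
  d1 <- s / 2
  d2 <- wrap_pi(d1 + pi)
  delay <- ifelse(abs(d1) <= abs(d2), d1, d2)
  list(phase = wrap_pi(phase_forward - delay), delay = delay)
}

#' Convert retinotopic phase to visual degrees
#'
#' Linear map of the phase range \[-pi, pi) onto
#' \[-extent/2, +extent/2).
#'
#' @param phase_map phase matrix in radians.
#' @param sweep_extent_deg swept extent in degrees (> 0).
#' @return matrix in visual degrees.
#' @export
phase_to_degrees <- function(phase_map, sweep_extent_deg) {
  if (sweep_extent_deg <= 0) stop("extent must be > 0", call. = FALSE)
  phase_map / (2 * pi) * sweep_extent_deg
}

#' Visual-field sign map
#'
#' The sign of the angle between the local retinotopic gradients:
#' `I = sin(angle(grad elevation) - angle(grad azimuth))`, evaluated
#' after Gaussian pre-smoothing of both maps (raw maps are too noisy for
#' pixelwise gradients). An azimuth map increasing along x with an
#' elevation map increasing along y gives `I = +1`; mirror-image areas
#' give `-1`. Pixels with a vanishing gradient (or missing coordinates)
#' get `I = 0`.
#'
#' @param azimuth_map,elevation_map retinotopic maps in degrees; `NA`
#'   marks unresponsive pixels.
#' @param sigma_px Gaussian pre-smoothing sigma in pixels (0 disables).
#' @return object of class `sign_map`: list with `I` (values in
#'   \[-1, 1\]) plus the smoothed maps.
#' @export
visual_field_sign <- function(azimuth_map, elevation_map, sigma_px = 2) {
  if (!identical(dim(azimuth_map), dim(elevation_map))) {
    stop("maps must share one pixel grid", call. = FALSE)
  }
  az <- gaussian_smooth(azimuth_map, sigma_px)
  el <- gaussian_smooth(elevation_map, sigma_px)
  gaz <- central_gradient(az)
  gel <- central_gradient(el)
  ok <- (gaz$gx^2 + gaz$gy^2) > 0 & (gel$gx^2 + gel$gy^2) > 0
  ok[is.na(ok)] <- FALSE
  I <- matrix(0, nrow(azimuth_map), ncol(azimuth_map))
  I[ok] <- sin(atan2(gel$gy, gel$gx)[ok] - atan2(gaz$gy, gaz$gx)[ok])
  structure(list(I = I, azimuth = az, elevation = el), class = "sign_map")
}

# NA-aware separable Gaussian smoothing (normalized convolution).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  w <- !is.na(m)
  x <- m
  x[!w] <- 0
  conv1 <- function(mat, along) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * shift_matrix(mat, off, along)
    }
    out
  }
  num <- conv1(conv1(x, "row"), "col")
  den <- conv1(conv1(w * 1, "row"), "col")
  res <- ifelse(den > 1e-10, num / den, NA_real_)
  res[!w] <- NA_real_
  res
}

# Shift with zero padding; along = "row" shifts down by off.
shift_matrix <- function(m, off, along) {
  out <- matrix(0, nrow(m), ncol(m))
  if (along == "row") {
    if (off >= 0) {
      if (off < nrow(m)) {
        out[(1 + off):nrow(m), ] <- m[1:(nrow(m) - off), ]
      }
    } else if (-off < nrow(m)) {
      out[1:(nrow(m) + off), ] <- m[(1 - off):nrow(m), ]
    }
  } else {
    if (off >= 0) {
      if (off < ncol(m)) {
        out[, (1 + off):ncol(m)] <- m[, 1:(ncol(m) - off)]
      }
    } else if (-off < ncol(m)) {
      out[, 1:(ncol(m) + off)] <- m[, (1 - off):ncol(m)]
    }
  }
  out
}

# Central-difference gradients; x along columns, y along rows.
# NAs propagate to NA, converted to zero-gradient by the caller.
central_gradient <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  gx <- matrix(NA_real_, ny, nx)
  gy <- matrix(NA_real_, ny, nx)
  gx[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]
  gx[, nx] <- m[, nx] - m[, nx - 1]
  gy[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]
  gy[ny, ] <- m[ny, ] - m[ny - 1, ]
  gx[is.na(gx)] <- 0
  gy[is.na(gy)] <- 0
  list(gx = gx, gy = gy)
}

#' Threshold and clean a visual-field sign map
#'
#' Retains pixels whose |I| reaches mean(|I|) + SD(|I|) (the
#' absolute-value reading keeps areas of both polarities), then smooths
#' the binary mask with a 3x3 median filter (majority of the
#' neighborhood, zero-padded at borders).
#'
#' @param sign_map a [visual_field_sign()] result (or plain matrix).
#' @return list with `mask` (binary matrix), `threshold`, and `sign`
#'   (the sign of I on retained pixels, for area polarity).
#' @export
threshold_and_clean <- function(sign_map) {
  I <- if (inherits(sign_map, "sign_map")) sign_map$I else sign_map
  stop_if_not_finite(I, "sign map")
  s <- stats::sd(abs(I))
  thr <- mean(abs(I)) + s
  # a constant map carries no sign structure: nothing exceeds the spread
  mask <- if (s == 0) matrix(0, nrow(I), ncol(I)) else (abs(I) >= thr) * 1
  mask <- median_filter3(mask)
  list(mask = mask, threshold = thr, sign = sign(I) * mask)
}

# 3x3 binary median filter (majority vote, zero padding).
median_filter3 <- function(mask) {
  s <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + shift_matrix(shift_matrix(mask, dr, "row"), dc, "col")
  }
  (s >= 5) * 1
}

#' Eight-neighbor isolation and gap filling
#'
#' A pixel is retained only if more than four of its eight neighbors are
#' non-zero; afterwards, gaps adjacent to retained pixels (zero pixels
#' with more than four retained neighbors) are filled. Pixels outside
#' the image border count as zero.
#'
#' @param mask binary matrix.
#' @return binary matrix.
#' @export
neighbor_filter <- function(mask) {
  nb <- neighbor_count(mask)
  kept <- (mask > 0 & nb > 4) * 1
  fill <- (kept == 0 & neighbor_count(kept) > 4) * 1
  pmax(kept, fill)
}

neighbor_count <- function(mask) {
  s <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + shift_matrix(shift_matrix(mask, dr, "row"), dc, "col")
  }
  s
}

#' Area borders, labels and geometry from a cleaned mask
#'
#' Binarizes the mask, finds borders with a Sobel edge detector, labels
#' connected components (8-connectivity), and computes per-area sizes
#' (pixels and mm^2) and centroids. Centroid coordinates are also
#' re-expressed relative to the centroid of the largest area (V1 by
#' construction).
#'
#' @param mask binary matrix from [threshold_and_clean()] /
#'   [neighbor_filter()].
#' @param pixel_mm pixel size in millimeters.
#' @param min_px discard components smaller than this many pixels.
#' @return object of class `area_segmentation`: list with `labels`
#'   (integer matrix), `edges` (binary Sobel edge map), and `areas`
#'   (data frame: label, n_px, area_mm2, centroid_row/col,
#'   centroid_x_mm/y_mm, rel_row/rel_col relative to the largest area).
#' @export
detect_borders <- function(mask, pixel_mm = 0.02, min_px = 9) {
  bin <- (mask > 0) * 1
  if (sum(bin) == 0) stop("empty mask", call. = FALSE)
  edges <- sobel_edges(bin)
  labels <- EBImage::bwlabel(bin)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_px)
  labels[!(labels %in% keep)] <- 0L
  rows <- lapply(keep, function(lb) {
    idx <- which(labels == lb, arr.ind = TRUE)
    data.frame(label = lb, n_px = nrow(idx),
               area_mm2 = nrow(idx) * pixel_mm^2,
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
  })
  areas <- do.call(rbind, rows)
  areas <- areas[order(-areas$n_px), ]
  areas$centroid_x_mm <- areas$centroid_col * pixel_mm
  areas$centroid_y_mm <- areas$centroid_row * pixel_mm
  areas$rel_row <- areas$centroid_row - areas$centroid_row[1]
  areas$rel_col <- areas$centroid_col - areas$centroid_col[1]
  rownames(areas) <- NULL
  structure(list(labels = labels, edges = edges, areas = areas,
                 pixel_mm = pixel_mm),
            class = "area_segmentation")
}

#' @export
print.area_segmentation <- function(x, ...) {
  cat("<area_segmentation>", nrow(x$areas), "areas\n")
  print(x$areas[, c("label", "n_px", "area_mm2", "centroid_row",
                    "centroid_col")], digits = 4)
  invisible(x)
}

# Sobel gradient magnitude > 0 on a binary image.
sobel_edges <- function(bin) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3(bin, kx)
  gy <- conv3(bin, t(kx))
  (sqrt(gx^2 + gy^2) > 0) * 1
}

conv3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in 1:3) for (j in 1:3) {
    out <- out + k[i, j] *
      shift_matrix(shift_matrix(m, i - 2L, "row"), j - 2L, "col")
  }
  out
}

#' Areal response strength from an episodic-grating stack
#'
#' Each pixel's time course is normalized to its mean over the
#' pre-stimulus segment, the peak spectral power inside the stimulus
#' band (default 0.05-0.1 Hz) is computed from the stimulus segment,
#' and the per-area strength is the maximum of that power map inside the
#' area's ROI. The pre-stimulus normalization makes the strength
#' invariant to a constant multiplicative gain on the stack.
#'
#' @param stack a [pixel_stack()] whose first `pre_s` seconds are
#'   stimulus-free.
#' @param areas an [detect_borders()] segmentation (or a label matrix).
#' @param stim_band frequency band in Hz.
#' @param pre_s pre-stimulus duration; defaults to the stack's `pre_s`
#'   attribute. Must be at least 10 s of data.
#' @return list with `power` (per-pixel normalized peak power map) and
#'   `strength` (named per-area maxima).
#' @export
areal_response_strength <- function(stack, areas, stim_band = c(0.05, 0.1),
                                    pre_s = NULL) {
  stopifnot(inherits(stack, "pixel_stack"))
  if (is.null(pre_s)) pre_s <- attr(stack, "pre_s")
  if (is.null(pre_s) || pre_s < 10) {
    stop("stack needs a >= 10 s pre-stimulus segment", call. = FALSE)
  }
  labels <- if (inherits(areas, "area_segmentation")) areas$labels else areas
  fr <- stack$frame_rate
  d <- dim(stack$data)
  pre_n <- round(pre_s * fr)
  if (pre_n >= d[3]) stop("no frames after the pre-stimulus segment",
                          call. = FALSE)
  m <- matrix(stack$data, d[1] * d[2], d[3])
  pre_mean <- rowMeans(m[, seq_len(pre_n), drop = FALSE])
  if (any(pre_mean <= 0)) stop("non-positive pre-stimulus mean",
                               call. = FALSE)
  rel <- m[, (pre_n + 1):d[3], drop = FALSE] / pre_mean
  nt <- ncol(rel)
  freqs <- (seq_len(nt) - 1) * fr / nt
  band <- which(freqs >= stim_band[1] & freqs <= stim_band[2])
  if (!length(band)) stop("no DFT bin inside the stimulus band",
                          call. = FALSE)
  sp <- Mod(stats::mvfft(t(rel)))^2 / nt^2
  pw <- matrix(apply(sp[band, , drop = FALSE], 2, max), d[1], d[2])
  labs <- sort(unique(labels[labels > 0]))
  strength <- vapply(labs, function(lb) max(pw[labels == lb]), numeric(1))
  names(strength) <- as.character(labs)
  list(power = pw, strength = strength)
}

#' End-to-end retinotopic mapping and area segmentation
#'
#' Chains the Fourier phase maps, delay subtraction, degree conversion,
#' visual-field sign map, thresholding, neighbor cleanup and border
#' detection for a four-stack retinotopy acquisition.
#'
#' @param stacks named list with `azimuth_forward`, `azimuth_reverse`,
#'   `elevation_forward`, `elevation_reverse` `pixel_stack`s.
#' @param sweep_extent_deg length-2 vector `(azimuth, elevation)` in
#'   degrees.
#' @param pixel_mm pixel size in mm.
#' @param sigma_px sign-map pre-smoothing sigma.
#' @param min_px minimum component size.
#' @param magnitude_floor pixels whose mean Fourier magnitude falls below
#'   this fraction of the image maximum are treated as unresponsive and
#'   excluded from the retinotopic maps (their phase is undefined), so
#'   they cannot bleed into the smoothed gradients.
#' @return list with `azimuth`, `elevation` (degree maps; `NA` on
#'   unresponsive pixels), `delay` (delay phase maps per axis),
#'   `sign_map`, `mask`, and `segmentation`.
#' @export
map_visual_areas <- function(stacks, sweep_extent_deg, pixel_mm = 0.02,
                             sigma_px = 2, min_px = 9,
                             magnitude_floor = 0.1) {
  need <- c("azimuth_forward", "azimuth_reverse",
            "elevation_forward", "elevation_reverse")
  stopifnot(all(need %in% names(stacks)))
  one_axis <- function(fwd, rev, extent) {
    pf <- fourier_component_map(fwd)
    pr <- fourier_component_map(rev)
    dc <- delay_corrected_retinotopy(pf$phase, pr$phase)
    list(deg = phase_to_degrees(dc$phase, extent), delay = dc$delay,
         magnitude = pf$magnitude)
  }
  az <- one_axis(stacks$azimuth_forward, stacks$azimuth_reverse,
                 sweep_extent_deg[[1]])
  el <- one_axis(stacks$elevation_forward, stacks$elevation_reverse,
                 sweep_extent_deg[[2]])
  resp <- (az$magnitude + el$magnitude) / 2
  silent <- resp < magnitude_floor * max(resp)
  az$deg[silent] <- NA_real_
  el$deg[silent] <- NA_real_
  sm <- visual_field_sign(az$deg, el$deg, sigma_px = sigma_px)
  tc <- threshold_and_clean(sm)
  mask <- neighbor_filter(tc$mask)
  seg <- detect_borders(mask, pixel_mm = pixel_mm, min_px = min_px)
  list(azimuth = az$deg, elevation = el$deg,
       delay = list(azimuth = az$delay, elevation = el$delay),
       sign_map = sm, mask = mask, segmentation = seg)
}
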