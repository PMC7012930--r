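#' Vector-sum preferred direction
#'
#' The preferred direction is the angle, in polar coordinates, of the
#' vector sum of the per-direction mean responses: each sampled direction
#' contributes a unit vector scaled by its (non-negative) mean amplitude,
#' and the angle is taken with the full-quadrant arctangent
#' `atan2(sum R_i sin d_i, sum R_i cos d_i)`. Negative amplitudes are
#' floored at zero before summation.
#'
#' @param curve a `tuning_curve`.
#' @param tf which temporal frequency (must be sampled).
#' @return list with `theta` (degrees in \[0, 360), `NA` when all
#'   responses are zero), `resultant` (vector-sum length), and
#'   `resultant_norm` (resultant / sum of amplitudes).
#' @export
preferred_direction <- function(curve, tf) {
  R <- curve_amplitudes(curve, tf)
  if (length(R) < 2L) stop("need >= 2 sampled directions", call. = FALSE)
  rad <- deg2rad(curve$directions)
  sx <- sum(R * sin(rad))
  cx <- sum(R * cos(rad))
  res <- sqrt(sx^2 + cx^2)
  if (sum(R) == 0) {
    return(list(theta = NA_real_, resultant = 0, resultant_norm = NA_real_))
  }
  list(theta = wrap_deg(rad2deg(atan2(sx, cx))), resultant = res,
       resultant_norm = res / sum(R))
}

# Non-negative mean amplitudes for one TF.
curve_amplitudes <- function(curve, tf) {
  j <- match(tf, curve$tfs)
  if (is.na(j)) stop("TF ", tf, " not sampled", call. = FALSE)
  unname(pmax(curve$mean[, j], 0))
}

# Index of the preferred sampled direction: nearest to the vector-sum
# angle, falling back to the maximum-amplitude direction when the
# resultant is numerically zero (perfectly symmetric curves).
preferred_index <- function(curve, tf) {
  R <- curve_amplitudes(curve, tf)
  if (sum(R) == 0) return(NA_integer_)
  pd <- preferred_direction(curve, tf)
  if (is.na(pd$theta) || pd$resultant_norm < 1e-9) return(which.max(R))
  nearest_direction(curve$directions, pd$theta)
}

#' Direction-selectivity index
#'
#' `DSI = (R_pref - R_opp) / (R_pref + R_opp)`, where `R_pref` is the
#' mean amplitude at the sampled direction closest to the vector-sum
#' preferred direction and `R_opp` the amplitude at the direction 180
#' degrees away. Amplitudes are floored at zero, so the index lies in
#' \[0, 1\]; it is 0 when both responses vanish.
#'
#' @inheritParams preferred_direction
#' @return scalar DSI.
#' @export
dsi <- function(curve, tf) {
  R <- curve_amplitudes(curve, tf)
  i_pref <- preferred_index(curve, tf)
  if (is.na(i_pref)) return(0)
  opp <- wrap_deg(curve$directions[i_pref] + 180)
  i_opp <- which(circ_dist_deg(curve$directions, opp) < 1e-6)
  if (length(i_opp) != 1L) {
    stop("direction opposite the preferred one (", opp,
         " deg) is not in the sampling grid", call. = FALSE)
  }
  r_p <- R[i_pref]; r_o <- R[i_opp]
  if (r_p + r_o == 0) return(0)
  (r_p - r_o) / (r_p + r_o)
}

#' Orientation-selectivity index
#'
#' `OSI = (R_pref - R_orth) / (R_pref + R_orth)`, where `R_pref` is the
#' mean response on the preferred orientation axis (the preferred
#' direction and its opposite) and `R_orth` the mean on the orthogonal
#' axis.
#'
#' @inheritParams preferred_direction
#' @return scalar OSI.
#' @export
osi <- function(curve, tf) {
  R <- curve_amplitudes(curve, tf)
  i_pref <- preferred_index(curve, tf)
  if (is.na(i_pref)) return(0)
  d0 <- curve$directions[i_pref]
  axis_mean <- function(base) {
    idx <- vapply(c(base, base + 180), function(a) {
      j <- which(circ_dist_deg(curve$directions, a) < 1e-6)
      if (length(j) != 1L) {
        stop("axis direction ", wrap_deg(a), " deg not sampled",
             call. = FALSE)
      }
      j
    }, integer(1))
    mean(R[idx])
  }
  r_p <- axis_mean(d0)
  r_o <- axis_mean(d0 + 90)
  if (r_p + r_o == 0) return(0)
  (r_p - r_o) / (r_p + r_o)
}

#' Direction-selective classification
#'
#' A cell is DS when it is visually responsive and its DSI strictly
#' exceeds `threshold` (default 0.3) in at least one TF.
#'
#' @param responsive logical responsiveness call.
#' @param dsi_per_tf numeric vector of DSI values across TFs.
#' @param threshold DSI gate.
#' @return logical.
#' @export
classify_ds <- function(responsive, dsi_per_tf, threshold = 0.3) {
  isTRUE(responsive) && max(dsi_per_tf) > threshold
}

#' Preferred temporal frequency
#'
#' The TF at which the preferred-direction mean amplitude (maximum over
#' directions at that TF) is largest; ties break toward the lower TF.
#'
#' @param curve a `tuning_curve`.
#' @return TF in Hz.
#' @export
preferred_tf <- function(curve) {
  peaks <- apply(curve$mean, 2, max)
  curve$tfs[which.max(peaks)]
}

#' ON-OFF index and ON-OFF classification from flash responses
#'
#' `OOI = (R_ON - R_OFF) / (R_ON + R_OFF)` per spot diameter (taken as 0
#' when both peaks are zero). A cell is classified ON-OFF when the mean
#' over diameters of |OOI| is below `threshold` (default 0.3): balanced
#' ON and OFF responses, whatever their sign pattern.
#'
#' @param flash data frame from [flash_peak_responses()] with columns
#'   `spot_diameter`, `r_on`, `r_off` (one row per diameter).
#' @param threshold classification gate on mean |OOI|.
#' @return list (class `flash_response`) with the per-diameter `ooi`,
#'   `mean_abs_ooi`, and `is_onoff`.
#' @export
ooi_and_onoff <- function(flash, threshold = 0.3) {
  stopifnot(all(c("spot_diameter", "r_on", "r_off") %in% names(flash)))
  s <- flash$r_on + flash$r_off
  ooi <- ifelse(s == 0, 0, (flash$r_on - flash$r_off) / s)
  m <- mean(abs(ooi))
  structure(list(spot_diameter = flash$spot_diameter, ooi = ooi,
                 mean_abs_ooi = m, is_onoff = m < threshold),
            class = "flash_response")
}

#' Horizontal/vertical axis class of a preferred direction
#'
#' Horizontal when the angle lies within 45 degrees of 0 or 180 (the
#' posterior-anterior axis), with the 45-degree boundary assigned to
#' horizontal; vertical otherwise.
#'
#' @param theta preferred direction(s) in degrees; `NA` passes through.
#' @return character vector, `"horizontal"` or `"vertical"`.
#' @export
axis_class <- function(theta) {
  ifelse(is.na(theta), NA_character_,
         ifelse(pmin(circ_dist_deg(theta, 0),
                     circ_dist_deg(theta, 180)) <= 45,
                "horizontal", "vertical"))
}

#' Ratio of response amplitudes at two temporal frequencies
#'
#' Preferred-direction amplitude at `tf_hi` divided by that at `tf_lo`
#' (defaults 1.2 and 0.3 Hz). Ratios above 1 flag cells whose response
#' grows with TF. A non-positive denominator yields `NA`.
#'
#' @param curve a `tuning_curve`.
#' @param tf_hi,tf_lo numerator and denominator TFs in Hz.
#' @return scalar ratio or `NA`.
#' @export
tf_response_ratio <- function(curve, tf_hi = 1.2, tf_lo = 0.3) {
  jh <- match(tf_hi, curve$tfs); jl <- match(tf_lo, curve$tfs)
  if (is.na(jh) || is.na(jl)) stop("both TFs must be sampled", call. = FALSE)
  hi <- max(curve$mean[, jh]); lo <- max(curve$mean[, jl])
  if (lo <= 0) return(NA_real_)
  hi / lo
}

#' Optomotor response ratio
#'
#' Ratio of the number of frames with head movement in the stimulus
#' direction to the number against it.
#'
#' @param frame_labels character/factor vector with levels
#'   `"with"`, `"against"`, `"neither"`.
#' @return scalar ratio; `NA` when no against-frames exist.
#' @export
omr_ratio <- function(frame_labels) {
  lv <- c("with", "against", "neither")
  if (!all(frame_labels %in% lv)) {
    stop("labels must be 'with', 'against' or 'neither'", call. = FALSE)
  }
  n_with <- sum(frame_labels == "with")
  n_against <- sum(frame_labels == "against")
  if (n_against == 0) return(NA_real_)
  n_with / n_against
}

#' Per-cell tuning summary
#'
#' Computes every per-TF tuning statistic for one cell: DSI, OSI,
#' vector-sum preferred direction, axis class, plus preferred TF, the
#' 1.2/0.3 Hz response ratio, responsiveness and the DS call.
#'
#' @param curve a `tuning_curve`.
#' @param responsive logical responsiveness call for the cell.
#' @param group,projection metadata labels carried into the row.
#' @param dsi_threshold DS gate (strict).
#' @return one-row data frame with columns `cell_id`, `group`,
#'   `projection`, `responsive`, `is_ds`, `preferred_tf`, `tf_ratio`, and
#'   per-TF columns `amp_<tf>`, `dsi_<tf>`, `osi_<tf>`, `theta_<tf>`,
#'   `axis_<tf>`.
#' @export
cell_summary <- function(curve, responsive = TRUE, group = NA_character_,
                         projection = NA_character_, dsi_threshold = 0.3) {
  tfs <- curve$tfs
  dsis <- vapply(tfs, function(tf) dsi(curve, tf), numeric(1))
  osis <- vapply(tfs, function(tf) osi(curve, tf), numeric(1))
  thetas <- vapply(tfs, function(tf) preferred_direction(curve, tf)$theta,
                   numeric(1))
  amps <- apply(curve$mean, 2, max)
  out <- data.frame(cell_id = curve$cell_id, group = group,
                    projection = projection, responsive = responsive,
                    is_ds = classify_ds(responsive, dsis, dsi_threshold),
                    preferred_tf = preferred_tf(curve),
                    tf_ratio = if (all(c(0.3, 1.2) %in% tfs))
                      tf_response_ratio(curve) else NA_real_)
  for (j in seq_along(tfs)) {
    out[[paste0("amp_", tfs[j])]] <- amps[j]
    out[[paste0("dsi_", tfs[j])]] <- dsis[j]
    out[[paste0("osi_", tfs[j])]] <- osis[j]
    out[[paste0("theta_", tfs[j])]] <- thetas[j]
    out[[paste0("axis_", tfs[j])]] <- axis_class(thetas[j])
  }
  out
}

#' Summaries for a list of tuning curves
#'
#' @param curves list of `tuning_curve` objects.
#' @param responsive logical vector (recycled) of responsiveness calls.
#' @param group,projection metadata labels (recycled).
#' @param dsi_threshold DS gate.
#' @return data frame with one row per cell (see [cell_summary()]).
#' @export
summarize_cells <- function(curves, responsive = TRUE, group = NA_character_,
                            projection = NA_character_, dsi_threshold = 0.3) {
  n <- length(curves)
  responsive <- rep_len(responsive, n)
  group <- rep_len(group, n)
  projection <- rep_len(projection, n)
  rows <- lapply(seq_len(n), function(i) {
    cell_summary(curves[[i]], responsive[i], group[i], projection[i],
                 dsi_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
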