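cos_stack <- function(psi, f = 0.05, fr = 2, n_periods = 4) {
  nt <- round(n_periods * fr / f)
  tt <- (seq_len(nt) - 1) / fr
  d <- array(0, dim = c(2, 2, nt))
  for (k in seq_len(nt)) d[, , k] <- cos(2 * pi * f * tt[k] + psi)
  pixel_stack(d, fr, stim_freq_hz = f)
}

test_that("Fourier maps read out phase and amplitude at the stimulus bin", {
  fc0 <- fourier_component_map(cos_stack(0))
  expect_lt(max(abs(fc0$phase)), 1e-9)
  expect_equal(fc0$magnitude[1, 1], 1, tolerance = 1e-9)
  fc1 <- fourier_component_map(cos_stack(-pi / 2))
  expect_equal(fc1$phase[1, 1], -pi / 2, tolerance = 1e-9)
  # a second, distant component does not leak into the stimulus bin
  s <- cos_stack(0.3)
  tt <- (seq_len(dim(s$data)[3]) - 1) / s$frame_rate
  s$data <- s$data * 0.4 + rep(0.25 * cos(2 * pi * 0.5 * tt),
                               each = 4) + 1
  fc2 <- fourier_component_map(s, stim_freq = 0.05)
  expect_equal(fc2$magnitude[1, 1], 0.4, tolerance = 0.02)
  expect_equal(fc2$phase[1, 1], 0.3, tolerance = 1e-6)
  expect_error(fourier_component_map(cos_stack(0), stim_freq = 5), "Nyquist")
})

test_that("delay subtraction separates retinotopy from hemodynamic delay", {
  d <- matrix(0.4, 3, 3)
  out <- delay_corrected_retinotopy(d, d)
  expect_equal(out$phase, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(out$delay, d, tolerance = 1e-12)
  th <- matrix(seq(-3, 3, length.out = 9), 3, 3)
  out2 <- delay_corrected_retinotopy(th + 0.4, -th + 0.4)
  expect_equal(dsstream:::wrap_pi(out2$phase), dsstream:::wrap_pi(th),
               tolerance = 1e-9)
  expect_error(delay_corrected_retinotopy(d, matrix(0, 2, 2)), "grid")
})

test_that("phase converts linearly to visual degrees", {
  expect_equal(phase_to_degrees(0, 134.46), 0)
  expect_equal(phase_to_degrees(pi / 2, 134.46), 33.615)
  ramp <- matrix(seq(-pi, pi - 0.01, length.out = 50), 5, 10)
  deg <- phase_to_degrees(ramp, 100)
  expect_equal(range(deg), range(ramp) / (2 * pi) * 100)
  expect_error(phase_to_degrees(0, -1), "> 0")
})

test_that("visual-field sign is +1 for matched and -1 for mirrored maps", {
  az <- outer(rep(1, 20), 1:20)   # increases along x
  el <- outer(1:20, rep(1, 20))   # increases along y
  sm <- visual_field_sign(az, el, sigma_px = 0)
  inner <- sm$I[3:18, 3:18]
  expect_equal(inner, matrix(1, 16, 16), tolerance = 1e-9)
  smm <- visual_field_sign(-az, el, sigma_px = 0)
  expect_equal(smm$I[3:18, 3:18], matrix(-1, 16, 16), tolerance = 1e-9)
  expect_error(visual_field_sign(az, el[1:5, 1:5]), "grid")
})

test_that("sign-map thresholding keeps strong pixels and cleans specks", {
  I <- matrix(0.05, 40, 40)
  I[5:14, 5:14] <- 0.95       # 100 of 1600 pixels strong
  tc <- threshold_and_clean(I)
  expect_true(all(tc$mask[6:13, 6:13] == 1))
  expect_true(all(tc$mask[20:40, 20:40] == 0))
  # constant maps carry no structure
  expect_equal(sum(threshold_and_clean(matrix(0.5, 10, 10))$mask), 0)
  # an isolated strong pixel does not survive the 3x3 median filter
  I2 <- matrix(0.01, 20, 20); I2[10, 10] <- 1
  expect_equal(sum(threshold_and_clean(I2)$mask), 0)
})

test_that("neighbor filter keeps >4-neighbor pixels and fills gaps", {
  m <- matrix(0, 9, 9)
  m[3:7, 3:7] <- 1
  m[5, 5] <- 0            # interior hole
  m[1, 1] <- 1            # isolated pixel
  out <- neighbor_filter(m)
  expect_equal(out[5, 5], 1)   # hole filled (8 retained neighbors)
  expect_equal(out[4, 4], 1)   # interior pixel of a solid block kept
  expect_equal(out[1, 1], 0)   # isolated pixel removed
  # exactly 5 non-zero neighbors retains, 4 does not
  m5 <- matrix(0, 5, 5); m5[2, 2:4] <- 1; m5[3, c(2, 4)] <- 1; m5[3, 3] <- 1
  expect_equal(neighbor_filter(m5)[3, 3], 1)
  m4 <- m5; m4[3, 4] <- 0
  expect_equal(neighbor_filter(m4)[3, 3], 0)
})

test_that("border detection labels areas with sizes and centroids", {
  m <- matrix(0, 40, 40)
  m[11:20, 6:15] <- 1
  seg <- detect_borders(m, pixel_mm = 0.01)
  expect_equal(nrow(seg$areas), 1)
  expect_equal(seg$areas$area_mm2, 100 * 0.01^2)
  expect_equal(seg$areas$centroid_row, 15.5)
  expect_equal(seg$areas$centroid_col, 10.5)
  m[25:39, 21:35] <- 1
  seg2 <- detect_borders(m, pixel_mm = 0.01)
  expect_equal(nrow(seg2$areas), 2)
  expect_equal(seg2$areas$rel_row[2], 15.5 - 32)
  expect_equal(seg2$areas$rel_col[2], 10.5 - 28)
  # translation moves centroids by the shift and conserves sizes
  m1 <- matrix(0, 40, 40); m1[11:20, 6:15] <- 1
  m2t <- matrix(0, 40, 40); m2t[14:23, 9:18] <- 1
  s1 <- detect_borders(m1, pixel_mm = 0.01)
  s2 <- detect_borders(m2t, pixel_mm = 0.01)
  expect_equal(s2$areas$n_px, s1$areas$n_px)
  expect_equal(s2$areas$centroid_row, s1$areas$centroid_row + 3)
  expect_equal(s2$areas$centroid_col, s1$areas$centroid_col + 3)
  expect_error(detect_borders(matrix(0, 5, 5)), "empty")
})

test_that("areal strength is gain-invariant and tracks squared amplitude", {
  proto <- make_stimulus_protocol("isoi-grating", n_trials = 2)
  lay <- hva_layout_spec(dims = c(20, 20))
  lay$areas <- list(list(name = "A", rows = 3:8, cols = 3:8, sign = 1),
                    list(name = "B", rows = 12:17, cols = 12:17, sign = -1))
  stk <- synthesize_isoi_grating_stack(lay, proto,
                                       strengths = c(A = 0.03, B = 0))
  labs <- matrix(0L, 20, 20); labs[3:8, 3:8] <- 1L; labs[12:17, 12:17] <- 2L
  ar <- areal_response_strength(stk, labs)
  expect_lt(ar$strength[["2"]], 1e-20)   # silent area: noise floor
  stk2 <- stk; stk2$data <- stk$data * 7; attr(stk2, "pre_s") <- 10
  ar2 <- areal_response_strength(stk2, labs)
  expect_equal(ar2$strength[["1"]], ar$strength[["1"]], tolerance = 1e-9)
  expect_error(areal_response_strength(pixel_stack(stk$data, 6), labs),
               "pre-stimulus")
})

test_that("two mirrored areas give opposite signs and a clean round trip", {
  lay <- hva_layout_spec(dims = c(48, 48), pixel_mm = 0.02)
  lay$areas <- list(list(name = "V1", rows = 6:29, cols = 8:39, sign = +1),
                    list(name = "LM", rows = 36:45, cols = 14:33, sign = -1))
  proto <- make_stimulus_protocol("retinotopy-bar", n_sweeps = 2,
                                  sweep_extent_deg = c(134.46, 102.75))
  sim <- synthesize_retinotopy_stack(lay, proto, seed = 2, delay_s = 0.8)
  maps <- map_visual_areas(sim$stacks, sim$sweep_extent_deg,
                           pixel_mm = lay$pixel_mm)
  m <- sim$truth$mask
  expect_lt(mean(abs(maps$azimuth[m] - sim$truth$azimuth[m])), 2)
  expect_lt(mean(abs(maps$elevation[m] - sim$truth$elevation[m])), 2)
  expect_equal(nrow(maps$segmentation$areas), 2)
  # polarity recovered: mean sign inside each rectangle
  expect_gt(mean(maps$sign_map$I[6:29, 8:39]), 0.5)
  expect_lt(mean(maps$sign_map$I[36:45, 14:33]), -0.5)
})
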