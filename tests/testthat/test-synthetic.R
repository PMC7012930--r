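test_that("population sampling is deterministic and validates its spec", {
  spec <- cortical_population_spec("control", n = 50)
  a <- sample_population(spec, seed = 3)
  b <- sample_population(spec, seed = 3)
  c <- sample_population(spec, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$theta_true, c$theta_true))
  bad <- spec
  bad$classes[[1]]$weight <- 0.9
  expect_error(population_spec(10, bad$classes), "sum to 1")
  cl <- spec$classes
  cl[[1]]$kappa <- -1
  expect_error(population_spec(10, cl), "kappa")
})

test_that("a degenerate mixture puts every cell at the stated direction", {
  tr <- sample_population(fixed_population(20, theta = 0), seed = 1)
  expect_true(all(tr$theta_true == 0))
  expect_true(all(tr$dsi_true == 0.6))
})

test_that("empirical class fractions match the mixture weights", {
  spec <- population_spec(10000, classes = list(
    list(name = "posterior", weight = 0.48,
         theta = list(mu = 0, kappa = Inf), kappa = 4, dsi = 0.7,
         amp_meanlog = log(0.4), amp_sdlog = 0.2, tf_profile = c(1, 1),
         noise_sd = 0),
    list(name = "other", weight = 0.52,
         theta = list(mu = 0, kappa = 0), kappa = 4, dsi = 0.5,
         amp_meanlog = log(0.4), amp_sdlog = 0.2, tf_profile = c(1, 1),
         noise_sd = 0)), tfs = c(0.3, 1.2))
  tr <- sample_population(spec, seed = 5)
  frac <- mean(tr$class == "posterior")
  tol <- 3 * sqrt(0.48 * 0.52 / 10000)
  expect_lt(abs(frac - 0.48), tol)
  # marginal summaries agree across seeds within sampling error
  tr2 <- sample_population(spec, seed = 6)
  expect_lt(abs(mean(tr2$class == "posterior") - frac), 2 * tol)
})

test_that("noiseless tuning model recovers dsi_true in closed form", {
  for (d in c(0.2, 0.6, 1)) {
    tr <- sample_population(fixed_population(1, theta = 90, kappa = 3,
                                             dsi = d), seed = 1)
    rp <- expected_amplitude(tr, 90, 1.2)[1, 1]
    ro <- expected_amplitude(tr, 270, 1.2)[1, 1]
    expect_equal((rp - ro) / (rp + ro), d, tolerance = 1e-12)
  }
  # near-delta tuning: response vanishes away from the peak
  tr <- sample_population(fixed_population(1, theta = 90, kappa = 400,
                                           dsi = 1), seed = 1)
  amps <- expected_amplitude(tr, seq(0, 330, by = 30), 1.2)[1, ]
  expect_gt(amps[["90"]], 0.49)
  expect_lt(max(amps[setdiff(names(amps), c("90", "60", "120"))]), 1e-3)
})

test_that("trace synthesis is deterministic and rejects bad input", {
  p <- small_protocol()
  tr <- sample_population(fixed_population(2, noise_sd = 0.05), seed = 1)
  a <- synthesize_recording(tr, p, seed = 9)
  b <- synthesize_recording(tr, p, seed = 9)
  expect_identical(a$traces, b$traces)
  expect_true(all(is.finite(a$traces)))
  expect_error(synthesize_recording(tr[0, ], p), "empty")
  expect_error(synthesize_recording(tr, make_stimulus_protocol("flash-spot"),
                                    drift_periods_s = 100), "120")
})

test_that("a gain-zero cell carries only baseline, drift and noise", {
  p <- small_protocol()
  spec <- fixed_population(1, amp = 1, noise_sd = 0)
  tr <- sample_population(spec, seed = 1)
  tr$amp_0.3 <- 0
  tr$amp_1.2 <- 0
  rec <- synthesize_recording(tr, p, seed = 2, drift_amp = 0.02)
  expect_equal(rec$traces[, 1], rec$f0_true[, 1], tolerance = 1e-12)
  pr <- process_recording(rec)
  expect_false(pr$responsive[1])
})

test_that("pipeline amplitudes match the closed-form expectation at zero noise", {
  p <- small_protocol()
  tr <- sample_population(fixed_population(1, theta = 60, kappa = 4,
                                           dsi = 0.7), seed = 1)
  rec <- synthesize_recording(tr, p, seed = 3, drift_amp = 0.02)
  pr <- process_recording(rec, use_true_f0 = TRUE)
  att <- kernel_attack_factor(p)
  for (tf in p$tfs) {
    want <- expected_amplitude(tr, pr$curves[[1]]$directions, tf)[1, ] * att
    got <- pr$curves[[1]]$mean[, as.character(tf)]
    expect_lt(max(abs(got - want) / want), 0.01)
  }
})

test_that("flash recordings encode the ON-OFF balance", {
  p <- flash_spot_protocol(n_trials = 2)
  spec <- fixed_population(1, noise_sd = 0, tfs = c(0.3, 1.2))
  tr <- sample_population(spec, seed = 1)
  for (bal in c(-0.6, 0, 0.8)) {
    tr$onoff_balance <- bal
    rec <- synthesize_recording(tr, p, seed = 1, drift_amp = 0)
    dff <- compute_dff(rec$traces[, 1], rec$f0_true[, 1], rec$frame_rate)
    fl <- flash_peak_responses(dff, p)
    oo <- ooi_and_onoff(fl)
    # the ON decay tail bleeds slightly into the OFF window
    expect_equal(mean(oo$ooi), bal, tolerance = 0.1)
    expect_equal(oo$is_onoff, abs(bal) < 0.3)
  }
})

test_that("retinotopy stacks encode coordinates as on-bin phases", {
  lay <- hva_layout_spec(dims = c(48, 48))
  lay$areas <- list(list(name = "V1", rows = 5:40, cols = 5:40, sign = +1))
  proto <- make_stimulus_protocol("retinotopy-bar", n_sweeps = 2,
                                  sweep_extent_deg = c(134.46, 102.75))
  sim <- synthesize_retinotopy_stack(lay, proto, seed = 1, delay_s = 0.5)
  fc <- fourier_component_map(sim$stacks$azimuth_forward)
  m <- sim$truth$mask
  # phase is affine in the ground-truth coordinate (offset = delay phase)
  phd <- 2 * pi * sim$sweep_freq_hz[["azimuth"]] * 0.5
  want <- 2 * pi * sim$truth$azimuth[m] / sim$sweep_extent_deg[[1]] + phd
  expect_lt(max(abs(dsstream:::wrap_pi(fc$phase[m] - want))), 1e-9)
  # uniform coordinates give uniform phases
  lay$deg_per_px <- 0
  sim0 <- synthesize_retinotopy_stack(lay, proto, seed = 1)
  fc0 <- fourier_component_map(sim0$stacks$azimuth_forward)
  expect_lt(diff(range(fc0$phase[sim0$truth$mask])), 1e-9)
})

test_that("episodic grating stacks put their power at the 20-s period", {
  proto <- make_stimulus_protocol("isoi-grating", n_trials = 3)
  lay <- hva_layout_spec(dims = c(24, 24), pixel_mm = 0.02)
  lay$areas <- list(list(name = "V1", rows = 3:12, cols = 3:12, sign = 1),
                    list(name = "RL", rows = 16:22, cols = 16:22, sign = -1))
  stk <- synthesize_isoi_grating_stack(lay, proto,
                                       strengths = c(V1 = 0.04, RL = 0.02))
  expect_equal(stk$stim_freq_hz, 0.05)
  px <- stk$data[5, 5, ]
  pre_n <- round(attr(stk, "pre_s") * stk$frame_rate)
  sp <- Mod(fft(px[-seq_len(pre_n)] - mean(px[-seq_len(pre_n)])))
  nt <- length(px) - pre_n
  freqs <- (seq_len(nt) - 1) * stk$frame_rate / nt
  expect_equal(freqs[which.max(sp[2:(nt %/% 2)]) + 1L], 0.05,
               tolerance = 1e-6)
  # linearity: double strength, four-fold power
  labs <- matrix(0L, 24, 24); labs[3:12, 3:12] <- 1L; labs[16:22, 16:22] <- 2L
  ar <- areal_response_strength(stk, labs)
  expect_equal(unname(ar$strength["2"] / ar$strength["1"]), 0.25,
               tolerance = 1e-6)
  expect_error(synthesize_isoi_grating_stack(lay, proto,
                                             strengths = c(V1 = -1)), ">= 0")
})
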