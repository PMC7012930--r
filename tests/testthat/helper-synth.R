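# Shared fixture builders (all fixtures are generated in code).

# Tuning curve with given mean-amplitude matrix (directions x TFs);
# trials are exact replicates unless a trial array is supplied.
make_curve <- function(mean_amps, directions, tfs, n_trials = 1,
                       cell_id = "c1") {
  m <- matrix(mean_amps, length(directions), length(tfs))
  trials <- array(rep(m, n_trials),
                  dim = c(length(directions), length(tfs), n_trials))
  dsstream:::new_tuning_curve(cell_id, directions, tfs, trials)
}

# Curve over the 12-direction grid with a single TF column.
curve12 <- function(amps, tf = 1.2, ...) {
  make_curve(amps, directions = seq(0, 330, by = 30), tfs = tf, ...)
}

# Noiseless curve sampled from the generator's closed-form tuning model.
truth_curve <- function(theta, kappa, dsi_true, amp = 0.5,
                        directions = seq(0, 330, by = 30),
                        tfs = c(0.3, 0.75, 1.2, 1.8)) {
  spec <- population_spec(1, classes = list(list(
    name = "x", weight = 1, theta = list(mu = theta, kappa = Inf),
    kappa = kappa, dsi = dsi_true, amp_meanlog = log(amp), amp_sdlog = 0,
    tf_profile = rep(1, length(tfs)), noise_sd = 0)), tfs = tfs)
  tr <- sample_population(spec, seed = 1)
  m <- vapply(tfs, function(tf) expected_amplitude(tr, directions, tf)[1, ],
              numeric(length(directions)))
  make_curve(m, directions, tfs)
}

# Small drifting-grating protocol for fast trace-level tests.
small_protocol <- function(tfs = c(0.3, 1.2), n_trials = 2, ...) {
  make_stimulus_protocol("drifting-grating", tfs = tfs,
                         n_trials = n_trials, ...)
}

# Single-class population spec with fixed parameters.
fixed_population <- function(n, theta = 90, kappa = 4, dsi = 0.6,
                             amp = 0.5, tf_profile = c(1, 1.5),
                             noise_sd = 0, tfs = c(0.3, 1.2),
                             theta_kappa = Inf) {
  population_spec(n, classes = list(list(
    name = "x", weight = 1, theta = list(mu = theta, kappa = theta_kappa),
    kappa = kappa, dsi = dsi, amp_meanlog = log(amp), amp_sdlog = 0,
    tf_profile = tf_profile, noise_sd = noise_sd)), tfs = tfs)
}

circ_err <- function(a, b) abs(((a - b + 180) %% 360) - 180)
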