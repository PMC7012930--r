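#' Describe a synthetic neural population
#'
#' A population specification is a mixture over cell classes. Each class
#' sets the distribution of preferred direction (a von Mises component or
#' uniform), tuning sharpness `kappa`, direction-selectivity `dsi`,
#' response amplitude, and a temporal-frequency gain profile. Classes with
#' an increasing TF profile and a posterior-concentrated direction
#' distribution emulate the cells whose amplitude grows with TF while
#' their tuning converges on posterior motion.
#'
#' @param n number of cells.
#' @param classes list of class descriptions; each a list with fields
#'   `name`, `weight`, `theta` (`list(mu=, kappa=)`, `kappa = Inf` for a
#'   point mass, `kappa = 0` for uniform), `kappa` (range, von Mises
#'   concentration of the tuning curve), `dsi` (range in \[0, 1\]),
#'   `amp_meanlog`/`amp_sdlog` (log-normal peak dF/F0 amplitude at the
#'   preferred TF), `tf_profile` (per-TF multiplicative gain),
#'   `tf_direction_coupling` (scalar; extra high-TF gain proportional to
#'   the cosine similarity of the cell's preferred direction with
#'   posterior), `noise_sd`, and optionally `onoff_balance` (range).
#' @param group group label attached to every cell (e.g. `"control"`).
#' @param tfs temporal frequencies the gain profile refers to.
#' @param baseline_f baseline fluorescence in arbitrary units; traces and
#'   noise are expressed relative to it.
#' @return An object of class `population_spec`.
#' @seealso [sample_population()], [cortical_population_spec()]
#' @export
population_spec <- function(n, classes, group = "control",
                            tfs = c(0.3, 0.75, 1.2, 1.8), baseline_f = 1) {
  stopifnot(n >= 1, length(classes) >= 1)
  w <- vapply(classes, function(cl) cl$weight, numeric(1))
  if (any(w < 0)) stop("class weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8) {
    stop("class weights must sum to 1", call. = FALSE)
  }
  for (cl in classes) {
    if (!is.null(cl$kappa) && any(cl$kappa < 0)) {
      stop("'kappa' must be >= 0", call. = FALSE)
    }
    if (!is.null(cl$noise_sd) && cl$noise_sd < 0) {
      stop("'noise_sd' must be >= 0", call. = FALSE)
    }
    if (length(cl$tf_profile) != length(tfs)) {
      stop("each class needs one 'tf_profile' gain per TF", call. = FALSE)
    }
    if (any(cl$tf_profile <= 0)) {
      stop("'tf_profile' gains must be > 0", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), classes = classes, group = group,
                 tfs = tfs, baseline_f = baseline_f),
            class = "population_spec")
}

#' Preset populations for the cortical genotype comparison
#'
#' Two-class mixtures representing the study conditions. The
#' `"posterior-highTF"` class prefers posterior motion (0 deg, von Mises
#' spread), has high DSI and a TF gain profile rising from 0.3 to 1.8 Hz
#' (amplitude ratio at 1.2 vs 0.3 Hz around 2). The `"generic"` class has
#' uniformly distributed preferred directions, mixed DSI, and a falling TF
#' profile (low-TF preference). The control population carries 45% of its
#' mass in the posterior-highTF class; the mutant population (disrupted
#' retinal horizontal direction selectivity) carries 20%, the only
#' difference between the two.
#'
#' @param group `"control"` or `"mutant"`.
#' @param n number of cells (default 1000).
#' @param noise_sd trial-to-trial response variability (dF/F0 units).
#' @return A `population_spec`.
#' @export
cortical_population_spec <- function(group = c("control", "mutant"),
                                     n = 1000, noise_sd = 0.05) {
  group <- match.arg(group)
  w_post <- if (group == "control") 0.45 else 0.20
  classes <- list(
    list(name = "posterior-highTF", weight = w_post,
         theta = list(mu = 0, kappa = 8),
         kappa = c(2, 6), dsi = c(0.45, 0.9),
         amp_meanlog = log(0.35), amp_sdlog = 0.35,
         tf_profile = c(0.55, 0.8, 1.15, 1.3),
         tf_direction_coupling = 0, noise_sd = noise_sd),
    list(name = "generic", weight = 1 - w_post,
         theta = list(mu = 0, kappa = 0),
         kappa = c(2, 6), dsi = c(0.2, 0.8),
         amp_meanlog = log(0.35), amp_sdlog = 0.35,
         tf_profile = c(1.3, 1.15, 0.8, 0.55),
         tf_direction_coupling = 0, noise_sd = noise_sd)
  )
  population_spec(n, classes, group = group)
}

#' Draw a ground-truth cell population
#'
#' Cells are drawn i.i.d. from the mixture in `spec`; the draw is a
#' deterministic function of `seed`. Empirical class fractions converge to
#' the specified weights as `n` grows.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return A data frame of class `tuning_truth`, one row per cell:
#'   `cell_id`, `group`, `projection`, `class`, `theta_true` (deg),
#'   `kappa`, `dsi_true`, `baseline_f`, `noise_sd`,
#'   `tf_direction_coupling`, `onoff_balance`, and one `amp_<tf>` column
#'   per TF (expected peak dF/F0 amplitude at the preferred direction).
#' @export
sample_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  with_seed(seed, {
    ki <- sample.int(length(spec$classes), n, replace = TRUE,
                     prob = vapply(spec$classes, `[[`, numeric(1), "weight"))
    draw_range <- function(r, m) {
      if (length(r) == 1L) rep(r, m) else stats::runif(m, r[1], r[2])
    }
    out <- lapply(seq_along(spec$classes), function(j) {
      m <- sum(ki == j)
      if (m == 0L) return(NULL)
      cl <- spec$classes[[j]]
      theta <- rvonmises(m, cl$theta$mu, cl$theta$kappa)
      kappa <- draw_range(cl$kappa, m)
      dsi <- draw_range(cl$dsi, m)
      amp <- stats::rlnorm(m, cl$amp_meanlog, cl$amp_sdlog)
      coup <- if (is.null(cl$tf_direction_coupling)) 0 else
        cl$tf_direction_coupling
      bal <- if (is.null(cl$onoff_balance)) rep(0, m) else
        draw_range(cl$onoff_balance, m)
      df <- data.frame(class = cl$name, theta_true = theta, kappa = kappa,
                       dsi_true = dsi, amp_base = amp,
                       tf_direction_coupling = coup, onoff_balance = bal,
                       proj = if (is.null(cl$projection)) "unspecific" else
                         cl$projection)
      df
    })
    # reassemble rows in the original draw order of ki
    counters <- integer(length(spec$classes))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      j <- ki[i]
      counters[j] <- counters[j] + 1L
      rows[[i]] <- out[[j]][counters[j], , drop = FALSE]
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    J <- length(spec$tfs)
    gv <- vapply(seq_len(n), function(i) {
      cl <- spec$classes[[ki[i]]]
      prof <- cl$tf_profile
      coup <- truth$tf_direction_coupling[i]
      if (coup != 0) {
        boost <- 1 + coup * cos(deg2rad(truth$theta_true[i])) *
          (seq_len(J) - 1) / (J - 1)
        prof <- prof * pmax(boost, 0.05)
      }
      truth$amp_base[i] * prof
    }, numeric(J))
    gains <- if (is.matrix(gv)) t(gv) else matrix(gv, ncol = 1L)
    colnames(gains) <- paste0("amp_", spec$tfs)
    res <- cbind(
      data.frame(cell_id = sprintf("cell%04d", seq_len(n)),
                 group = spec$group, projection = truth$proj,
                 class = truth$class,
                 theta_true = wrap_deg(truth$theta_true),
                 kappa = truth$kappa, dsi_true = truth$dsi_true,
                 amp_base = truth$amp_base,
                 baseline_f = spec$baseline_f, noise_sd = vapply(
                   ki, function(j) spec$classes[[j]]$noise_sd, numeric(1)),
                 tf_direction_coupling = truth$tf_direction_coupling,
                 onoff_balance = truth$onoff_balance),
      gains)
    attr(res, "tfs") <- spec$tfs
    class(res) <- c("tuning_truth", "data.frame")
    res
  })
}

#' Von Mises random angles in degrees
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` gives uniform angles,
#' `kappa = Inf` a point mass at `mu`.
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (!is.finite(kappa)) return(rep(wrap_deg(mu), n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_deg(mu + rad2deg(theta))
}

#' Noiseless expected response amplitude of a synthetic cell
#'
#' The tuning model is a baseline-plus-von-Mises curve normalized so that
#' the direction-selectivity index of the noiseless curve equals
#' `dsi_true` exactly: with `b = (1 - dsi) / (1 + dsi)`,
#' `R(d, tf) = A_tf * (b + (1 - b) * vm(d))` where `vm` is the von Mises
#' density rescaled to \[0, 1\] with its peak at `theta_true`, and `A_tf`
#' is the cell's `amp_<tf>` gain.
#'
#' @param truth a `tuning_truth` data frame (or a single row of one).
#' @param direction stimulus direction(s) in degrees.
#' @param tf a single temporal frequency present in the truth table.
#' @return matrix of expected dF/F0 amplitudes, cells x directions.
#' @export
expected_amplitude <- function(truth, direction, tf) {
  amp_col <- paste0("amp_", tf)
  if (!amp_col %in% names(truth)) {
    stop("TF ", tf, " not present in truth table", call. = FALSE)
  }
  A <- truth[[amp_col]]
  shape <- tuning_shape(outer(rep(1, nrow(truth)), direction),
                        truth$theta_true, truth$kappa, truth$dsi_true)
  out <- A * shape
  dimnames(out) <- list(truth$cell_id, as.character(direction))
  out
}

# Normalized tuning shape in [b, 1]; rows follow theta/kappa/dsi recycling.
tuning_shape <- function(direction, theta, kappa, dsi) {
  b <- (1 - dsi) / (1 + dsi)
  dd <- cos(deg2rad(direction - theta))
  # (exp(kappa (cos-1)) - exp(-2 kappa)) / (1 - exp(-2 kappa)), stable form
  num <- exp(kappa * (dd - 1)) - exp(-2 * kappa)
  den <- 1 - exp(-2 * kappa)
  vm <- num / ifelse(den > 0, den, 1)
  flat <- den == 0  # kappa = 0: untuned, shape is constant at its peak
  if (any(flat)) {
    if (is.matrix(vm)) vm[flat, ] <- 1 else vm[flat] <- 1
  }
  b + (1 - b) * vm
}

#' Sample trial-resolved tuning curves directly from ground truth
#'
#' Bypasses trace synthesis: each trial amplitude is the closed-form
#' expected amplitude plus independent Gaussian trial noise of standard
#' deviation `noise_sd` (floored at zero). This is the generative model of
#' trial-to-trial variability used for parameter-recovery and
#' population-level benchmarks, where the quantity of interest is the
#' amplitude sample, not the frame-level trace.
#'
#' @param truth a `tuning_truth` table.
#' @param protocol a drifting-grating `stim_protocol`.
#' @param seed integer seed.
#' @return list of [tuning_curve][build_tuning_curve] objects, one per cell.
#' @export
sample_tuning_curves <- function(truth, protocol, seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"),
            protocol$kind == "drifting-grating")
  dirs <- protocol$directions
  tfs <- protocol$tfs
  nt <- protocol$n_trials
  with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      row <- truth[i, , drop = FALSE]
      mu <- vapply(tfs, function(tf) expected_amplitude(row, dirs, tf)[1, ],
                   numeric(length(dirs)))
      trials <- array(pmax(0, rep(mu, nt) +
                             stats::rnorm(length(mu) * nt, 0, row$noise_sd)),
                      dim = c(length(dirs), length(tfs), nt))
      new_tuning_curve(row$cell_id, dirs, tfs, trials)
    })
  })
}
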