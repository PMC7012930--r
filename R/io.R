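#' Default run configuration
#'
#' Collects the analysis constants in one place: the 0.06 dF/F0
#' responsiveness gate, the 0.3 DSI and ON-OFF gates, the 8x8 grid, the
#' 0.05 significance level, the protocol parameters, and the
#' synthetic-population settings used by [run_pipeline()].
#'
#' @return named list of defaults (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    responsiveness_threshold = 0.06,
    dsi_threshold = 0.3,
    ooi_threshold = 0.3,
    grid_n = 8L,
    alpha = 0.05,
    target_rate = 15.4,
    tau_s = 0.6,
    n_cells_per_group = 1000L,
    noise_sd = 0.05,
    posterior_fraction_control = 0.45,
    posterior_fraction_mutant = 0.20,
    directions = seq(0, 330, by = 30),
    tfs = c(0.3, 0.75, 1.2, 1.8),
    n_trials = 6L,
    drift_s = 3,
    gray_s = 3,
    frame_rate = 30.9,
    run_isoi = FALSE,
    isoi_pixel_mm = 0.02,
    sweep_extent_deg = c(134.46, 102.75),
    sweep_speed_deg_per_s = 9
  ), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Absent keys fall back to [default_config()]; unknown keys are
#' rejected; thresholds must be positive.
#'
#' @param path path to a JSON file (an empty object gives all defaults).
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                   error = function(e) {
                     stop("malformed config: ", conditionMessage(e),
                          call. = FALSE)
                   })
  cfg <- default_config()
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("responsiveness_threshold", "dsi_threshold", "ooi_threshold",
           "grid_n", "alpha", "target_rate", "tau_s", "frame_rate",
           "n_cells_per_group", "drift_s", "gray_s")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0)) {
      stop("config key '", k, "' must be positive", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      !is.finite(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config key 'seed' must be an integer", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$grid_n <- as.integer(cfg$grid_n)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 12),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Write pipeline results to disk
#'
#' Emits deterministic CSV tables (`cell_summary.csv`,
#' `grid_classes.csv`, and `area_table.csv` when present), a `log.txt`
#' with per-stage counts, and a `manifest.json` with the configuration,
#' its hash and the package version.
#'
#' @param results a [run_pipeline()] result (or compatible list with
#'   `summary`, `grid_comparison`, optional `segmentation`, `counts`,
#'   `config`).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(results$summary)) {
    f <- file.path(out_dir, "cell_summary.csv")
    utils::write.csv(results$summary, f, row.names = FALSE)
    files <- c(files, "cell_summary.csv")
  }
  if (!is.null(results$grid_comparison)) {
    f <- file.path(out_dir, "grid_classes.csv")
    utils::write.csv(results$grid_comparison$grids, f, row.names = FALSE)
    files <- c(files, "grid_classes.csv")
  }
  if (!is.null(results$segmentation)) {
    f <- file.path(out_dir, "area_table.csv")
    utils::write.csv(results$segmentation$areas, f, row.names = FALSE)
    files <- c(files, "area_table.csv")
  }
  log_lines <- c(sprintf("stage counts:"),
                 vapply(names(results$counts), function(k) {
                   sprintf("  %s: %d", k, results$counts[[k]])
                 }, character(1)))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  manifest <- list(package = "dsstream",
                   version = as.character(utils::packageVersion("dsstream")),
                   config = unclass(results$config),
                   config_hash = config_hash(results$config),
                   files = files,
                   counts = results$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12)
  invisible(manifest)
}

#' Run the simulate-process-analyze pipeline
#'
#' Samples a control and a mutant population (differing only in the
#' fraction of posterior-preferring high-TF cells), draws trial-resolved
#' tuning curves, computes per-cell summaries, and runs the PCA / grid
#' comparison. Per-stage counts (cells generated, responsive, DS, grids
#' by class) are logged and returned; `DS <= responsive <= generated`
#' always holds.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @param out_dir optional output directory; when given,
#'   [write_report()] is called.
#' @return list with `summary`, `response_matrix`, `pca`, `assignment`,
#'   `grid_comparison`, `counts`, `config`, and (with `run_isoi`)
#'   `segmentation`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  protocol <- make_stimulus_protocol(
    "drifting-grating", directions = config$directions, tfs = config$tfs,
    n_trials = config$n_trials, drift_s = config$drift_s,
    gray_s = config$gray_s, frame_rate = config$frame_rate,
    order_seed = config$seed)
  groups <- list(control = cortical_population_spec(
                   "control", config$n_cells_per_group, config$noise_sd),
                 mutant = cortical_population_spec(
                   "mutant", config$n_cells_per_group, config$noise_sd))
  groups$control$classes[[1]]$weight <- config$posterior_fraction_control
  groups$control$classes[[2]]$weight <- 1 - config$posterior_fraction_control
  groups$mutant$classes[[1]]$weight <- config$posterior_fraction_mutant
  groups$mutant$classes[[2]]$weight <- 1 - config$posterior_fraction_mutant
  summaries <- list()
  for (g in names(groups)) {
    truth <- sample_population(groups[[g]],
                               seed = config$seed + match(g, names(groups)))
    curves <- sample_tuning_curves(truth, protocol,
                                   seed = config$seed + 10L +
                                     match(g, names(groups)))
    responsive <- vapply(curves, function(cv) {
      classify_responsive(cv, "cortical",
                          config$responsiveness_threshold)$responsive
    }, logical(1))
    summaries[[g]] <- summarize_cells(curves, responsive, group = g,
                                      dsi_threshold = config$dsi_threshold)
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  summary$cell_id <- paste(summary$group, summary$cell_id, sep = "_")
  message("generated: ", nrow(summary), "; responsive: ",
          sum(summary$responsive), "; DS: ", sum(summary$is_ds))
  rm_ <- build_response_matrix(summary, tfs = config$tfs)
  pca <- embed_pca(rm_)
  assignment <- segment_grid(pca$embedding, n = config$grid_n)
  gc_ <- classify_grids(assignment,
                        factor(rm_$meta$group,
                               levels = c("control", "mutant")),
                        alpha = config$alpha)
  counts <- list(generated = nrow(summary),
                 responsive = sum(summary$responsive),
                 ds = sum(summary$is_ds),
                 grids_decreased = sum(gc_$grids$class == "decreased"),
                 grids_increased = sum(gc_$grids$class == "increased"))
  message("grids decreased/increased: ", counts$grids_decreased, "/",
          counts$grids_increased)
  results <- list(summary = summary, response_matrix = rm_, pca = pca,
                  assignment = assignment, grid_comparison = gc_,
                  counts = counts, config = config)
  if (isTRUE(config$run_isoi)) {
    proto_r <- make_stimulus_protocol(
      "retinotopy-bar", sweep_extent_deg = config$sweep_extent_deg,
      sweep_speed_deg_per_s = config$sweep_speed_deg_per_s, n_sweeps = 3)
    sim <- synthesize_retinotopy_stack(hva_layout_spec(), proto_r,
                                       seed = config$seed)
    maps <- map_visual_areas(sim$stacks, sim$sweep_extent_deg,
                             pixel_mm = config$isoi_pixel_mm)
    results$segmentation <- maps$segmentation
    results$counts$areas <- nrow(maps$segmentation$areas)
  }
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}

#' Write and read a synthetic recording as CSV + JSON
#'
#' `traces.csv` holds one column per ROI (wide format, one row per
#' frame); `events.csv` the event table; `sidecar.json` the frame rate,
#' protocol parameters and ground truth.
#'
#' @param rec a `synthetic_recording`.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rec$traces),
                   file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(rec$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  side <- list(frame_rate = rec$frame_rate,
               kind = rec$protocol$kind,
               drift_s = rec$protocol$drift_s,
               gray_s = rec$protocol$gray_s,
               truth = as.data.frame(rec$truth))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(dir)
}

#' @rdname write_recording
#' @param protocol the `stim_protocol` the recording was generated with
#'   (the sidecar stores only its scalar parameters).
#' @export
read_recording <- function(dir, protocol = NULL) {
  traces <- as.matrix(utils::read.csv(file.path(dir, "traces.csv")))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  side <- jsonlite::fromJSON(file.path(dir, "sidecar.json"))
  structure(list(traces = traces, frame_rate = side$frame_rate,
                 events = events, truth = side$truth,
                 protocol = protocol),
            class = "synthetic_recording")
}

#' Write and read a pixel stack as multi-page TIFF + JSON sidecar
#'
#' Frames are stored as 32-bit float pages scaled to \[0, 1\]; the
#' sidecar records the scaling, the frame rate, and the stimulus
#' frequency so the round trip is lossless to float precision.
#'
#' @param stack a `pixel_stack`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- stack$data
  lo <- min(d); hi <- max(d)
  scl <- if (hi > lo) (d - lo) / (hi - lo) else d * 0
  pages <- lapply(seq_len(dim(d)[3]), function(k) scl[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(lo = lo, hi = hi,
                            frame_rate = stack$frame_rate,
                            stim_freq_hz = stack$stim_freq_hz,
                            pre_s = attr(stack, "pre_s")),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 12)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  d <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (side$hi > side$lo) d <- d * (side$hi - side$lo) + side$lo
  out <- pixel_stack(d, side$frame_rate, stim_freq_hz = side$stim_freq_hz)
  if (!is.null(side$pre_s)) attr(out, "pre_s") <- side$pre_s
  out
}
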