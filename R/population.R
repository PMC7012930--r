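#' Response matrix for population decomposition
#'
#' Assembles the n_cells x 8 matrix consumed by the PCA/grid analysis:
#' the peak dF/F0 amplitude at each of the four TFs followed by the DSI
#' at each TF, one row per DS cell, rows sorted by preferred TF and then
#' cell id. Rows keep their group (genotype) and projection labels.
#'
#' @param summary a [summarize_cells()] data frame restricted or
#'   restrictable to DS cells; must contain at least two distinct groups.
#' @param tfs the temporal frequencies expected in the summary columns.
#' @param ds_only drop rows with `is_ds == FALSE` first (default TRUE).
#' @return object of class `response_matrix`: list with `matrix`
#'   (numeric, 2 * length(tfs) columns) and `meta` (cell_id, group,
#'   projection, preferred_tf per row).
#' @export
build_response_matrix <- function(summary, tfs = c(0.3, 0.75, 1.2, 1.8),
                                  ds_only = TRUE) {
  if (ds_only) summary <- summary[summary$is_ds, , drop = FALSE]
  if (nrow(summary) == 0L) stop("no DS cells", call. = FALSE)
  if (length(unique(summary$group)) < 2L) {
    stop("need at least two groups in the response matrix", call. = FALSE)
  }
  amp_cols <- paste0("amp_", tfs)
  dsi_cols <- paste0("dsi_", tfs)
  miss <- setdiff(c(amp_cols, dsi_cols), names(summary))
  if (length(miss)) {
    stop("missing TF condition columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(summary$preferred_tf, summary$cell_id)
  summary <- summary[ord, , drop = FALSE]
  m <- as.matrix(summary[, c(amp_cols, dsi_cols)])
  rownames(m) <- summary$cell_id
  structure(list(matrix = m,
                 meta = summary[, c("cell_id", "group", "projection",
                                    "preferred_tf")],
                 tfs = tfs),
            class = "response_matrix")
}

#' Two-dimensional PCA embedding of a response matrix
#'
#' Columns are standardized (zero mean, unit variance) before projection
#' because amplitudes and DSI values live on different scales, then
#' projected onto the top two principal components. Zero-variance
#' columns are dropped with a warning. For reproducibility each
#' component's sign is fixed so that the loading of the highest-TF
#' amplitude column (or the first non-zero loading if that one
#' vanishes) is non-negative.
#'
#' @param rm a [build_response_matrix()] result (or plain numeric matrix).
#' @return list with `embedding` (n x 2, columns PC1/PC2), `loadings`,
#'   `explained` (proportion of variance per component, all components),
#'   and `meta` (when available).
#' @export
embed_pca <- function(rm) {
  m <- if (inherits(rm, "response_matrix")) rm$matrix else as.matrix(rm)
  if (nrow(m) < 3L) stop("need at least 3 cells for PCA", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ref_col <- grep("^amp_", colnames(z), value = TRUE)
  ref_idx <- if (length(ref_col)) {
    match(ref_col[length(ref_col)], colnames(z))
  } else ncol(z)
  for (j in 1:2) {
    ld <- pc$rotation[, j]
    key <- ld[[ref_idx]]
    if (abs(key) < 1e-12) key <- ld[which(abs(ld) > 1e-12)[1]]
    if (key < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(embedding = pc$x[, 1:2, drop = FALSE],
       loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       meta = if (inherits(rm, "response_matrix")) rm$meta else NULL)
}

#' Grid segmentation of a 2-D embedding
#'
#' Splits the bounding box of the pooled (all groups) embedding into an
#' `n x n` grid of equal cells. Bins are half-open; points on the top or
#' right boundary fall in the last bin, so every cell receives exactly
#' one grid.
#'
#' @param embedding n x 2 numeric matrix.
#' @param n grids per axis (default 8).
#' @return object of class `grid_assignment`: list with `grid` (integer
#'   vector of linear grid ids, column-major `(gx - 1) * n + gy`), `gx`,
#'   `gy` (1-based bin indices), `edges_x`, `edges_y`, `n`.
#' @export
segment_grid <- function(embedding, n = 8) {
  emb <- as.matrix(embedding)
  stop_if_not_finite(emb, "embedding")
  rx <- range(emb[, 1]); ry <- range(emb[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("degenerate bounding box (zero extent)", call. = FALSE)
  }
  ex <- seq(rx[1], rx[2], length.out = n + 1)
  ey <- seq(ry[1], ry[2], length.out = n + 1)
  gx <- findInterval(emb[, 1], ex, rightmost.closed = TRUE)
  gy <- findInterval(emb[, 2], ey, rightmost.closed = TRUE)
  structure(list(grid = (gx - 1L) * n + gy, gx = gx, gy = gy,
                 edges_x = ex, edges_y = ey, n = n),
            class = "grid_assignment")
}

#' Per-group grid occupancy fractions
#'
#' The fraction of each group's cells falling in each grid; fractions
#' sum to 1 per group.
#'
#' @param assignment a [segment_grid()] result.
#' @param groups group label per cell.
#' @return list with `counts` and `fractions` (each an n^2 x n_groups
#'   matrix, rows = linear grid ids) and `totals` per group.
#' @export
grid_fraction_maps <- function(assignment, groups) {
  stopifnot(inherits(assignment, "grid_assignment"))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  n2 <- assignment$n^2
  cnt <- table(factor(assignment$grid, levels = seq_len(n2)), groups)
  cnt <- matrix(as.integer(cnt), n2, nlevels(groups),
                dimnames = list(NULL, levels(groups)))
  tot <- colSums(cnt)
  list(counts = cnt, fractions = sweep(cnt, 2, tot, "/"), totals = tot)
}

#' Classify grids by genotype fraction change
#'
#' For every grid a 2x2 contingency table (in-grid vs out-of-grid by
#' group) is tested with a two-sided Yates-corrected chi-square test.
#' A grid is `"decreased"` when p < alpha and the second group's
#' fraction is below the first's, `"increased"` when above, and
#' `"unchanged"` otherwise (including grids empty in both groups, whose
#' p is undefined). No multiple-testing correction is applied by
#' default; `p_adjust = "fdr"` switches the gate to BH-adjusted
#' p-values.
#'
#' @param assignment a [segment_grid()] result.
#' @param groups group label per cell; must have exactly 2 levels, the
#'   first level is the reference (e.g. control).
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return object of class `grid_comparison`: data frame `grids` with
#'   per-grid counts, fractions, chi-square statistic, p-value, class and
#'   mutation index, plus `n`, `groups`, `alpha`.
#' @export
classify_grids <- function(assignment, groups, alpha = 0.05,
                           p_adjust = "none") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("grid classification needs exactly 2 groups", call. = FALSE)
  }
  fm <- grid_fraction_maps(assignment, groups)
  a <- fm$counts[, 1]; b <- fm$counts[, 2]
  na <- fm$totals[1]; nb <- fm$totals[2]
  stat <- p <- rep(NA_real_, length(a))
  for (i in seq_along(a)) {
    if (a[i] + b[i] == 0L) next
    tab <- matrix(c(a[i], na - a[i], b[i], nb - b[i]), 2, 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    stat[i] <- unname(ct$statistic)
    p[i] <- ct$p.value
  }
  p_gate <- if (p_adjust == "none") p else stats::p.adjust(p, p_adjust)
  f1 <- fm$fractions[, 1]; f2 <- fm$fractions[, 2]
  cls <- rep("unchanged", length(a))
  sig <- !is.na(p_gate) & p_gate < alpha
  cls[sig & f2 < f1] <- "decreased"
  cls[sig & f2 > f1] <- "increased"
  grids <- data.frame(grid = seq_along(a),
                      gx = (seq_along(a) - 1L) %/% assignment$n + 1L,
                      gy = (seq_along(a) - 1L) %% assignment$n + 1L,
                      count_1 = a, count_2 = b,
                      fraction_1 = f1, fraction_2 = f2,
                      chisq = stat, p = p, class = cls,
                      mi = mutation_index(f1, f2))
  names(grids)[names(grids) == "count_1"] <-
    paste0("count_", levels(groups)[1])
  names(grids)[names(grids) == "count_2"] <-
    paste0("count_", levels(groups)[2])
  names(grids)[names(grids) == "fraction_1"] <-
    paste0("fraction_", levels(groups)[1])
  names(grids)[names(grids) == "fraction_2"] <-
    paste0("fraction_", levels(groups)[2])
  structure(list(grids = grids, n = assignment$n,
                 groups = levels(groups), alpha = alpha),
            class = "grid_comparison")
}

#' @export
print.grid_comparison <- function(x, ...) {
  tb <- table(x$grids$class)
  cat("<grid_comparison>", x$n, "x", x$n, "grids;",
      x$groups[1], "vs", x$groups[2], "\n")
  cat("  decreased:", tb["decreased"] %||% 0,
      " increased:", tb["increased"] %||% 0,
      " unchanged:", tb["unchanged"] %||% 0, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Mutation index
#'
#' Normalized difference of per-grid fractions between the reference
#' (control) and the comparison (mutant) population:
#' `MI = (F_control - F_mutant) / (F_control + F_mutant)`. Positive MI
#' means the grid's fraction is decreased in the mutant. 0/0 yields 0.
#'
#' @param f_control,f_mutant non-negative fractions (vectorized).
#' @return values in \[-1, 1\].
#' @export
mutation_index <- function(f_control, f_mutant) {
  if (any(f_control < 0) || any(f_mutant < 0)) {
    stop("fractions must be >= 0", call. = FALSE)
  }
  s <- f_control + f_mutant
  ifelse(s == 0, 0, (f_control - f_mutant) / s)
}

#' Projection target index
#'
#' `PTI = (F_RLp - F_PMp) / (F_RLp + F_PMp)` comparing the per-grid
#' fractions of RL-projecting and PM-projecting cells; positive values
#' mark grids enriched in RL-projecting cells. 0/0 yields 0.
#'
#' @param f_rlp,f_pmp non-negative fractions (vectorized).
#' @return values in \[-1, 1\].
#' @export
projection_target_index <- function(f_rlp, f_pmp) {
  if (any(f_rlp < 0) || any(f_pmp < 0)) {
    stop("fractions must be >= 0", call. = FALSE)
  }
  s <- f_rlp + f_pmp
  ifelse(s == 0, 0, (f_rlp - f_pmp) / s)
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Computes the mean resultant length `r`, the Rayleigh statistic
#' `z = n * r^2`, and the p-value with the standard small-sample
#' correction used in circular-statistics toolboxes:
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * r`.
#' Optional non-negative weights give the weighted resultant with
#' `n = sum(weights)`.
#'
#' @param theta_deg angles in degrees.
#' @param weights optional non-negative weights.
#' @return list with `z`, `p.value`, `r` (mean resultant length),
#'   `mean_direction` (degrees), `n`.
#' @export
rayleigh_test <- function(theta_deg, weights = NULL) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (length(theta_deg) < 2L) stop("need n >= 2 angles", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  rad <- deg2rad(theta_deg)
  cx <- sum(weights * cos(rad))
  sx <- sum(weights * sin(rad))
  n <- sum(weights)
  r <- sqrt(cx^2 + sx^2) / n
  R <- n * r
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(z = z, p.value = min(1, p), r = r,
       mean_direction = wrap_deg(rad2deg(atan2(sx, cx))), n = n)
}

#' Compare two preferred-direction distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on directions linearized
#' to \[0, 360) with the cut at 0 degrees (posterior).
#'
#' @param thetas_a,thetas_b angles in degrees.
#' @return list with `statistic` (D) and `p.value`.
#' @export
compare_direction_distributions <- function(thetas_a, thetas_b) {
  thetas_a <- thetas_a[!is.na(thetas_a)]
  thetas_b <- thetas_b[!is.na(thetas_b)]
  if (!length(thetas_a) || !length(thetas_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(wrap_deg(thetas_a),
                                        wrap_deg(thetas_b)))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Two-group scalar comparison
#'
#' Delegates to the two-sided Mann-Whitney U test (unpaired) or the
#' Wilcoxon signed-rank test (paired).
#'
#' @param values_a,values_b numeric samples; equal lengths when paired.
#' @param paired logical.
#' @return list with `statistic` and `p.value`.
#' @export
group_scalar_tests <- function(values_a, values_b, paired = FALSE) {
  if (paired) {
    if (length(values_a) != length(values_b)) {
      stop("paired samples must have equal length", call. = FALSE)
    }
    if (all(values_a == values_b)) {
      stop("all paired differences are zero", call. = FALSE)
    }
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            paired = paired,
                                            alternative = "two.sided",
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}
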