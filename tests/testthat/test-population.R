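make_summary <- function(n_per_group = 20, seed = 1) {
  p <- cortical_grating_protocol()
  out <- lapply(c("control", "mutant"), function(g) {
    tr <- sample_population(cortical_population_spec(g, n_per_group),
                            seed = seed + match(g, c("control", "mutant")))
    cv <- sample_tuning_curves(tr, p, seed = seed + 10)
    summarize_cells(cv, responsive = TRUE, group = g)
  })
  s <- do.call(rbind, out)
  s$cell_id <- paste(s$group, s$cell_id, sep = "_")
  s
}

test_that("response matrix has 8 ordered columns and sorted rows", {
  s <- make_summary(10)
  rm_ <- build_response_matrix(s)
  expect_equal(ncol(rm_$matrix), 8)
  expect_equal(colnames(rm_$matrix),
               c("amp_0.3", "amp_0.75", "amp_1.2", "amp_1.8",
                 "dsi_0.3", "dsi_0.75", "dsi_1.2", "dsi_1.8"))
  expect_true(!is.unsorted(rm_$meta$preferred_tf))
  expect_true(all(s$is_ds[match(rm_$meta$cell_id, s$cell_id)]))
  one <- s[s$group == "control", ]
  expect_error(build_response_matrix(one), "two groups")
})

test_that("PCA embedding is standardized, sign-fixed and deterministic", {
  s <- make_summary(25)
  rm_ <- build_response_matrix(s)
  pc <- embed_pca(rm_)
  expect_equal(dim(pc$embedding), c(nrow(rm_$matrix), 2))
  expect_gte(pc$loadings["amp_1.8", 1], 0)
  expect_gte(pc$loadings["amp_1.8", 2], 0)
  # duplicating every row leaves the embedding unchanged up to the
  # sample-SD rescaling of the standardization step
  m2 <- rbind(rm_$matrix, rm_$matrix)
  pc2 <- embed_pca(m2)
  unitize <- function(e) sweep(e, 2, apply(e, 2, sd), "/")
  expect_equal(unitize(pc2$embedding[seq_len(nrow(rm_$matrix)), ]),
               unitize(pc$embedding), tolerance = 1e-6,
               ignore_attr = TRUE)
  # collinear data: one component carries all the variance
  line <- cbind(1:40, 2 * (1:40) + 3)
  pcl <- embed_pca(line)
  expect_equal(pcl$explained[1], 1, tolerance = 1e-12)
  # isotropic cloud: eigenvalues of the covariance are ~equal
  set.seed(5)
  iso <- matrix(rnorm(4000), ncol = 2)
  pci <- embed_pca(iso)
  expect_lt(abs(pci$explained[1] - 0.5), 0.05)
  withz <- cbind(rm_$matrix, dead = 0)
  expect_warning(embed_pca(withz), "zero-variance")
})

test_that("grid segmentation bins the pooled bounding box half-open", {
  emb <- rbind(c(0, 0), c(1, 1), c(0.999, 0.5), c(0.5, 0.13))
  g <- segment_grid(emb, n = 8)
  expect_equal(c(g$gx[1], g$gy[1]), c(1, 1))
  expect_equal(c(g$gx[2], g$gy[2]), c(8, 8))  # max falls in the last bin
  expect_equal(g$gx[3], 8)
  expect_equal(g$gy[4], 2)  # 0.13 in [1/8, 2/8)
  expect_error(segment_grid(cbind(rep(1, 4), 1:4)), "degenerate")
  # uniform points occupy grids near-uniformly (multinomial check)
  set.seed(6)
  u <- cbind(runif(6400), runif(6400))
  gu <- segment_grid(u, n = 8)
  cnt <- tabulate(gu$grid, nbins = 64)
  expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
})

test_that("grid fractions sum to one per group and flag empty groups", {
  set.seed(7)
  emb <- cbind(runif(200), runif(200))
  g <- segment_grid(emb, 8)
  grp <- rep(c("control", "mutant"), each = 100)
  fm <- grid_fraction_maps(g, grp)
  expect_equal(unname(colSums(fm$fractions)), c(1, 1))
  expect_error(grid_fraction_maps(g, factor(grp, levels =
                                              c("control", "mutant", "x"))),
               "empty")
})

test_that("grid classification applies the Yates-corrected chi-square", {
  # one grid holding 10/30 control and 20/30 mutant cells: the 2x2 table
  # [[10,20],[20,10]] has Yates chi-square 5.4, p < 0.05
  emb <- rbind(matrix(0.05, 10, 2), matrix(0.95, 20, 2),
               matrix(0.05, 20, 2), matrix(0.95, 10, 2))
  grp <- rep(c("control", "mutant"), each = 30)
  g <- segment_grid(emb, n = 2)
  gc_ <- classify_grids(g, grp)
  occupied <- gc_$grids[gc_$grids$count_control + gc_$grids$count_mutant > 0, ]
  expect_equal(occupied$chisq, c(5.4, 5.4), tolerance = 1e-9)
  expect_true(all(occupied$p < 0.05))
  expect_setequal(occupied$class, c("increased", "decreased"))
  # the grid where the mutant fraction is lower is the decreased one
  expect_equal(occupied$class[occupied$fraction_mutant <
                                occupied$fraction_control], "decreased")
  # empty grids stay unchanged with undefined p
  empty <- gc_$grids[gc_$grids$count_control + gc_$grids$count_mutant == 0, ]
  expect_true(all(empty$class == "unchanged"))
  expect_true(all(is.na(empty$p)))
  # identical distributions: nothing is significant
  gc2 <- classify_grids(g, rep(c("control", "mutant"), 30))
  expect_true(all(gc2$grids$class == "unchanged"))
})

test_that("mutation and projection-target indices follow their formulas", {
  expect_equal(mutation_index(0.10, 0.05), 1 / 3, tolerance = 1e-9)
  expect_equal(mutation_index(0.2, 0.2), 0)
  expect_equal(mutation_index(0.2, 0), 1)
  expect_equal(mutation_index(0, 0), 0)
  expect_error(mutation_index(-0.1, 0.2), ">= 0")
  expect_equal(projection_target_index(0.6, 0.2), 0.5)
  expect_equal(projection_target_index(0.3, 0.3), 0)
  expect_equal(projection_target_index(0, 0.3), -1)
  # swapping the groups negates both indices
  set.seed(8)
  f1 <- runif(20); f2 <- runif(20)
  expect_equal(mutation_index(f1, f2), -mutation_index(f2, f1))
  expect_equal(projection_target_index(f1, f2),
               -projection_target_index(f2, f1))
})

test_that("Rayleigh test detects concentration and respects uniformity", {
  r1 <- rayleigh_test(rep(77, 20))
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p.value, 1e-3)
  r2 <- rayleigh_test(seq(0, 330, by = 30))
  expect_lt(r2$r, 1e-12)
  expect_gt(r2$p.value, 0.99)
  set.seed(9)
  vm <- rvonmises(1000, 180, 1)
  expect_lt(rayleigh_test(vm)$p.value, 1e-3)
  expect_lt(circ_err(rayleigh_test(vm)$mean_direction, 180), 10)
  expect_error(rayleigh_test(45), "n >= 2")
  # weights: doubling every weight must not change r
  th <- c(10, 50, 200, 340)
  expect_equal(rayleigh_test(th, rep(2, 4))$r, rayleigh_test(th)$r)
})

test_that("direction-distribution and scalar group tests behave", {
  set.seed(10)
  a <- runif(500, 0, 360)
  cd <- compare_direction_distributions(a, a)
  expect_equal(cd$statistic, 0)
  disj <- compare_direction_distributions(runif(50, 0, 100),
                                          runif(50, 200, 300))
  expect_equal(disj$statistic, 1)
  same <- compare_direction_distributions(runif(500, 0, 360),
                                          runif(500, 0, 360))
  expect_gt(same$p.value, 0.05)
  expect_error(compare_direction_distributions(a, numeric(0)), "non-empty")
  x <- rnorm(100); y <- rnorm(100) + 3
  expect_lt(group_scalar_tests(x, y)$p.value, 1e-3)
  expect_gt(group_scalar_tests(x, x + rnorm(100, 0, 1e-6),
                               paired = FALSE)$p.value, 0.5)
  expect_lt(group_scalar_tests(x, x + abs(rnorm(100)) + 0.1,
                               paired = TRUE)$p.value, 1e-3)
  expect_error(group_scalar_tests(x, x, paired = TRUE), "zero")
})
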