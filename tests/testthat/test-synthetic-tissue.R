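small_cfg <- function(seed = 5, ...) {
  simulation_config(
    list(cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 1.0)),
    xy_pixel_um = 0.25, field_shape = c(40L, 160L, 160L),
    n_cells_per_fov = 6L, background_spot_density = 0,
    autofluor_spot_density = 0, n_fovs_per_group = 1L, seed = seed, ...)
}

test_that("noise-free single-type tissue is pure signal with one label per nucleus", {
  tis <- generate_tissue(small_cfg())
  f <- tis[[1]]
  expect_true(all(f$truth_spots$origin == "signal"))
  labs <- setdiff(unique(as.vector(f$mask$volume)), 0L)
  expect_setequal(labs, f$truth_cells$cell)
  expect_equal(length(labs), 6L)
  # every signal spot lies inside its generating cell's sphere
  for (i in seq_len(nrow(f$spots))) {
    cid <- f$truth_spots$cell[i]
    d <- sqrt(sum((as.numeric(f$spots[i, c("z_um", "y_um", "x_um")]) -
                     as.numeric(f$truth_cells[cid, c("z_um", "y_um", "x_um")]))^2))
    expect_lte(d, f$truth_cells$cell_radius_um[cid] + 1e-9)
  }
})

test_that("identical config and seed give bit-identical tissues", {
  t1 <- generate_tissue(small_cfg(seed = 17))
  t2 <- generate_tissue(small_cfg(seed = 17))
  expect_identical(t1[[1]]$spots, t2[[1]]$spots)
  expect_identical(t1[[1]]$mask$volume, t2[[1]]$mask$volume)
  expect_identical(t1[[1]]$truth_cells, t2[[1]]$truth_cells)
  t3 <- generate_tissue(small_cfg(seed = 18))
  expect_false(identical(t1[[1]]$spots, t3[[1]]$spots))
})

test_that("empirical cell-type frequencies converge to configured proportions", {
  cfg <- simulation_config(
    list(cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 0.3,
                        mean_spots_per_cell = 5),
         cell_type_spec("AM", "Chil3", "Cy5", proportion = 0.2,
                        mean_spots_per_cell = 5)),
    xy_pixel_um = 0.3, field_shape = c(54L, 300L, 300L),
    n_cells_per_fov = 60L, n_fovs_per_group = 10L,
    background_spot_density = 0, autofluor_spot_density = 0, seed = 4)
  tis <- generate_tissue(cfg)
  types <- unlist(lapply(tis, function(f) f$truth_cells$type))
  n <- length(types)
  props <- c(AT2 = 0.3, AM = 0.2)
  for (nm in names(props)) {
    p <- props[[nm]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(types == nm) - p), 3 * se + 1e-12)
  }
})

test_that("rasterized nucleus volumes match the analytic sphere within 5%", {
  tis <- generate_tissue(small_cfg(seed = 9))
  f <- tis[[1]]
  vs <- f$mask$voxel_size
  voxel_vol <- prod(vs)
  for (i in f$truth_cells$cell) {
    nvox <- sum(f$mask$volume == i)
    analytic <- 4 / 3 * pi * f$truth_cells$nucleus_radius_um[i]^3
    expect_lt(abs(nvox * voxel_vol - analytic) / analytic, 0.05)
  }
})

test_that("autofluorescent pairs appear in two channels within the jitter", {
  cfg <- simulation_config(
    list(cell_type_spec("A", "g1", "Cy3", proportion = 0.2,
                        mean_spots_per_cell = 5),
         cell_type_spec("B", "g2", "Cy5", proportion = 0.2,
                        mean_spots_per_cell = 5)),
    xy_pixel_um = 0.3, field_shape = c(30L, 150L, 150L),
    n_cells_per_fov = 8L, background_spot_density = 0,
    autofluor_spot_density = 2e-3, autofluor_jitter_um = 0, seed = 21)
  f <- generate_tissue(cfg)[[1]]
  af <- which(f$truth_spots$origin == "autofluor")
  expect_gt(length(af), 0)
  for (p in unique(f$truth_spots$pair[af])) {
    rows <- af[f$truth_spots$pair[af] == p]
    expect_equal(length(unique(f$spots$channel[rows])), 2L)
    # jitter 0: coordinates identical across the two channels
    xyz <- as.matrix(f$spots[rows, c("z_um", "y_um", "x_um")])
    expect_equal(max(dist(xyz)), 0)
  }
})

test_that("impossible placement density raises an explicit error", {
  cfg <- simulation_config(
    list(cell_type_spec("A", "g1", "Cy3", proportion = 1,
                        cell_radius_um = 3, nucleus_radius_um = 1)),
    xy_pixel_um = 0.3, field_shape = c(30L, 40L, 40L),
    n_cells_per_fov = 50L, background_spot_density = 0,
    autofluor_spot_density = 0, seed = 1)
  expect_error(generate_tissue(cfg), "density")
})

test_that("group effects modify proportions, volumes and spot counts", {
  cfg <- small_cfg(seed = 30)
  tis <- generate_tissue(cfg, group_effects = list(
    A = list(), B = list(volume_scale = 2)))
  va <- tis[[1]]$truth_cells$true_volume_um3[1]
  vb <- tis[[2]]$truth_cells$true_volume_um3[1]
  expect_equal(vb / va, 2, tolerance = 1e-9)
  expect_error(generate_tissue(cfg, group_effects = list(A = list(bogus = 1))),
               "unknown group effect")
})

test_that("expression generator plants the signature effect reproducibly", {
  g0 <- generate_expression_matrix(100, 200, 20, effect_size = 1, seed = 3)
  s0 <- score_cells(g0$matrix, g0$signature_genes)
  d0 <- mean(s0$score[g0$class == "high"]) - mean(s0$score[g0$class == "low"])
  expect_lt(abs(d0), 0.1)   # null effect: classes exchangeable

  g4 <- generate_expression_matrix(100, 500, 50, effect_size = 4, seed = 3)
  s4 <- score_cells(g4$matrix, g4$signature_genes)
  expect_gt(mean(s4$score[g4$class == "high"]), mean(s4$score[g4$class == "low"]))

  expect_identical(generate_expression_matrix(10, 5, 2, 2, seed = 8)$matrix,
                   generate_expression_matrix(10, 5, 2, 2, seed = 8)$matrix)
  expect_error(generate_expression_matrix(10, 5, 2, effect_size = 0), "effect_size")
  expect_error(generate_expression_matrix(10, 5, c("nope"), 2), "signature gene")
})

test_that("probe pools carry their constructed rule violations", {
  bad <- generate_probe_pool(20, violate = "AAAA", seed = 2)
  expect_true(all(grepl("AAAA", bad, fixed = TRUE)))
  good <- generate_probe_pool(20, length_range = c(26, 32), seed = 2)
  for (s in good) expect_true(all(oracle_probe_flags(s)))
  expect_length(generate_probe_pool(0), 0)
  expect_error(generate_probe_pool(5, length_range = c(5, 9)), "length_range")
})
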