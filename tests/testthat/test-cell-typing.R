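unit_cube <- as.matrix(expand.grid(z = 0:1, y = 0:1, x = 0:1))
unit_tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("hull volumes of analytic solids are exact", {
  expect_identical(build_hull(unit_cube)$volume_um3, 1)
  expect_identical(build_hull(unit_tetra)$volume_um3, 1 / 6)
  # interior points do not change the hull
  cube_plus <- rbind(unit_cube, c(0.5, 0.5, 0.5), c(0.2, 0.7, 0.3))
  expect_equal(build_hull(cube_plus)$volume_um3, 1, tolerance = 1e-12)
})

test_that("degenerate point clouds are flagged with zero volume", {
  flat <- cbind(0, matrix(runif(20), 10, 2))        # coplanar
  h <- build_hull(flat)
  expect_true(h$degenerate)
  expect_identical(h$volume_um3, 0)
  line <- cbind(1:5, 1:5, 1:5)                       # collinear
  expect_true(build_hull(line)$degenerate)
  expect_error(build_hull(unit_tetra[1:3, ]), "at least 4")
})

test_that("hull volume of random clouds matches a rejection-sampling estimate", {
  set.seed(21)
  u <- matrix(rnorm(150 * 3), 150, 3)
  X <- u / sqrt(rowSums(u^2)) * runif(150)^(1 / 3) * 3   # ball radius 3
  h <- build_hull(X)
  hs <- oracle_hull_halfspaces(X)
  M <- 40000
  box_lo <- apply(X, 2, min); box_hi <- apply(X, 2, max)
  P <- cbind(runif(M, box_lo[1], box_hi[1]), runif(M, box_lo[2], box_hi[2]),
             runif(M, box_lo[3], box_hi[3]))
  f <- mean(oracle_points_in_hull(hs, P))
  box_vol <- prod(box_hi - box_lo)
  mc <- f * box_vol
  se <- box_vol * sqrt(f * (1 - f) / M)
  expect_lt(abs(h$volume_um3 - mc), 3 * se)
})

test_that("point-in-hull membership matches the brute-force facet oracle", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(runif(3 * 25, 0, 4), 25, 3)
    h <- build_hull(X)
    hs <- oracle_hull_halfspaces(X)
    P <- matrix(runif(3 * 500, -0.5, 4.5), 500, 3)
    expect_equal(points_in_hull(h, P), oracle_points_in_hull(hs, P))
  }
})

make_mask <- function(center, radius, shape = c(30L, 60L, 60L),
                      vs = c(0.3, 0.2, 0.2), label = 1L) {
  vol <- array(0L, shape)
  idx <- which(outer(outer(((seq_len(shape[1]) - 0.5) * vs[1] - center[1])^2,
                           ((seq_len(shape[2]) - 0.5) * vs[2] - center[2])^2, `+`),
                     ((seq_len(shape[3]) - 0.5) * vs[3] - center[3])^2, `+`)
               <= radius^2)
  vol[idx] <- label
  nucleus_label_map(vol, vs, "f")
}

test_that("overlap fraction is 1 for containment and 0 for disjoint hulls", {
  mask <- make_mask(c(4, 5, 5), 1.2)
  # big hull around the nucleus
  big <- build_hull(rbind(c(0, 0, 0), c(9, 0, 0), c(0, 12, 0), c(0, 0, 12),
                          c(9, 12, 0), c(9, 0, 12), c(0, 12, 12), c(9, 12, 12)))
  ov <- hull_nucleus_overlap(big, mask)
  expect_equal(unname(ov["1"]), 1)
  far <- build_hull(unit_cube + 50)
  expect_equal(unname(hull_nucleus_overlap(far, mask)["1"]), 0)
  # empty mask: empty result
  empty <- nucleus_label_map(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_length(hull_nucleus_overlap(big, empty), 0)
})

test_that("overlap fractions agree with the independent facet oracle", {
  set.seed(31)
  for (i in 1:6) {
    center <- c(runif(1, 2, 6), runif(1, 3, 9), runif(1, 3, 9))
    mask <- make_mask(center, runif(1, 0.8, 1.6))
    X <- sweep(matrix(rnorm(3 * 30, 0, 2), 30, 3), 2,
               center + runif(3, -1, 1), `+`)
    X <- pmax(X, 0.01)
    h <- build_hull(X)
    ov <- hull_nucleus_overlap(h, mask)
    hs <- oracle_hull_halfspaces(X)
    cc <- fishcall:::nucleus_voxel_centers(mask)[["1"]]
    expect_equal(unname(ov["1"]), mean(oracle_points_in_hull(hs, cc)),
                 tolerance = 1e-12)
  }
})

test_that("hull assignment honors the per-type threshold K", {
  h <- build_hull(unit_cube); h$gene <- "Lamp3"
  K <- c(AT2 = 0.20)
  mm <- c(Lamp3 = "AT2")
  low <- assign_hulls(list(h), list(c(`7` = 0.10)), K, mm)[[1]]
  expect_equal(low$status, "removed")
  expect_length(low$assigned_nuclei, 0)
  full <- assign_hulls(list(h), list(c(`7` = 1.0)), K, mm)[[1]]
  expect_equal(full$status, "assigned")
  expect_equal(full$assigned_nuclei, 7L)
  two <- assign_hulls(list(h), list(c(`1` = 0.6, `2` = 0.3)),
                      c(AT2 = 0.25), mm)[[1]]
  expect_setequal(two$assigned_nuclei, c(1L, 2L))
  # exactly K qualifies ("at least an overlap of K%")
  edge <- assign_hulls(list(h), list(c(`3` = 0.20)), K, mm)[[1]]
  expect_equal(edge$status, "assigned")
  expect_error(assign_hulls(list(h), list(c(`1` = 1)), c(Other = 0.2), mm),
               "K configured")
})

fake_hull <- function(gene, nuclei, volume, degenerate = FALSE) {
  h <- build_hull(unit_cube); h$gene <- gene
  h$volume_um3 <- volume; h$degenerate <- degenerate
  h$assigned_nuclei <- nuclei
  h$status <- if (length(nuclei)) "assigned" else "removed"
  h
}

test_that("cell-type calls count each nucleus once with correct proportions", {
  mm <- c(Lamp3 = "AT2", Chil3 = "AM")
  hulls <- list(fake_hull("Lamp3", 1:5, 500))
  calls <- call_cell_types(hulls, 1:20, mm)
  expect_equal(calls$n_nuclei, 20L)
  s <- calls$summary
  expect_equal(s$proportion[s$gene == "Lamp3"], 0.25)
  expect_equal(s$proportion[s$gene == "Chil3"], 0)
  expect_equal(nrow(calls$cells), 20L)

  # co-positive nucleus counted in both numerators and as co-expressing
  hulls2 <- list(fake_hull("Lamp3", 3L, 400), fake_hull("Chil3", 3L, 600))
  calls2 <- call_cell_types(hulls2, 1:10, mm)
  s2 <- calls2$summary
  expect_equal(s2$positive[s2$gene == "Lamp3"], 1L)
  expect_equal(s2$positive[s2$gene == "Chil3"], 1L)
  expect_equal(calls2$n_coexpressing, 1L)
  expect_equal(calls2$cells$types[3], "AT2,AM")

  # no hulls at all: proportions 0 with full denominator
  calls3 <- call_cell_types(list(), 1:7, mm)
  expect_true(all(calls3$summary$proportion == 0))
  expect_equal(calls3$summary$total_nuclei, c(7L, 7L))
})

test_that("cell volume is the hull volume averaged over assigned nuclei", {
  one <- fake_hull("Lamp3", 5L, 900)
  expect_equal(estimate_cell_volume(one), c(`5` = 900))
  two <- fake_hull("Lamp3", c(5L, 9L), 900)
  expect_equal(estimate_cell_volume(two), c(`5` = 450, `9` = 450))
  degen <- fake_hull("Lamp3", 5L, 0, degenerate = TRUE)
  expect_length(estimate_cell_volume(degen), 0)
  # volumes of several same-gene hulls claiming one nucleus are summed
  calls <- call_cell_types(list(fake_hull("Lamp3", 1L, 300),
                                fake_hull("Lamp3", 1L, 200)),
                           1:2, c(Lamp3 = "AT2"))
  expect_equal(calls$cells$volume_Lamp3_um3[1], 500)
})

test_that("raising K never increases the positive-nucleus count", {
  set.seed(13)
  mm <- c(Lamp3 = "AT2")
  hulls <- lapply(1:6, function(i) {
    h <- build_hull(matrix(runif(3 * 10), 10, 3)); h$gene <- "Lamp3"; h
  })
  overlaps <- lapply(1:6, function(i)
    setNames(runif(4), as.character(sample(1:12, 4))))
  counts <- vapply(seq(0, 1, by = 0.1), function(k) {
    a <- assign_hulls(hulls, overlaps, c(AT2 = k), mm)
    calls <- call_cell_types(a, 1:12, mm)
    as.integer(calls$summary$positive[1])
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})
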