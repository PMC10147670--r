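#' Generate synthetic tissue fields of view with known ground truth
#'
#' Simulates one or more experimental groups of 3D smFISH fields of view under
#' a [simulation_config()]. Each field contains non-overlapping spherical
#' cells with concentric spherical nuclei; nuclei are rasterized into a 3D
#' labeled mask, marker spots are drawn as Poisson counts uniformly in each
#' cell's cytoplasmic shell (cell sphere minus nucleus sphere), background
#' spots follow a homogeneous Poisson process over the field, and
#' autofluorescent particles are duplicated into two distinct channels with
#' isotropic Gaussian jitter. Ground truth (per-nucleus type and volume,
#' per-spot origin) is returned alongside.
#'
#' @param config A [simulation_config()].
#' @param group_effects Named list of per-group overrides; names are group
#'   labels, values are lists with optional elements `proportion` (named
#'   vector of replacement per-type proportions), `volume_scale`
#'   (multiplicative factor on cell volume) and `spots_scale` (factor on mean
#'   spots per cell). `list(NI = list())` simulates a single unmodified group.
#' @return A list of class `"synthetic_tissue"`: one element per field of
#'   view, each a list with components `fov` (id), `group`, `mask`
#'   (a [nucleus_label_map()]), `spots` (a `spot_table`), `truth_cells`
#'   (data frame: `cell`, `type`, `z_um`, `y_um`, `x_um`,
#'   `cell_radius_um`, `nucleus_radius_um`, `true_volume_um3`) and
#'   `truth_spots` (data frame aligned with `spots`: `origin` in
#'   signal/background/autofluor, `cell`, `pair`).
#' @export
#' @examples
#' cfg <- simulation_config(
#'   cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 0.3),
#'   xy_pixel_um = 0.2, field_shape = c(20, 80, 80),
#'   n_cells_per_fov = 8, n_fovs_per_group = 1, seed = 7)
#' tis <- generate_tissue(cfg, group_effects = list(NI = list()))
#' tis[[1]]$truth_cells$type
generate_tissue <- function(config, group_effects = list(NI = list())) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(names(group_effects)) || any(!nzchar(names(group_effects))))
    stop_fmt("group_effects must be a named list (one element per group)")
  groups <- names(group_effects)
  n_total <- length(groups) * config$n_fovs_per_group
  seeds <- derive_seeds(config$seed, n_total)
  out <- vector("list", n_total)
  k <- 0L
  for (g in groups) {
    gcfg <- apply_group_effects(config, group_effects[[g]])
    for (i in seq_len(config$n_fovs_per_group)) {
      k <- k + 1L
      fov_id <- sprintf("%s_f%02d", g, i)
      out[[k]] <- with_seed(seeds[k], generate_fov(gcfg, fov_id))
      out[[k]]$group <- g
    }
  }
  structure(out, class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("synthetic_tissue: %d fields of view (groups: %s)\n", length(x),
              paste(unique(vapply(x, `[[`, "", "group")), collapse = ", ")))
  ns <- vapply(x, function(f) nrow(f$spots), 0L)
  nc <- vapply(x, function(f) nrow(f$truth_cells), 0L)
  cat(sprintf("  spots/fov: %s   cells/fov: %s\n",
              paste(range(ns), collapse = "-"), paste(range(nc), collapse = "-")))
  invisible(x)
}

# One field of view under the active RNG state.
generate_fov <- function(config, fov_id, max_tries = 2000L) {
  ext <- config$field_shape * config$voxel_size        # physical extent, um
  cts <- config$cell_types
  n <- config$n_cells_per_fov

  # assign types (remainder of the proportion budget = marker-negative cells)
  props <- vapply(cts, `[[`, 0, "proportion")
  type_pool <- c(names(cts), ".negative")
  types <- sample(type_pool, n, replace = TRUE, prob = c(props, 1 - sum(props)))

  neg_cell_r <- mean(vapply(cts, `[[`, 0, "cell_radius_um"))
  neg_nuc_r <- mean(vapply(cts, `[[`, 0, "nucleus_radius_um"))
  cell_r <- vapply(types, function(t) if (t == ".negative") neg_cell_r
                   else cts[[t]]$cell_radius_um, 0)
  nuc_r <- vapply(types, function(t) if (t == ".negative") neg_nuc_r
                  else cts[[t]]$nucleus_radius_um, 0)

  if (any(2 * max(cell_r) > ext))
    stop_fmt("field extent (%.1f x %.1f x %.1f um) cannot contain a cell of radius %.1f um",
             ext[1], ext[2], ext[3], max(cell_r))

  centers <- place_spheres(n, cell_r, ext, max_tries = max_tries)

  truth_cells <- data.frame(
    cell = seq_len(n), type = types,
    z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
    cell_radius_um = cell_r, nucleus_radius_um = nuc_r,
    true_volume_um3 = 4 / 3 * pi * cell_r^3,
    stringsAsFactors = FALSE)

  mask <- rasterize_nuclei(centers, nuc_r, config$field_shape,
                           config$voxel_size, fov_id)

  # spot accumulators (single data.frame assembly at the end)
  acc_xyz <- list(); acc_gene <- list(); acc_chan <- list()
  acc_origin <- list(); acc_cell <- list(); acc_pair <- list()
  push <- function(xyz, gene, chan, origin, cell, pair) {
    k <- length(acc_xyz) + 1L
    m <- nrow(xyz)
    acc_xyz[[k]] <<- xyz
    acc_gene[[k]] <<- rep_len(gene, m)
    acc_chan[[k]] <<- rep_len(chan, m)
    acc_origin[[k]] <<- rep_len(origin, m)
    acc_cell[[k]] <<- rep_len(as.integer(cell), m)
    acc_pair[[k]] <<- rep_len(as.integer(pair), m)
  }

  # marker spots: Poisson count per positive cell, uniform in the shell
  for (i in seq_len(n)) {
    t <- types[i]
    if (t == ".negative") next
    ct <- cts[[t]]
    m <- rpois(1L, ct$mean_spots_per_cell)
    if (m == 0L) next
    pts <- runif_shell(m, centers[i, ], nuc_r[i], cell_r[i])
    push(pts, ct$marker_gene, ct$channel, "signal", i, NA)
  }

  vol <- prod(ext)
  genes <- unname(vapply(cts, `[[`, "", "marker_gene"))
  chans <- unname(vapply(cts, `[[`, "", "channel"))

  # uniform background false detections, independently per gene
  if (config$background_spot_density > 0) {
    for (j in seq_along(genes)) {
      m <- rpois(1L, config$background_spot_density * vol)
      if (m == 0L) next
      pts <- cbind(runif(m, 0, ext[1]), runif(m, 0, ext[2]), runif(m, 0, ext[3]))
      push(pts, genes[j], chans[j], "background", NA, NA)
    }
  }

  # autofluorescent particles, detected in two distinct channels
  if (config$autofluor_spot_density > 0) {
    m <- rpois(1L, config$autofluor_spot_density * vol)
    if (m > 0L) {
      base <- cbind(runif(m, 0, ext[1]), runif(m, 0, ext[2]), runif(m, 0, ext[3]))
      uchan <- unique(chans)
      for (p in seq_len(m)) {
        two <- sample(uchan, 2L)
        for (ci in seq_along(two)) {
          pos <- base[p, ]
          if (ci > 1L && config$autofluor_jitter_um > 0) {
            pos <- pos + rnorm(3L, 0, config$autofluor_jitter_um)
            pos <- pmin(pmax(pos, 0), ext)   # keep inside the field
          }
          gene_in_chan <- genes[chans == two[ci]]
          g <- if (length(gene_in_chan) > 1L) sample(gene_in_chan, 1L) else gene_in_chan
          push(matrix(pos, 1L), g, two[ci], "autofluor", NA, p)
        }
      }
    }
  }

  if (length(acc_xyz)) {
    xyz <- do.call(rbind, acc_xyz)
    spots <- data.frame(fov = fov_id, gene = unlist(acc_gene),
                        channel = unlist(acc_chan),
                        z_um = xyz[, 1], y_um = xyz[, 2], x_um = xyz[, 3],
                        stringsAsFactors = FALSE)
    truth_spots <- data.frame(origin = unlist(acc_origin),
                              cell = unlist(acc_cell), pair = unlist(acc_pair),
                              stringsAsFactors = FALSE)
  } else {
    spots <- data.frame(fov = character(), gene = character(),
                        channel = character(), z_um = numeric(),
                        y_um = numeric(), x_um = numeric())
    truth_spots <- data.frame(origin = character(), cell = integer(),
                              pair = integer())
  }
  rownames(spots) <- rownames(truth_spots) <- NULL

  list(fov = fov_id, group = NA_character_,
       mask = mask, spots = as_spot_table(spots),
       truth_cells = truth_cells, truth_spots = truth_spots)
}

# Rejection-sample n non-overlapping spheres of radius r inside the box `ext`,
# each kept fully inside the field. Returns an n x 3 matrix (z, y, x) in um.
place_spheres <- function(n, r, ext, max_tries = 2000L) {
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, r[i], ext[1] - r[i]),
             runif(1, r[i], ext[2] - r[i]),
             runif(1, r[i], ext[3] - r[i]))
      if (i == 1L) { centers[i, ] <- p; placed <- TRUE; break }
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
      if (all(d2 > (r[seq_len(i - 1L)] + r[i])^2)) {
        centers[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_fmt("could not place cell %d of %d after %d tries; cell density too high for the field",
               i, n, max_tries)
  }
  centers
}

# m points uniform in the spherical shell r_in < r <= r_out around `center`.
runif_shell <- function(m, center, r_in, r_out) {
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (runif(m) * (r_out^3 - r_in^3) + r_in^3)^(1 / 3)
  sweep(u * r, 2, center, `+`)
}

# Paint spherical nuclei into an integer (z,y,x) array; label i = cell i.
# A voxel belongs to a nucleus when its center lies inside the sphere.
rasterize_nuclei <- function(centers, radii, field_shape, voxel_size, fov_id) {
  vol <- array(0L, dim = field_shape)
  for (i in seq_len(nrow(centers))) {
    idx <- nucleus_voxel_indices(centers[i, ], radii[i], field_shape, voxel_size)
    if (nrow(idx)) vol[idx] <- i
  }
  # construction guarantees the invariants; skip the O(n) validation scans
  structure(list(volume = vol,
                 voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
                 fov = as.character(fov_id)),
            class = "nucleus_label_map")
}

# Integer voxel indices (1-based, (z,y,x)) whose centers fall inside a sphere.
nucleus_voxel_indices <- function(center, radius, field_shape, voxel_size) {
  lo <- pmax(1L, floor((center - radius) / voxel_size) + 1L)
  hi <- pmin(field_shape, ceiling((center + radius) / voxel_size))
  if (any(lo > hi)) return(matrix(integer(), 0, 3))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  cz <- (g[, 1] - 0.5) * voxel_size[1]
  cy <- (g[, 2] - 0.5) * voxel_size[2]
  cx <- (g[, 3] - 0.5) * voxel_size[3]
  keep <- (cz - center[1])^2 + (cy - center[2])^2 + (cx - center[3])^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Collapse a 3D label map to independent per-plane 2D labels
#'
#' Emulates plane-by-plane 2D nucleus segmentation: every (z-plane, nucleus)
#' occurrence receives its own label, so a nucleus spanning k planes becomes k
#' distinct 2D labels.
#'
#' @param mask A [nucleus_label_map()].
#' @return A `nucleus_label_map` with per-plane labels.
#' @export
collapse_labels_2d <- function(mask) {
  stopifnot(inherits(mask, "nucleus_label_map"))
  vol <- mask$volume
  nxt <- 0L
  for (z in seq_len(dim(vol)[1])) {
    plane <- vol[z, , ]
    labs <- sort(unique(plane[plane > 0L]))
    if (!length(labs)) next
    new <- nxt + seq_along(labs)
    plane2 <- plane
    for (j in seq_along(labs)) plane2[plane == labs[j]] <- new[j]
    vol[z, , ] <- plane2
    nxt <- nxt + length(labs)
  }
  nucleus_label_map(vol, mask$voxel_size, mask$fov)
}
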