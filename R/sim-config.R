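#' Describe one simulated cell type
#'
#' Helper constructor for the `cell_types` entries of [simulation_config()].
#' Each cell type is identified by a single marker gene imaged in a single
#' channel; its geometry is a sphere of radius `cell_radius_um` with a
#' concentric spherical nucleus of radius `nucleus_radius_um`.
#'
#' @param name Cell-type name (e.g. `"AT2"`).
#' @param marker_gene Marker gene; must be unique across cell types.
#' @param channel Imaging channel the marker is read out in (e.g. `"Cy3"`).
#' @param proportion Expected fraction of cells of this type, in `[0, 1]`.
#' @param mean_spots_per_cell Mean of the Poisson spot count per cell (> 0).
#' @param cell_radius_um,nucleus_radius_um Cell and nucleus radii in
#'   micrometres; the nucleus must be strictly smaller than the cell.
#' @return A named list of class `"cell_type_spec"`.
#' @export
#' @examples
#' cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 0.126)
cell_type_spec <- function(name, marker_gene, channel, proportion,
                           mean_spots_per_cell = 60,
                           cell_radius_um = 3.5,
                           nucleus_radius_um = 2.0) {
  stopifnot(is.character(name), nzchar(name),
            is.character(marker_gene), nzchar(marker_gene),
            is.character(channel), nzchar(channel))
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1)
    stop_fmt("proportion of cell type '%s' must be in [0, 1]", name)
  if (mean_spots_per_cell <= 0)
    stop_fmt("mean_spots_per_cell of '%s' must be > 0", name)
  if (nucleus_radius_um >= cell_radius_um)
    stop_fmt("nucleus radius must be smaller than cell radius for '%s'", name)
  structure(list(name = name, marker_gene = marker_gene, channel = channel,
                 proportion = proportion,
                 mean_spots_per_cell = mean_spots_per_cell,
                 cell_radius_um = cell_radius_um,
                 nucleus_radius_um = nucleus_radius_um),
            class = "cell_type_spec")
}

#' Configuration of the synthetic-tissue generator
#'
#' Defines one simulated acquisition condition: the field of view (a 3D image
#' stack of `field_shape` voxels), the voxel size, the cell types present with
#' their marker genes and geometry, and the spot noise model (uniform
#' background detections plus autofluorescent detections duplicated across
#' channels). Defaults emulate a widefield z-stack of 54 planes spaced 0.3 um
#' (16.2 um total depth); the xy pixel size has no authoritative default and
#' must be supplied.
#'
#' @param cell_types List of [cell_type_spec()] objects. Proportions must sum
#'   to at most 1; the remainder are marker-negative cells that contribute
#'   nuclei but no marker spots.
#' @param xy_pixel_um Pixel size in y and x, micrometres (required).
#' @param z_step_um z-plane spacing in micrometres (default 0.3).
#' @param field_shape Integer `(z, y, x)` voxel dimensions of one stack.
#' @param n_cells_per_fov Number of cells (nuclei) placed per field of view.
#' @param background_spot_density Uniform false-detection density per gene,
#'   spots/um^3 (>= 0).
#' @param autofluor_spot_density Density of autofluorescent particles,
#'   spots/um^3 (>= 0); each is detected in two distinct channels.
#' @param autofluor_jitter_um Isotropic Gaussian jitter (sd, um) applied to the
#'   duplicated detection of each autofluorescent particle; 0 gives identical
#'   coordinates across channels.
#' @param n_fovs_per_group Fields of view generated per experimental group.
#' @param seed Integer master seed; all outputs are reproducible from it.
#' @return A validated list of class `"simulation_config"`.
#' @seealso [generate_tissue()]
#' @export
simulation_config <- function(cell_types,
                              xy_pixel_um,
                              z_step_um = 0.3,
                              field_shape = c(54L, 300L, 300L),
                              n_cells_per_fov = 100L,
                              background_spot_density = 0.001,
                              autofluor_spot_density = 5e-4,
                              autofluor_jitter_um = 0.1,
                              n_fovs_per_group = 5L,
                              seed = 1L) {
  if (missing(xy_pixel_um))
    stop_fmt("xy_pixel_um is required (no default pixel size is assumed)")
  if (inherits(cell_types, "cell_type_spec")) cell_types <- list(cell_types)
  stopifnot(length(cell_types) >= 1L,
            all(vapply(cell_types, inherits, TRUE, "cell_type_spec")))
  names(cell_types) <- vapply(cell_types, `[[`, "", "name")
  props <- vapply(cell_types, `[[`, 0, "proportion")
  if (sum(props) > 1 + 1e-12)
    stop_fmt("cell-type proportions sum to %.3f > 1", sum(props))
  markers <- vapply(cell_types, `[[`, "", "marker_gene")
  if (anyDuplicated(markers))
    stop_fmt("each marker gene must map to exactly one cell type")
  stopifnot(xy_pixel_um > 0, z_step_um > 0,
            length(field_shape) == 3L, all(field_shape >= 1),
            is_count(n_cells_per_fov), n_cells_per_fov >= 1,
            background_spot_density >= 0, autofluor_spot_density >= 0,
            autofluor_jitter_um >= 0,
            is_count(n_fovs_per_group), n_fovs_per_group >= 1,
            is_count(seed))
  channels <- unique(vapply(cell_types, `[[`, "", "channel"))
  if (autofluor_spot_density > 0 && length(channels) < 2L)
    stop_fmt("autofluorescent spots need >= 2 channels to be duplicated into")
  structure(list(
    cell_types = cell_types,
    voxel_size = c(z = z_step_um, y = xy_pixel_um, x = xy_pixel_um),
    field_shape = as.integer(field_shape),
    n_cells_per_fov = as.integer(n_cells_per_fov),
    background_spot_density = background_spot_density,
    autofluor_spot_density = autofluor_spot_density,
    autofluor_jitter_um = autofluor_jitter_um,
    n_fovs_per_group = as.integer(n_fovs_per_group),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  fs <- x$field_shape
  vs <- x$voxel_size
  cat(sprintf("simulation_config: %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              fs[1], fs[2], fs[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  %d cells/fov, %d fovs/group, seed %d\n",
              x$n_cells_per_fov, x$n_fovs_per_group, x$seed))
  for (ct in x$cell_types)
    cat(sprintf("  %-12s %s (%s)  p=%.3f  r=%.2f/%.2f um  %.0f spots\n",
                ct$name, ct$marker_gene, ct$channel, ct$proportion,
                ct$nucleus_radius_um, ct$cell_radius_um,
                ct$mean_spots_per_cell))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror [simulation_config()] arguments; `cell_types` is a
#' list of mappings with the fields of [cell_type_spec()]; `group_effects`
#' (optional) is a mapping of group label to override lists and is returned
#' as the `"group_effects"` attribute.
#'
#' @param path Path to the YAML file.
#' @return A [simulation_config()], with attribute `group_effects`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_fmt("no such config: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$cell_types)) stop_fmt("config is missing cell_types")
  cts <- lapply(y$cell_types, function(ct) do.call(cell_type_spec, ct))
  keep <- intersect(names(y), setdiff(names(formals(simulation_config)),
                                      "cell_types"))
  cfg <- do.call(simulation_config, c(list(cell_types = cts), y[keep]))
  attr(cfg, "group_effects") <- y$group_effects
  cfg
}

# Apply per-group overrides to a config. Supported effects:
#   proportion   named vector replacing per-type proportions
#   volume_scale factor on cell volume (radii scaled by its cube root)
#   spots_scale  factor on mean spots per cell
apply_group_effects <- function(config, effects) {
  if (is.null(effects) || length(effects) == 0L) return(config)
  stopifnot(is.list(effects))
  bad <- setdiff(names(effects), c("proportion", "volume_scale", "spots_scale"))
  if (length(bad)) stop_fmt("unknown group effect(s): %s", paste(bad, collapse = ", "))
  cts <- config$cell_types
  if (!is.null(effects$proportion)) {
    pr <- effects$proportion
    unknown <- setdiff(names(pr), names(cts))
    if (length(unknown)) stop_fmt("proportion override for unknown type: %s",
                                  paste(unknown, collapse = ", "))
    for (nm in names(pr)) cts[[nm]]$proportion <- pr[[nm]]
  }
  if (!is.null(effects$volume_scale)) {
    s <- effects$volume_scale
    if (s <= 0) stop_fmt("volume_scale must be > 0")
    for (nm in names(cts)) {
      cts[[nm]]$cell_radius_um <- cts[[nm]]$cell_radius_um * s^(1 / 3)
      cts[[nm]]$nucleus_radius_um <- cts[[nm]]$nucleus_radius_um * s^(1 / 3)
    }
  }
  if (!is.null(effects$spots_scale)) {
    for (nm in names(cts))
      cts[[nm]]$mean_spots_per_cell <- cts[[nm]]$mean_spots_per_cell * effects$spots_scale
  }
  props <- vapply(cts, `[[`, 0, "proportion")
  if (sum(props) > 1 + 1e-12) stop_fmt("overridden proportions sum to > 1")
  config$cell_types <- cts
  config
}
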