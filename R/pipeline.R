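#' Run the full smFISH quantification pipeline
#'
#' Executes, for every field of view, the stages in order: cross-channel
#' autofluorescence filtering, per-gene OPTICS/DBSCAN clustering, convex-hull
#' construction, hull-to-nucleus assignment at the per-cell-type overlap
#' threshold, per-nucleus cell-type calling and volume estimation; then
#' aggregates per-image quantifications and compares the configured group
#' contrasts with Mann-Whitney tests and multiplicity adjustment. Processing
#' is per-fov independent and fails fast: any error aborts the run naming
#' the stage and fov. Results are byte-stable given identical inputs and
#' configuration (no stage uses random numbers).
#'
#' @param config A [run_config()].
#' @param fovs Input fields of view: either a `synthetic_tissue` object from
#'   [generate_tissue()], or a named list (keyed by fov id) of lists with
#'   elements `spots` (a `spot_table`) and `mask` (a [nucleus_label_map()]).
#' @param group_map Named character vector fov -> group label; inferred
#'   automatically for `synthetic_tissue` input.
#' @param compare Character vector of quantities to compare between groups
#'   (columns of the aggregated table); default proportion and median
#'   volume.
#' @return An object of class `"fishcall_run"`: `calls` (per-fov
#'   [call_cell_types()] results), `hulls` (per-fov assigned hull lists),
#'   `quantifications` (per-image long table), `comparisons` (a
#'   `comparison_table` over all genes, quantities and contrasts; `NULL`
#'   with fewer than two groups), `manifest` (per-stage record counts,
#'   config hash, package version, seed).
#' @seealso [write_run_outputs()]
#' @export
run_pipeline <- function(config, fovs, group_map = NULL,
                         compare = c("proportion", "median_volume_um3")) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(fovs, "synthetic_tissue")) {
    group_map <- setNames(vapply(fovs, `[[`, "", "group"),
                          vapply(fovs, `[[`, "", "fov"))
    fovs <- setNames(lapply(fovs, function(f) list(spots = f$spots, mask = f$mask)),
                     names(group_map))
  }
  if (is.null(names(fovs)) || any(!nzchar(names(fovs))))
    stop_fmt("fovs must be a named list keyed by fov id")
  if (is.null(group_map)) stop_fmt("group_map is required")
  missing_grp <- setdiff(names(fovs), names(group_map))
  if (length(missing_grp))
    stop_fmt("no group label for fov(s): %s", paste(missing_grp, collapse = ", "))
  # validate inputs before any computation (fail-fast)
  for (id in names(fovs)) {
    f <- fovs[[id]]
    if (!inherits(f$mask, "nucleus_label_map"))
      stop_fmt("fov '%s': mask is not a nucleus_label_map", id)
    f$spots <- as_spot_table(as.data.frame(f$spots))
    stray <- setdiff(unique(f$spots$gene), names(config$marker_map))
    if (length(stray))
      stop_fmt("fov '%s': gene(s) without marker-map entry: %s", id,
               paste(stray, collapse = ", "))
    fovs[[id]]$spots <- f$spots
  }

  calls <- list(); hulls_all <- list(); stage_counts <- list()
  for (id in names(fovs)) {
    res <- tryCatch(process_fov(config, fovs[[id]]$spots, fovs[[id]]$mask),
                    error = function(e)
                      stop_fmt("fov '%s', stage %s: %s", id,
                               attr(e, "stage") %||% "unknown",
                               conditionMessage(e)))
    calls[[id]] <- res$calls
    hulls_all[[id]] <- res$hulls
    stage_counts[[id]] <- res$counts
  }

  quant <- aggregate_quantifications(calls, group_map)
  comparisons <- NULL
  if (length(unique(group_map)) >= 2L) {
    contrasts <- config$contrasts
    tabs <- list()
    for (g in names(config$marker_map)) for (v in compare) {
      tab <- tryCatch(
        compare_panel(quant, g, value = v, contrasts = contrasts,
                      p_adjust_method = config$p_adjust_method),
        error = function(e) NULL)   # e.g. no finite volumes for a marker
      if (!is.null(tab)) tabs[[length(tabs) + 1L]] <- tab
    }
    if (length(tabs)) {
      comparisons <- do.call(rbind, tabs)
      attr(comparisons, "p_adjust_method") <- config$p_adjust_method
      class(comparisons) <- c("comparison_table", "data.frame")
    }
  }

  manifest <- build_manifest(config, stage_counts, group_map)
  structure(list(calls = calls, hulls = hulls_all, quantifications = quant,
                 comparisons = comparisons, manifest = manifest,
                 config = config),
            class = "fishcall_run")
}

# One fov through filtering -> clustering -> hulls -> assignment -> calls.
process_fov <- function(config, spots, mask) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      attr(e, "stage") <- name
      stop(e)
    })
  }
  filt <- stage("crosstalk_filter",
                filter_cross_channel(spots, config$crosstalk_tolerance_um))
  centers <- stage("overlap", precompute_centers(mask))
  hulls <- list()
  n_clusters <- 0L
  for (g in unique(filt$kept$gene)) {
    sub <- filt$kept[filt$kept$gene == g, , drop = FALSE]
    clus <- stage("clustering",
                  cluster_spots(sub, eps = config$eps[[g]],
                                min_samples = config$min_samples,
                                min_cluster_size = config$min_cluster_size))
    n_clusters <- n_clusters + length(clus$clusters)
    for (ci in seq_along(clus$clusters)) {
      coords <- as.matrix(sub[clus$clusters[[ci]], c("z_um", "y_um", "x_um")])
      hulls[[length(hulls) + 1L]] <-
        stage("hull", build_hull(coords, gene = g, fov = sub$fov[1],
                                 cluster_id = ci))
    }
  }
  overlaps <- stage("overlap",
                    lapply(hulls, hull_nucleus_overlap, mask = NULL,
                           denominator = config$overlap_denominator,
                           centers = centers))
  hulls <- stage("assignment",
                 assign_hulls(hulls, overlaps, config$K, config$marker_map))
  calls <- stage("typing",
                 call_cell_types(hulls, as.integer(names(centers)),
                                 config$marker_map))
  n_assigned <- sum(vapply(hulls, function(h) identical(h$status, "assigned"), TRUE))
  counts <- c(spots_in = nrow(spots),
              spots_removed = nrow(filt$removed),
              spots_kept = nrow(filt$kept),
              clusters = n_clusters,
              hulls_built = length(hulls),
              hulls_assigned = n_assigned,
              hulls_removed = length(hulls) - n_assigned,
              nuclei = calls$n_nuclei)
  list(calls = calls, hulls = hulls, counts = counts)
}

build_manifest <- function(config, stage_counts, group_map) {
  cfgfile <- tempfile()
  writeLines(deparse(config[setdiff(names(config), "contrasts")]), cfgfile)
  hash <- unname(tools::md5sum(cfgfile))
  unlink(cfgfile)
  counts <- do.call(rbind, stage_counts)
  # conservation checks: no record silently dropped between stages
  stopifnot(all(counts[, "spots_in"] ==
                  counts[, "spots_kept"] + counts[, "spots_removed"]),
            all(counts[, "hulls_built"] ==
                  counts[, "hulls_assigned"] + counts[, "hulls_removed"]))
  list(config_hash = hash,
       version = as.character(utils::packageVersion("fishcall")),
       seed = config$seed,
       fovs = rownames(counts),
       groups = unname(group_map[rownames(counts)]),
       counts = counts)
}

#' @export
print.fishcall_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("fishcall_run: %d fov(s), %d group(s)\n",
              length(m$fovs), length(unique(m$groups))))
  tot <- as.integer(colSums(m$counts))
  names(tot) <- colnames(m$counts)
  cat(sprintf("  spots %d (removed %d) -> clusters %d -> hulls %d (assigned %d) over %d nuclei\n",
              tot["spots_in"], tot["spots_removed"], tot["clusters"],
              tot["hulls_built"], tot["hulls_assigned"], tot["nuclei"]))
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print.data.frame(x$comparisons[c("gene", "value", "group_a", "group_b",
                                     "U", "p", "p_adj", "stars")], digits = 3)
  }
  invisible(x)
}

#' @export
summary.fishcall_run <- function(object, ...) {
  q <- object$quantifications
  agg <- aggregate(cbind(proportion, median_volume_um3) ~ group + gene,
                   data = q, FUN = function(v) mean(v, na.rm = TRUE),
                   na.action = stats::na.pass)
  cat("per-group mean of per-image quantifications:\n")
  print.data.frame(agg, digits = 3)
  invisible(agg)
}

#' @export
plot.fishcall_run <- function(x, gene = NULL, value = "proportion", ...) {
  q <- x$quantifications
  if (is.null(gene)) gene <- q$gene[1]
  q <- q[q$gene == gene, , drop = FALSE]
  graphics::stripchart(q[[value]] ~ factor(q$group), vertical = TRUE,
                       method = "jitter", pch = 19,
                       ylab = value, xlab = "group",
                       main = sprintf("%s per image (%s)", value, gene), ...)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes, per field of view, `cells_<fov>.tsv` (one row per nucleus with
#' markers, types and volumes) and `hulls_<fov>.tsv` (per hull: gene,
#' volume, status, assigned nuclei, overlap fractions); plus
#' `quantifications.tsv`, `comparisons.tsv` and `manifest.json` at the top
#' level.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "fishcall_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(run$calls)) {
    utils::write.table(run$calls[[id]]$cells,
                       file.path(dir, sprintf("cells_%s.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    hl <- run$hulls[[id]]
    hdf <- do.call(rbind, lapply(hl, function(h) data.frame(
      gene = h$gene, cluster = h$cluster_id, n_spots = h$n_spots,
      volume_um3 = h$volume_um3, degenerate = h$degenerate,
      status = h$status,
      nuclei = paste(h$assigned_nuclei, collapse = ","),
      fractions = paste(sprintf("%s:%.3f", names(h$overlap), h$overlap),
                        collapse = ","),
      stringsAsFactors = FALSE)))
    if (is.null(hdf)) hdf <- data.frame()
    utils::write.table(hdf, file.path(dir, sprintf("hulls_%s.tsv", id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(run$quantifications, file.path(dir, "quantifications.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$comparisons))
    utils::write.table(run$comparisons, file.path(dir, "comparisons.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  m <- run$manifest
  m$counts <- as.data.frame(m$counts)
  jsonlite::write_json(m, file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
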