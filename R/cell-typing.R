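#' Fractional overlap between a cell hull and each nucleus
#'
#' For every nucleus label in the mask, computes the fraction of that
#' nucleus' voxels whose centers lie inside the hull (the default,
#' `denominator = "nucleus"`), or the overlapping nucleus volume relative to
#' the hull volume (`denominator = "hull"`). Point-in-hull tests are done in
#' physical micrometres at voxel centers. Nuclei with fewer than `min_voxels`
#' voxels are excluded to bound discretization error.
#'
#' @param hull A [build_hull()] result.
#' @param mask A [nucleus_label_map()] sharing the hull's field of view.
#' @param denominator `"nucleus"` or `"hull"`.
#' @param min_voxels Minimum nucleus size in voxels (default 8).
#' @param centers Optional precomputed result of the internal voxel-center
#'   extraction, to amortize cost across many hulls.
#' @return Named numeric vector of overlap fractions in `[0, 1]`, one entry
#'   per retained nucleus label (0 when disjoint). Empty mask gives an empty
#'   vector.
#' @export
hull_nucleus_overlap <- function(hull, mask, denominator = c("nucleus", "hull"),
                                 min_voxels = 8L, centers = NULL) {
  stopifnot(inherits(hull, "cell_hull"))
  denominator <- match.arg(denominator)
  if (is.null(centers)) {
    stopifnot(inherits(mask, "nucleus_label_map"))
    centers <- nucleus_voxel_centers(mask)
    vs <- mask$voxel_size
  } else {
    vs <- attr(centers, "voxel_size")
  }
  if (!length(centers)) return(setNames(numeric(0), character(0)))
  nvox <- vapply(centers, nrow, 0L)
  bboxes <- attr(centers, "bbox")
  centers <- centers[nvox >= min_voxels]
  if (!is.null(bboxes)) bboxes <- bboxes[nvox >= min_voxels, , drop = FALSE]
  if (!length(centers)) return(setNames(numeric(0), character(0)))
  out <- setNames(numeric(length(centers)), names(centers))
  if (hull$degenerate) return(out)
  bb <- hull_bbox(hull)
  voxel_vol <- prod(vs)
  if (is.null(bboxes))
    bboxes <- t(vapply(centers, function(cc)
      c(min(cc[, 1]), max(cc[, 1]), min(cc[, 2]), max(cc[, 2]),
        min(cc[, 3]), max(cc[, 3])), numeric(6)))
  # cheap reject: nucleus bounding box vs hull bounding box
  cand <- which(!(bboxes[, 2] < bb[1, 1] | bboxes[, 1] > bb[2, 1] |
                    bboxes[, 4] < bb[1, 2] | bboxes[, 3] > bb[2, 2] |
                    bboxes[, 6] < bb[1, 3] | bboxes[, 5] > bb[2, 3]))
  for (k in cand) {
    cc <- centers[[k]]
    inside <- sum(points_in_hull(hull, cc))
    out[k] <- if (denominator == "nucleus") inside / nrow(cc)
    else min(1, inside * voxel_vol / hull$volume_um3)
  }
  out
}

# attach voxel size and per-label bounding boxes so precomputed centers can
# be reused across many hulls
precompute_centers <- function(mask) {
  centers <- nucleus_voxel_centers(mask)
  attr(centers, "voxel_size") <- mask$voxel_size
  if (length(centers))
    attr(centers, "bbox") <- t(vapply(centers, function(cc)
      c(min(cc[, 1]), max(cc[, 1]), min(cc[, 2]), max(cc[, 2]),
        min(cc[, 3]), max(cc[, 3])), numeric(6)))
  centers
}

#' Assign hulls to nuclei by the per-cell-type overlap threshold K
#'
#' A nucleus is assigned to a hull when its overlap fraction reaches the
#' threshold `K` configured for the hull's cell type (several nuclei may
#' qualify for one hull, e.g. neighboring cells of the same type). Hulls with
#' no qualifying nucleus get status `"removed"` and are excluded downstream —
#' this typically happens when the generating cell's nucleus is outside the
#' imaged volume.
#'
#' @param hulls List of [build_hull()] results.
#' @param overlaps List parallel to `hulls` of [hull_nucleus_overlap()]
#'   vectors.
#' @param K Named numeric vector of thresholds per cell type, in `[0, 1]`.
#' @param marker_map Named character vector, gene -> cell type.
#' @return The hulls, each augmented with `overlap` (named fractions),
#'   `assigned_nuclei` (integer labels) and `status`
#'   (`"assigned"`/`"removed"`).
#' @export
assign_hulls <- function(hulls, overlaps, K, marker_map) {
  stopifnot(length(hulls) == length(overlaps))
  lapply(seq_along(hulls), function(i) {
    h <- hulls[[i]]
    if (!h$gene %in% names(marker_map))
      stop_fmt("gene '%s' has no cell type in the marker map", h$gene)
    type <- marker_map[[h$gene]]
    if (!type %in% names(K))
      stop_fmt("no overlap threshold K configured for cell type '%s'", type)
    ov <- overlaps[[i]]
    hit <- names(ov)[ov >= K[[type]]]
    h$cell_type <- type
    h$overlap <- ov
    h$assigned_nuclei <- as.integer(hit)
    h$status <- if (length(hit)) "assigned" else "removed"
    h
  })
}

#' Call per-nucleus cell types from assigned hulls
#'
#' Every segmented nucleus appears exactly once. A marker is positive for a
#' nucleus when at least one assigned hull of that marker's gene includes it;
#' the cell type follows from the marker (one marker gene per cell type).
#' Nuclei positive for several markers are reported as co-expressing. Cell
#' volume is estimated per marker as the hull volume divided by the number of
#' nuclei assigned to that hull (average cell volume per nucleus when a point
#' cloud contains several nuclei); volumes of several same-gene hulls
#' claiming one nucleus are summed. Degenerate hulls contribute positivity
#' but no volume estimate.
#'
#' @param assigned_hulls Output of [assign_hulls()].
#' @param mask The [nucleus_label_map()] of the field of view (defines the
#'   denominator: all segmented nuclei), or an integer vector of labels.
#' @param marker_map Named character vector, gene -> cell type.
#' @return A list of class `"cell_calls"`: `cells` (data frame: `nucleus`,
#'   `markers`, `types`, `n_markers`, one volume column
#'   `volume_<gene>_um3` per marker), `summary` (data frame per marker:
#'   positive count, total nuclei, proportion), `n_nuclei`,
#'   `n_coexpressing`.
#' @export
call_cell_types <- function(assigned_hulls, mask, marker_map) {
  labels <- if (inherits(mask, "nucleus_label_map")) {
    sort(setdiff(unique(as.vector(mask$volume)), 0L))
  } else sort(unique(as.integer(mask)))
  genes <- names(marker_map)
  n <- length(labels)
  pos <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  vol <- matrix(NA_real_, n, length(genes), dimnames = list(NULL, genes))
  for (h in assigned_hulls) {
    if (!identical(h$status, "assigned")) next
    rows <- match(h$assigned_nuclei, labels)
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    pos[rows, h$gene] <- TRUE
    if (!h$degenerate && h$volume_um3 > 0) {
      share <- h$volume_um3 / length(h$assigned_nuclei)
      old <- vol[rows, h$gene]
      vol[rows, h$gene] <- ifelse(is.na(old), share, old + share)
    }
  }
  markers <- apply(pos, 1L, function(r) paste(genes[r], collapse = ","))
  types <- apply(pos, 1L, function(r)
    paste(unname(marker_map[genes[r]]), collapse = ","))
  cells <- data.frame(nucleus = labels, markers = markers, types = types,
                      n_markers = rowSums(pos), stringsAsFactors = FALSE)
  for (g in genes) cells[[paste0("volume_", g, "_um3")]] <- vol[, g]
  summary <- data.frame(
    gene = genes, cell_type = unname(marker_map[genes]),
    positive = as.integer(colSums(pos)), total_nuclei = n,
    proportion = if (n > 0) colSums(pos) / n else rep(NA_real_, length(genes)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cells = cells, summary = summary, n_nuclei = n,
                 n_coexpressing = sum(rowSums(pos) >= 2L)),
            class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat(sprintf("cell_calls: %d nuclei, %d co-expressing\n",
              x$n_nuclei, x$n_coexpressing))
  print.data.frame(x$summary)
  invisible(x)
}

#' Per-nucleus cell-volume estimates from one assigned hull
#'
#' The cell volume of each nucleus assigned to a hull is the hull volume
#' divided by the number of assigned nuclei (average cell volume per nucleus
#' for multi-nucleus point clouds). Degenerate hulls yield no estimate.
#'
#' @param hull An assigned hull (from [assign_hulls()]).
#' @return Named numeric vector (nucleus label -> volume in um^3); empty for
#'   removed or degenerate hulls.
#' @export
estimate_cell_volume <- function(hull) {
  stopifnot(inherits(hull, "cell_hull"))
  if (!identical(hull$status, "assigned") || hull$degenerate ||
      hull$volume_um3 <= 0 || !length(hull$assigned_nuclei))
    return(setNames(numeric(0), character(0)))
  setNames(rep(hull$volume_um3 / length(hull$assigned_nuclei),
               length(hull$assigned_nuclei)),
           as.character(hull$assigned_nuclei))
}
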