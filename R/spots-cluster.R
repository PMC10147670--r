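# OPTICS (Ankerst et al.) over a 3D point set with max_eps = Inf.
# min_samples counts the point itself, so the core distance of a point is the
# distance to its (min_samples - 1)-th nearest other point.
optics_order <- function(X, min_samples) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  core_dist <- kth_smallest_rows(D, min_samples)
  reach_rec <- rep(Inf, n)    # reachability recorded at pop time
  work <- rep(Inf, n)         # NA once processed (which.min skips NA)
  ordering <- integer(n)
  for (k in seq_len(n)) {
    p <- which.min(work)      # ties and fresh components: lowest index
    ordering[k] <- p
    reach_rec[p] <- work[p]
    nr <- pmax(core_dist[p], D[, p])
    upd <- which(nr < work)
    work[upd] <- nr[upd]
    work[p] <- NA
  }
  reach_rec[ordering[1L]] <- Inf
  list(ordering = ordering, reachability = reach_rec,
       core_distance = core_dist, dist = D)
}

# k-th smallest entry of each row (self distance 0 included), via k passes of
# max.col; falls back to partial sort for large k.
kth_smallest_rows <- function(D, k) {
  n <- nrow(D)
  if (k > 8L)
    return(apply(D, 1L, function(d) sort(d, partial = k)[k]))
  D2 <- -D
  idx <- NULL
  for (j in seq_len(k)) {
    idx <- max.col(D2, ties.method = "first")
    if (j < k) D2[cbind(seq_len(n), idx)] <- -Inf
  }
  D[cbind(seq_len(n), idx)]
}

# DBSCAN labels extracted from an OPTICS run at radius eps: walk the ordering,
# opening a new cluster whenever reachability exceeds eps at a core point.
extract_dbscan <- function(opt, eps) {
  n <- length(opt$ordering)
  labels <- integer(n)                  # 0 = noise
  cl <- 0L
  for (p in opt$ordering) {
    if (opt$reachability[p] > eps) {
      if (opt$core_distance[p] <= eps) {
        cl <- cl + 1L
        labels[p] <- cl
      } else labels[p] <- 0L
    } else labels[p] <- cl
  }
  labels
}

#' Cluster the spots of one gene with OPTICS/DBSCAN
#'
#' Runs OPTICS (which determines core distances and the reachability
#' ordering) with the configured `min_samples` and extracts a DBSCAN
#' labeling at the per-gene radius `eps`; clusters with fewer than
#' `min_cluster_size` members are demoted to noise. Cluster membership is
#' deterministic and invariant to input permutation: non-core (border) points
#' reachable from several clusters are assigned to the cluster of their
#' nearest core point, ties broken by the lowest cluster id.
#'
#' @param spots A `spot_table` restricted to one gene in one field of view,
#'   or a numeric matrix of `(z, y, x)` coordinates in micrometres.
#' @param eps Neighborhood radius in micrometres (> 0); a per-gene analysis
#'   parameter adjusted to expression level.
#' @param min_samples Minimum neighbors (point included) for a core point.
#' @param min_cluster_size Minimum retained cluster size.
#' @return A list of class `"spot_clustering"`: `labels` (integer per spot,
#'   0 = noise), `clusters` (list of member index vectors, ordered by first
#'   member), `is_core` (logical), and `optics` (ordering, reachability,
#'   core distances).
#' @export
cluster_spots <- function(spots, eps, min_samples = 4L, min_cluster_size = 4L) {
  X <- spot_coords(spots)
  if (eps <= 0) stop_fmt("eps must be > 0")
  n <- nrow(X)
  if (n == 0L)
    return(structure(list(labels = integer(), clusters = list(),
                          is_core = logical(), optics = NULL),
                     class = "spot_clustering"))
  if (n < min_samples)   # nobody can be a core point
    return(structure(list(labels = rep(0L, n), clusters = list(),
                          is_core = rep(FALSE, n), optics = NULL),
                     class = "spot_clustering"))
  opt <- optics_order(X, min_samples)
  labels <- extract_dbscan(opt, eps)
  is_core <- opt$core_distance <= eps
  # deterministic border assignment: nearest core point, ties by cluster id
  noncore <- which(!is_core)
  core <- which(is_core)
  if (length(noncore) && length(core)) {
    core <- core[order(labels[core], core)]   # tie-break: lowest cluster id
    sub <- opt$dist[noncore, core, drop = FALSE]
    sub[sub > eps] <- Inf
    j <- max.col(-sub, ties.method = "first")
    reachable <- is.finite(sub[cbind(seq_along(noncore), j)])
    labels[noncore] <- ifelse(reachable, labels[core][j], 0L)
  } else if (length(noncore)) {
    labels[noncore] <- 0L
  }
  labels <- canonical_labels(labels)
  # demote undersized clusters to noise
  if (any(labels > 0L)) {
    sizes <- table(labels[labels > 0L])
    small <- as.integer(names(sizes)[sizes < min_cluster_size])
    labels[labels %in% small] <- 0L
    labels <- canonical_labels(labels)
  }
  clusters <- split(seq_len(n), labels)
  clusters <- unname(clusters[names(clusters) != "0"])
  opt$dist <- NULL
  structure(list(labels = labels, clusters = clusters, is_core = is_core,
                 optics = opt), class = "spot_clustering")
}

#' @export
print.spot_clustering <- function(x, ...) {
  cat(sprintf("spot_clustering: %d spots, %d cluster(s), %d noise\n",
              length(x$labels), length(x$clusters), sum(x$labels == 0L)))
  invisible(x)
}

# renumber cluster ids 1,2,... by order of first member index
canonical_labels <- function(labels) {
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  first <- vapply(split(seq_along(labels)[pos], labels[pos]), min, 0L)
  map <- setNames(rank(first), names(first))
  labels[pos] <- as.integer(map[as.character(labels[pos])])
  labels
}

spot_coords <- function(spots) {
  if (is.matrix(spots)) {
    stopifnot(ncol(spots) == 3L, is.numeric(spots))
    return(spots)
  }
  df <- as.data.frame(spots)
  stopifnot(all(c("z_um", "y_um", "x_um") %in% names(df)))
  as.matrix(df[c("z_um", "y_um", "x_um")])
}

#' Suggest a clustering radius from the OPTICS reachability profile
#'
#' Proposes an `eps` at the knee of the sorted finite reachability curve
#' (largest perpendicular distance to the chord joining its endpoints).
#' This is a starting point for manual per-gene adjustment only; the
#' pipeline always uses the configured `eps`, never this suggestion.
#'
#' @param spots Spot table or coordinate matrix (one gene, one field of view).
#' @param min_samples OPTICS density parameter.
#' @return A list: `eps` (strictly positive suggestion), `reachability`
#'   (sorted finite reachability profile used).
#' @export
suggest_eps <- function(spots, min_samples = 4L) {
  X <- spot_coords(spots)
  if (nrow(X) < min_samples)
    stop_fmt("need at least min_samples = %d spots, got %d", min_samples, nrow(X))
  opt <- optics_order(X, min_samples)
  r <- sort(opt$reachability[is.finite(opt$reachability)])
  if (!length(r)) stop_fmt("no finite reachability values")
  if (length(r) == 1L || r[length(r)] == r[1L])
    return(list(eps = max(r[1L], .Machine$double.eps), reachability = r))
  m <- length(r)
  # perpendicular distance of each profile point to the chord
  x1 <- 1; y1 <- r[1]; x2 <- m; y2 <- r[m]
  num <- abs((y2 - y1) * seq_len(m) - (x2 - x1) * r + x2 * y1 - y2 * x1)
  k <- which.max(num)
  eps <- if (k < m) (r[k] + r[k + 1L]) / 2 else r[k]
  list(eps = max(eps, .Machine$double.eps), reachability = r)
}
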