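# 3D convex hull (quickhull) with outward-oriented triangular facets.
# Small point sets (tens to hundreds of spots per cluster), pure R.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Returns list(faces = m x 3 index matrix, outward oriented; degenerate flag).
quickhull3 <- function(P, tol = NULL) {
  n <- nrow(P)
  stopifnot(n >= 4L, ncol(P) == 3L)
  rng <- max(apply(P, 2, function(v) diff(range(v))), .Machine$double.eps)
  if (is.null(tol)) tol <- 1e-10 * rng

  # initial extreme pair: farthest-apart axis extremes
  ext <- unique(as.vector(apply(P, 2, function(v) c(which.min(v), which.max(v)))))
  best <- c(ext[1], ext[2]); bd <- -1
  for (i in ext) for (j in ext) if (j > i) {
    d <- sum((P[i, ] - P[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  i1 <- best[1]; i2 <- best[2]
  if (bd <= tol^2) return(list(degenerate = TRUE))
  u <- P[i2, ] - P[i1, ]
  # farthest from the line (i1, i2)
  rel <- sweep(P, 2, P[i1, ])
  t <- as.vector(rel %*% u) / sum(u^2)
  perp2 <- rowSums((rel - outer(t, u))^2)
  i3 <- which.max(perp2)
  if (sqrt(perp2[i3]) <= tol) return(list(degenerate = TRUE))
  # farthest from the plane (i1, i2, i3)
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  hgt <- as.vector(rel %*% nrm)
  i4 <- which.max(abs(hgt))
  if (abs(hgt[i4]) <= tol) return(list(degenerate = TRUE))

  o <- colMeans(P[c(i1, i2, i3, i4), ])   # fixed interior reference point

  orient <- function(v) {                 # outward-orient one triangle
    nn <- cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    if (sum(nn * (o - P[v[1], ])) > 0) v[c(1L, 3L, 2L)] else v
  }
  faces <- rbind(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  face_plane <- function(v) {             # unit outward normal and offset
    nn <- cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    nn <- nn / sqrt(sum(nn^2))
    c(nn, sum(nn * P[v[1], ]))
  }
  planes <- t(apply(faces, 1L, face_plane))   # F x 4: (nz, ny, nx, d)

  alive <- rep(TRUE, nrow(faces))
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  repeat {
    fp <- NULL
    live <- which(alive)
    nmat <- t(planes[live, 1:3, drop = FALSE])
    dvec <- planes[live, 4]
    if (length(remaining)) {
      # farthest outside point over all live faces
      S <- P[remaining, , drop = FALSE] %*% nmat
      S <- sweep(S, 2, dvec)
      mc <- max.col(S, ties.method = "first")
      mx <- S[cbind(seq_along(remaining), mc)]
      k <- which.max(mx)
      if (mx[k] > tol) fp <- remaining[k]
    }
    if (is.null(fp)) break
    p <- P[fp, ]
    vis <- live[as.vector(p %*% nmat) - dvec > tol]
    # horizon: edges used by exactly one visible face
    v1 <- faces[vis, , drop = FALSE]
    ea <- c(v1[, 1], v1[, 2], v1[, 3])
    eb <- c(v1[, 2], v1[, 3], v1[, 1])
    key <- pmin(ea, eb) * (n + 1) + pmax(ea, eb)
    solo <- !(key %in% key[duplicated(key)])
    ha <- ea[solo]; hb <- eb[solo]
    alive[vis] <- FALSE
    new_faces <- matrix(0L, length(ha), 3L)
    new_planes <- matrix(0, length(ha), 4L)
    for (e in seq_along(ha)) {
      v <- orient(c(ha[e], hb[e], fp))
      new_faces[e, ] <- v
      new_planes[e, ] <- face_plane(v)
    }
    faces <- rbind(faces, new_faces)
    planes <- rbind(planes, new_planes)
    alive <- c(alive, rep(TRUE, length(ha)))
    remaining <- setdiff(remaining, fp)
    if (length(remaining)) {    # drop points now inside every live face
      live <- which(alive)
      S <- sweep(P[remaining, , drop = FALSE] %*%
                   t(planes[live, 1:3, drop = FALSE]), 2, planes[live, 4])
      remaining <- remaining[rowSums(S > tol) > 0L]
    }
  }
  keep <- which(alive)
  list(degenerate = FALSE,
       faces = faces[keep, , drop = FALSE],
       normals = planes[keep, 1:3, drop = FALSE],
       offsets = planes[keep, 4],
       tol = tol)
}

# Enclosed volume of an outward-oriented closed triangulated surface
# (divergence theorem; exact for lattice-coordinate solids).
surface_volume <- function(P, faces) {
  v <- 0
  for (f in seq_len(nrow(faces))) {
    a <- P[faces[f, 1], ]; b <- P[faces[f, 2], ]; c <- P[faces[f, 3], ]
    v <- v + sum(a * cross3(b, c))
  }
  v / 6
}

#' Build the convex-hull territory of one spot cluster
#'
#' Computes the 3D convex hull of a cluster's member spots; the hull is the
#' proxy for the cytoplasmic territory of one cell and its volume is the
#' cell-volume estimate. Degenerate (collinear or coplanar) point clouds are
#' flagged with volume 0 and excluded from volume statistics downstream.
#'
#' @param coords Numeric matrix of member spot coordinates `(z, y, x)` in
#'   micrometres, at least 4 rows, or a `spot_table` subset.
#' @param gene,fov,cluster_id Identification carried into the result.
#' @return An object of class `"cell_hull"`: `vertices` (coordinates of hull
#'   vertices), `faces`, `normals`/`offsets` (outward facet planes),
#'   `volume_um3`, `degenerate`, `n_spots`, plus the ids.
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(z = 0:1, y = 0:1, x = 0:1))
#' build_hull(cube)$volume_um3   # exactly 1
build_hull <- function(coords, gene = NA_character_, fov = NA_character_,
                       cluster_id = NA_integer_) {
  X <- spot_coords(coords)
  if (nrow(X) < 4L)
    stop_fmt("a hull needs at least 4 spots, got %d", nrow(X))
  qh <- quickhull3(X)
  if (isTRUE(qh$degenerate)) {
    h <- list(vertices = X, faces = NULL, normals = NULL, offsets = NULL,
              volume_um3 = 0, degenerate = TRUE, n_spots = nrow(X),
              gene = gene, fov = fov, cluster_id = cluster_id)
    return(structure(h, class = "cell_hull"))
  }
  vol <- surface_volume(X, qh$faces)
  structure(list(vertices = X, faces = qh$faces, normals = qh$normals,
                 offsets = qh$offsets, volume_um3 = vol, degenerate = FALSE,
                 n_spots = nrow(X), gene = gene, fov = fov,
                 cluster_id = cluster_id, tol = qh$tol),
            class = "cell_hull")
}

#' @export
print.cell_hull <- function(x, ...) {
  cat(sprintf("cell_hull%s: %d spots, volume %.1f um^3%s\n",
              if (!is.na(x$gene)) sprintf(" [%s]", x$gene) else "",
              x$n_spots, x$volume_um3,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Test points for hull membership
#'
#' @param hull A [build_hull()] result.
#' @param points Numeric matrix `(z, y, x)`, micrometres.
#' @param tol Boundary tolerance; points within `tol` of a facet plane count
#'   as inside.
#' @return Logical vector; all `FALSE` for a degenerate hull.
#' @export
points_in_hull <- function(hull, points, tol = 1e-9) {
  stopifnot(inherits(hull, "cell_hull"))
  P <- as.matrix(points)
  if (hull$degenerate || nrow(P) == 0L) return(rep(FALSE, nrow(P)))
  S <- sweep(P %*% t(hull$normals), 2, hull$offsets)
  rowSums(S > tol) == 0L
}

hull_bbox <- function(hull) apply(hull$vertices, 2, range)
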