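# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity by the most literal method
# available (exhaustive pair scans, BFS cluster expansion, facet
# enumeration, permutation enumeration) and share no code with R/.

# --- cross-channel coincidence: O(n^2) all-pairs scan ----------------------
oracle_crosschannel_removed <- function(spots, tol) {
  n <- nrow(spots)
  removed <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (spots$fov[i] != spots$fov[j]) next
    if (spots$channel[i] == spots$channel[j]) next
    d <- sqrt((spots$z_um[i] - spots$z_um[j])^2 +
                (spots$y_um[i] - spots$y_um[j])^2 +
                (spots$x_um[i] - spots$x_um[j])^2)
    if (d <= tol) removed[i] <- TRUE
  }
  removed
}

# --- DBSCAN: neighbor counting + breadth-first expansion -------------------
# Border points go to the cluster of their nearest core point (ties: lowest
# cluster id); clusters below min_cluster_size are demoted to noise.
oracle_dbscan <- function(X, eps, min_samples = 4L, min_cluster_size = 4L) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nbrs <- D <= eps
  core <- rowSums(nbrs) >= min_samples   # neighbor count includes the point
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      nb <- which(nbrs[q, ] & core & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cand <- which(core & D[i, ] <= eps)
    if (!length(cand)) { labels[i] <- 0L; next }
    dmin <- min(D[i, cand])
    best <- cand[D[i, cand] == dmin]
    labels[i] <- min(labels[best])
  }
  if (cl > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = cl)
    small <- which(sizes > 0L & sizes < min_cluster_size)
    labels[labels %in% small] <- 0L
  }
  labels
}

# canonical partition signature: clusters as sorted member lists, ordered by
# first member, so labelings can be compared independently of cluster ids
partition_signature <- function(labels) {
  cl <- split(seq_along(labels), labels)
  cl <- cl[names(cl) != "0"]
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, min, 0L))])
}

# --- convex hull via brute-force facet enumeration -------------------------
# Every triple of points whose plane has all other points (weakly) on one
# side is a facet; membership = inside every such half-space.
oracle_hull_halfspaces <- function(X, tol = 1e-9) {
  n <- nrow(X)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- X[i, ]; b <- X[j, ]; c <- X[k, ]
    u <- b - a; v <- c - a
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-12) next
    nrm <- nrm / nl
    s <- as.vector(X %*% nrm) - sum(nrm * a)
    if (all(s <= tol)) planes[[length(planes) + 1L]] <- c(nrm, sum(nrm * a))
    else if (all(s >= -tol)) planes[[length(planes) + 1L]] <- c(-nrm, -sum(nrm * a))
  }
  do.call(rbind, planes)
}

oracle_points_in_hull <- function(halfspaces, P, tol = 1e-9) {
  S <- sweep(P %*% t(halfspaces[, 1:3, drop = FALSE]), 2, halfspaces[, 4])
  rowSums(S > tol) == 0L
}

# --- exact two-sided Mann-Whitney by exhaustive enumeration ----------------
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  labelings <- utils::combn(n + m, n)
  us <- apply(labelings, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# --- naive window-scanning probe-rule checker ------------------------------
oracle_probe_flags <- function(seq, len_min = 26L, len_max = 32L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  n_a <- sum(ch == "A"); n_c <- sum(ch == "C"); n_g <- sum(ch == "G")
  has_aaaa <- FALSE
  if (L >= 4L) for (i in 1:(L - 3L))
    if (all(ch[i:(i + 3L)] == "A")) has_aaaa <- TRUE
  pre <- ch[1:min(12L, L)]
  np <- length(pre)
  cccc_bad <- FALSE; c4_bad <- FALSE
  if (np >= 6L) {
    for (i in 1:(np - 5L)) {
      w <- pre[i:(i + 5L)]
      runlen <- 0L
      for (x in w) {
        runlen <- if (x == "C") runlen + 1L else 0L
        if (runlen >= 4L) cccc_bad <- TRUE
      }
      if (sum(w == "C") >= 4L) c4_bad <- TRUE
    }
  } else {
    runlen <- 0L
    for (x in pre) {
      runlen <- if (x == "C") runlen + 1L else 0L
      if (runlen >= 4L) cccc_bad <- TRUE
    }
    if (sum(pre == "C") >= 4L) c4_bad <- TRUE
  }
  c(length = L >= len_min && L <= len_max,
    GC = (n_g + n_c) / L >= 0.40 && (n_g + n_c) / L <= 0.60,
    A_comp = n_a / L < 0.28,
    AAAA = !has_aaaa,
    C_comp = n_c / L >= 0.22 && n_c / L <= 0.28,
    CCCC_first12 = !cccc_bad,
    nonconsecC_first12 = !c4_bad)
}

# --- shared scenario builders ---------------------------------------------

# Fig. 2c-style study: AT2 (Lamp3, 12.6% in control) plus a sparse AM
# population; one group receives a reduced AT2 proportion.
fig2c_config <- function(seed, n_fovs = 5L) {
  simulation_config(
    list(cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 0.126,
                        mean_spots_per_cell = 45),
         cell_type_spec("AM", "Chil3", "Cy5", proportion = 0.05,
                        mean_spots_per_cell = 30, cell_radius_um = 4.0,
                        nucleus_radius_um = 2.2)),
    xy_pixel_um = 0.2, field_shape = c(54L, 500L, 500L),
    n_cells_per_fov = 100L, n_fovs_per_group = n_fovs, seed = seed)
}

fig2c_run_config <- function() {
  run_config(marker_map = c(Lamp3 = "AT2", Chil3 = "AM"),
             eps = c(Lamp3 = 2.8, Chil3 = 2.8))
}

# Alveolar-macrophage volume study: control AM volume 459 um^3, irradiated
# group scaled to 925 um^3 (ratio ~2.0).
am_volume_config <- function(seed, n_fovs = 5L) {
  r_am <- (3 * 459 / (4 * pi))^(1 / 3)   # sphere radius giving 459 um^3
  simulation_config(
    list(cell_type_spec("AM", "Chil3", "Cy5", proportion = 0.25,
                        mean_spots_per_cell = 60, cell_radius_um = r_am,
                        nucleus_radius_um = 2.6),
         cell_type_spec("AT2", "Lamp3", "Cy3", proportion = 0.05,
                        mean_spots_per_cell = 30)),
    xy_pixel_um = 0.2, field_shape = c(54L, 500L, 500L),
    n_cells_per_fov = 40L, n_fovs_per_group = n_fovs, seed = seed)
}

# Run one group through the pipeline and return per-image quantifications.
run_group_quant <- function(cfg, rc, group_name, effects = list()) {
  tis <- generate_tissue(cfg, group_effects = setNames(list(effects), group_name))
  run <- run_pipeline(rc, tis)
  run$quantifications
}
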