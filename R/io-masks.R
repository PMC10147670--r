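#' 3D labeled nucleus mask
#'
#' Container for a 3D integer-labeled nucleus segmentation with voxel-size
#' metadata. Axis order is `(z, y, x)`; label 0 is background and each
#' positive label is one nucleus.
#'
#' @param volume 3D integer array `(z, y, x)` of non-negative labels.
#' @param voxel_size Numeric length-3 `(z, y, x)` voxel size in micrometres,
#'   strictly positive.
#' @param fov Field-of-view identifier.
#' @return An object of class `"nucleus_label_map"`.
#' @export
nucleus_label_map <- function(volume, voxel_size, fov = "fov") {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop_fmt("volume must be a 3D array (z, y, x)")
  if (is.double(volume)) {
    if (any(volume != round(volume)))
      stop_fmt("labels must be integers (found fractional values)")
    storage.mode(volume) <- "integer"
  }
  if (!is.integer(volume)) stop_fmt("labels must be integer-valued")
  if (any(volume < 0L)) stop_fmt("labels must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_fmt("voxel_size must be 3 strictly positive numbers (z, y, x)")
  names(voxel_size) <- c("z", "y", "x")
  structure(list(volume = volume, voxel_size = voxel_size,
                 fov = as.character(fov)),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("nucleus_label_map '%s': %d x %d x %d voxels (z,y,x), %d nuclei\n",
              x$fov, d[1], d[2], d[3], n_labels(x)))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

n_labels <- function(mask) length(setdiff(unique(as.vector(mask$volume)), 0L))

MAX_TIFF_LABEL <- 65535L

#' Read a 3D label map from a multi-page TIFF
#'
#' One TIFF page per z-plane, unsigned-integer labels, 0 = background. Pages
#' must share shape; float-valued pages are rejected.
#'
#' @param path Path to the multi-page TIFF.
#' @param voxel_size `(z, y, x)` voxel size in micrometres.
#' @param fov Field-of-view id; default is the file name without extension.
#' @return A [nucleus_label_map()].
#' @export
read_label_map <- function(path, voxel_size,
                           fov = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop_fmt("no such label map: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_fmt("TIFF pages have mixed shapes: %s", paste(unique(shapes), collapse = ", "))
  if (any(vapply(pages, function(p) any(p != round(p)), TRUE)))
    stop_fmt("TIFF contains non-integer sample values; expected integer labels")
  d <- dim(pages[[1]])
  vol <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vol[z, , ] <- as.integer(round(pages[[z]]))
  nucleus_label_map(vol, voxel_size, fov)
}

#' Write a 3D label map as a multi-page TIFF
#'
#' Labels are stored as 16-bit unsigned samples (one page per z-plane), which
#' round-trips exactly through [read_label_map()] for labels up to 65535.
#'
#' @param mask A [nucleus_label_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(mask, path) {
  stopifnot(inherits(mask, "nucleus_label_map"))
  if (max(mask$volume) > MAX_TIFF_LABEL)
    stop_fmt("labels exceed %d; cannot store as 16-bit TIFF", MAX_TIFF_LABEL)
  pages <- lapply(seq_len(dim(mask$volume)[1]),
                  function(z) mask$volume[z, , ] / MAX_TIFF_LABEL)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# Per-nucleus voxel centers in physical um, as a list keyed by label.
# Used by the overlap computation; voxel (i,j,k) (1-based) has center
# ((i-0.5)*vz, (j-0.5)*vy, (k-0.5)*vx).
nucleus_voxel_centers <- function(mask) {
  vol <- mask$volume
  vs <- mask$voxel_size
  idx <- which(vol > 0L)
  if (!length(idx)) return(list())
  d <- dim(vol)
  lab <- vol[idx]
  i0 <- idx - 1L
  z <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  x <- i0 %/% (d[1] * d[2])
  centers <- cbind(z = (z + 0.5) * vs[1], y = (y + 0.5) * vs[2],
                   x = (x + 0.5) * vs[3])
  o <- order(lab)
  lab <- lab[o]
  centers <- centers[o, , drop = FALSE]
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- lapply(seq_along(runs$values), function(i)
    centers[starts[i]:ends[i], , drop = FALSE])
  names(out) <- runs$values
  out
}
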