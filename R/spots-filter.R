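#' Remove cross-channel coincident (autofluorescent) spots
#'
#' Detections that appear in several channels at (nearly) the same 3D
#' location are taken to be autofluorescent particles rather than RNA and are
#' removed. A spot is removed if and only if some spot of a *different*
#' channel in the same field of view lies within Euclidean distance
#' `tolerance_um`; both partners of a coincident pair are removed. Spots are
#' compared in physical micrometres across `(z, y, x)`.
#'
#' The operation is idempotent and partitions its input:
#' `kept` and `removed` are disjoint and their union is the input table.
#'
#' @param spots A `spot_table` (see [read_spot_table()]).
#' @param tolerance_um Coincidence tolerance in micrometres (>= 0). With a
#'   single channel present nothing can be removed.
#' @return A list with `kept` and `removed` (both `spot_table`s preserving
#'   input row order) and `report`: a data frame naming, for each removed
#'   spot, its original row, its nearest other-channel partner row and their
#'   distance, for audit.
#' @export
#' @examples
#' s <- data.frame(fov = "f", gene = c("a", "b"), channel = c("Cy3", "Cy5"),
#'                 z_um = 1, y_um = 2, x_um = 3)
#' filter_cross_channel(fishcall:::as_spot_table(s), tolerance_um = 0)$removed
filter_cross_channel <- function(spots, tolerance_um = 0.35) {
  spots <- as_spot_table(as.data.frame(spots))
  if (tolerance_um < 0) stop_fmt("tolerance_um must be >= 0")
  n <- nrow(spots)
  removed <- logical(n)
  partner <- rep(NA_integer_, n)
  pdist <- rep(NA_real_, n)
  if (n > 0L && length(unique(spots$channel)) > 1L) {
    for (f in unique(spots$fov)) {
      idx <- which(spots$fov == f)
      ch <- spots$channel[idx]
      chans <- unique(ch)
      if (length(chans) < 2L) next
      xyz <- as.matrix(spots[idx, c("z_um", "y_um", "x_um")])
      # pairwise only across channel blocks, never within a channel; the
      # fast quadratic-form distance suffers cancellation near zero, so
      # candidate pairs are re-measured exactly from coordinate differences
      for (a in seq_len(length(chans) - 1L)) for (b in (a + 1L):length(chans)) {
        ia <- which(ch == chans[a]); ib <- which(ch == chans[b])
        A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
        D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
        cand <- which(D2 <= (tolerance_um + 1e-6)^2 + 1e-9, arr.ind = TRUE)
        if (!nrow(cand)) next
        d2 <- (A[cand[, 1], 1] - B[cand[, 2], 1])^2 +
          (A[cand[, 1], 2] - B[cand[, 2], 2])^2 +
          (A[cand[, 1], 3] - B[cand[, 2], 3])^2
        keep <- d2 <= tolerance_um^2
        cand <- cand[keep, , drop = FALSE]
        d <- sqrt(d2[keep])
        for (k in seq_len(nrow(cand))) {
          gi <- idx[ia[cand[k, 1]]]; gj <- idx[ib[cand[k, 2]]]
          removed[c(gi, gj)] <- TRUE
          if (is.na(pdist[gi]) || d[k] < pdist[gi]) {
            partner[gi] <- gj; pdist[gi] <- d[k]
          }
          if (is.na(pdist[gj]) || d[k] < pdist[gj]) {
            partner[gj] <- gi; pdist[gj] <- d[k]
          }
        }
      }
    }
  }
  report <- data.frame(row = which(removed),
                       partner_row = partner[removed],
                       distance_um = pdist[removed])
  kept <- spots[!removed, , drop = FALSE]
  gone <- spots[removed, , drop = FALSE]
  rownames(kept) <- rownames(gone) <- NULL
  class(kept) <- class(gone) <- c("spot_table", "data.frame")
  list(kept = kept, removed = gone, report = report)
}
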