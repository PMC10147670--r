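#' Pipeline run configuration
#'
#' Collects every tunable of the quantification pipeline: the cross-channel
#' coincidence tolerance, the per-gene DBSCAN radius `eps`, the OPTICS
#' density parameters, the marker-to-cell-type map, the per-cell-type
#' hull/nucleus overlap threshold `K`, and the multiplicity-adjustment
#' method.
#'
#' @param marker_map Named character vector mapping marker gene to cell type
#'   (e.g. `c(Lamp3 = "AT2")`); must be injective.
#' @param eps Named numeric vector, clustering radius in micrometres per gene;
#'   every gene in `marker_map` needs an entry. The radius is a free,
#'   per-gene analysis parameter (adjusted to expression level), never
#'   estimated automatically by the pipeline.
#' @param K Named numeric vector, minimum hull/nucleus overlap fraction per
#'   cell type in `[0, 1]`. Values are typically chosen in `[0.20, 0.55]` to
#'   accommodate cell morphologies; the default fills 0.375 (the midpoint of
#'   that range) for every type.
#' @param crosstalk_tolerance_um Distance below which spots of different
#'   channels count as the same location (autofluorescence); default 0.35 um,
#'   about one xy pixel at high-NA widefield sampling. A free parameter, not
#'   a published value.
#' @param min_samples,min_cluster_size OPTICS density parameters (default 4
#'   and 4). `min_samples` counts the point itself.
#' @param overlap_denominator Which volume the overlap fraction is relative
#'   to: `"nucleus"` (default; fraction of the nucleus captured by the hull)
#'   or `"hull"`.
#' @param p_adjust_method Multiplicity adjustment across the comparisons of a
#'   panel: `"holm"` (default), `"BH"` or `"none"`.
#' @param contrasts Optional list of length-2 character vectors naming group
#'   pairs to compare; `NULL` compares every group against the first.
#' @param seed Integer seed recorded in the run manifest.
#' @return A validated list of class `"run_config"`.
#' @seealso [run_pipeline()], [read_run_config()]
#' @export
run_config <- function(marker_map, eps,
                       K = NULL,
                       crosstalk_tolerance_um = 0.35,
                       min_samples = 4L,
                       min_cluster_size = 4L,
                       overlap_denominator = c("nucleus", "hull"),
                       p_adjust_method = c("holm", "BH", "none"),
                       contrasts = NULL,
                       seed = 1L) {
  if (is.null(names(marker_map)) || any(!nzchar(names(marker_map))))
    stop_fmt("marker_map must be a named vector (gene -> cell type)")
  marker_map <- vapply(marker_map, as.character, "")
  if (anyDuplicated(marker_map))
    stop_fmt("marker_map must be injective: each cell type has one marker gene")
  genes <- names(marker_map)
  types <- unname(marker_map)
  if (is.null(names(eps))) stop_fmt("eps must be named by gene")
  missing_eps <- setdiff(genes, names(eps))
  if (length(missing_eps))
    stop_fmt("no eps configured for gene(s): %s", paste(missing_eps, collapse = ", "))
  if (any(eps <= 0)) stop_fmt("eps must be strictly positive")
  if (is.null(K)) K <- setNames(rep(0.375, length(types)), types)
  missing_K <- setdiff(types, names(K))
  if (length(missing_K))
    stop_fmt("no overlap threshold K for cell type(s): %s",
             paste(missing_K, collapse = ", "))
  if (any(K < 0 | K > 1)) stop_fmt("K must lie in [0, 1]")
  stopifnot(crosstalk_tolerance_um >= 0,
            is_count(min_samples), min_samples >= 1,
            is_count(min_cluster_size), min_cluster_size >= 1,
            is_count(seed))
  overlap_denominator <- match.arg(overlap_denominator)
  p_adjust_method <- match.arg(p_adjust_method)
  if (!is.null(contrasts)) {
    stopifnot(is.list(contrasts),
              all(vapply(contrasts, function(x) is.character(x) && length(x) == 2L, TRUE)))
  }
  structure(list(marker_map = marker_map, eps = eps, K = K,
                 crosstalk_tolerance_um = crosstalk_tolerance_um,
                 min_samples = as.integer(min_samples),
                 min_cluster_size = as.integer(min_cluster_size),
                 overlap_denominator = overlap_denominator,
                 p_adjust_method = p_adjust_method,
                 contrasts = contrasts,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Expected top-level keys mirror the arguments of [run_config()]:
#' `marker_map`, `eps` and `K` as mappings, scalars for the rest, and
#' `contrasts` as a list of two-element lists.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("no such config: %s", path)
  y <- yaml::read_yaml(path)
  need <- setdiff(c("marker_map", "eps"), names(y))
  if (length(need)) stop_fmt("config is missing: %s", paste(need, collapse = ", "))
  run_config(
    marker_map = unlist(y$marker_map),
    eps = unlist(y$eps),
    K = if (!is.null(y$K)) unlist(y$K) else NULL,
    crosstalk_tolerance_um = y$crosstalk_tolerance_um %||% 0.35,
    min_samples = y$min_samples %||% 4L,
    min_cluster_size = y$min_cluster_size %||% 4L,
    overlap_denominator = y$overlap_denominator %||% "nucleus",
    p_adjust_method = y$p_adjust_method %||% "holm",
    contrasts = if (!is.null(y$contrasts)) lapply(y$contrasts, unlist) else NULL,
    seed = y$seed %||% 1L
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config\n")
  cat(sprintf("  crosstalk tolerance: %.3g um; OPTICS min_samples=%d, min_cluster_size=%d\n",
              x$crosstalk_tolerance_um, x$min_samples, x$min_cluster_size))
  for (g in names(x$marker_map))
    cat(sprintf("  %-8s -> %-12s eps=%.3g um  K=%.2f\n", g, x$marker_map[[g]],
                x$eps[[g]], x$K[[x$marker_map[[g]]]]))
  cat(sprintf("  overlap denominator: %s; p adjustment: %s\n",
              x$overlap_denominator, x$p_adjust_method))
  invisible(x)
}
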