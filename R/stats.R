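#' Aggregate per-image quantifications across fields of view
#'
#' Builds one record per analyzed image (field of view) — the statistical
#' unit of all group comparisons — from per-fov cell calls. Markers with no
#' positive nucleus in an image are reported as 0 over the image's nucleus
#' count.
#'
#' @param calls Named list of [call_cell_types()] results, one per fov (names
#'   are fov ids).
#' @param group_map Named character vector mapping fov id to group label;
#'   every fov must be present.
#' @param replicate_map Optional named character vector mapping fov id to
#'   biological replicate id.
#' @return A data frame of class `"image_quantification"` in long format:
#'   `fov`, `group`, `replicate`, `gene`, `cell_type`, `positive`,
#'   `total_nuclei`, `proportion`, `n_coexpressing`, `median_volume_um3`.
#' @export
aggregate_quantifications <- function(calls, group_map, replicate_map = NULL) {
  stopifnot(is.list(calls), length(calls) >= 1L)
  fovs <- names(calls)
  if (is.null(fovs) || any(!nzchar(fovs)))
    stop_fmt("calls must be a named list keyed by fov id")
  missing_grp <- setdiff(fovs, names(group_map))
  if (length(missing_grp))
    stop_fmt("no group label for fov(s): %s", paste(missing_grp, collapse = ", "))
  rows <- lapply(fovs, function(f) {
    cl <- calls[[f]]
    stopifnot(inherits(cl, "cell_calls"))
    s <- cl$summary
    med_vol <- vapply(s$gene, function(g) {
      v <- cl$cells[[paste0("volume_", g, "_um3")]]
      v <- v[!is.na(v)]
      if (length(v)) median(v) else NA_real_
    }, 0)
    data.frame(fov = f, group = unname(group_map[[f]]),
               replicate = if (!is.null(replicate_map))
                 unname(replicate_map[[f]]) else NA_character_,
               gene = s$gene, cell_type = s$cell_type,
               positive = s$positive, total_nuclei = s$total_nuclei,
               proportion = s$proportion,
               n_coexpressing = cl$n_coexpressing,
               median_volume_um3 = unname(med_vol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("image_quantification", "data.frame")
  out
}

#' Two-sided Mann-Whitney-Wilcoxon comparison of two groups of images
#'
#' Compares per-image values (proportions, volumes, counts) between two
#' experimental groups with the two-sided Mann-Whitney U test. The exact
#' null distribution is used when both groups have at most `exact_limit`
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation (with continuity correction) is used.
#'
#' @param values_a,values_b Numeric per-image values of the two groups
#'   (each non-empty).
#' @param exact_limit Largest per-group size for the exact distribution
#'   (default 10).
#' @return A list of class `"group_comparison"`: `U` (the Mann-Whitney
#'   statistic, pairs where an `a` value exceeds a `b` value), `p`
#'   (two-sided), `method` (`"exact"` or `"normal"`), `n_a`, `n_b`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p   # exact: 2/choose(6, 3) = 0.1
compare_groups <- function(values_a, values_b, exact_limit = 10L) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (!length(values_a) || !length(values_b))
    stop_fmt("both groups must be non-empty")
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- !has_ties && length(values_a) <= exact_limit &&
    length(values_b) <= exact_limit
  if (all(values_a == values_a[1]) && all(values_b == values_b[1]) &&
      values_a[1] == values_b[1]) {
    # fully degenerate: identical constant samples; no evidence either way
    w <- list(statistic = length(values_a) * length(values_b) / 2, p.value = 1)
  } else {
    w <- suppressWarnings(wilcox.test(values_a, values_b,
                                      alternative = "two.sided",
                                      exact = use_exact, correct = TRUE))
  }
  structure(list(U = unname(w$statistic), p = w$p.value,
                 method = if (use_exact) "exact" else "normal",
                 n_a = length(values_a), n_b = length(values_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s, n = %d vs %d)\n",
              x$U, x$p, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Adjust p values across the comparisons of one panel
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @param method `"holm"` (default), `"BH"` or `"none"`.
#' @return Adjusted p values (monotone, `>=` raw, `<=` 1).
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_fmt("p values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Star annotation of an adjusted p value
#'
#' Thresholds are strict inequalities: `n/s` for p > 0.05 (and for p = 0.05
#' exactly), `*` for p < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.
#'
#' @param p Numeric vector of adjusted p values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_fmt("p values must lie in [0, 1]")
  vapply(p, function(x) {
    if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 1e-2) "**"
    else if (x < 0.05) "*"
    else "n/s"
  }, "")
}

#' Compare a quantity between groups across a set of contrasts
#'
#' Runs [compare_groups()] for each requested pair of groups on per-image
#' values of one quantity, adjusts the p values across the panel and adds
#' star labels.
#'
#' @param quant An [aggregate_quantifications()] data frame.
#' @param gene Marker gene whose per-image values are compared.
#' @param value Column to compare: `"proportion"` (default),
#'   `"median_volume_um3"`, `"positive"` or `"n_coexpressing"`.
#' @param contrasts List of length-2 character vectors of group labels;
#'   `NULL` compares every other group against the first group level.
#' @param p_adjust_method Passed to [adjust_pvalues()].
#' @return A data frame of class `"comparison_table"`: `gene`, `value`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p`, `p_adj`, `stars`,
#'   `method`, with the adjustment method in `attr(, "p_adjust_method")`.
#' @export
compare_panel <- function(quant, gene, value = "proportion", contrasts = NULL,
                          p_adjust_method = "holm") {
  stopifnot(value %in% names(quant))
  q <- quant[quant$gene == gene, , drop = FALSE]
  if (!nrow(q)) stop_fmt("no quantifications for gene '%s'", gene)
  groups <- unique(q$group)
  if (is.null(contrasts)) {
    if (length(groups) < 2L) stop_fmt("need at least two groups to compare")
    contrasts <- lapply(groups[-1], function(g) c(groups[1], g))
  }
  rows <- lapply(contrasts, function(ct) {
    va <- q[[value]][q$group == ct[1]]
    vb <- q[[value]][q$group == ct[2]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    cmp <- compare_groups(va, vb)
    data.frame(gene = gene, value = value,
               group_a = ct[1], group_b = ct[2],
               n_a = cmp$n_a, n_b = cmp$n_b, U = cmp$U, p = cmp$p,
               method = cmp$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, p_adjust_method)
  out$stars <- star_annotation(out$p_adj)
  rownames(out) <- NULL
  attr(out, "p_adjust_method") <- p_adjust_method
  class(out) <- c("comparison_table", "data.frame")
  out
}
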