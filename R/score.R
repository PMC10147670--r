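#' Per-cell gene-signature score
#'
#' For each signature gene present in the matrix, the expression values are
#' centered (mean across cells subtracted) and normalized (divided by the
#' standard deviation across cells); the score of a cell is the mean of
#' these standardized values over the genes used. Genes absent from the
#' matrix are dropped with a warning, as are zero-variance genes (whose
#' standardized values would be undefined). When no genes are dropped the
#' grand mean of the scores over all cells is 0 by construction, and the
#' score is invariant to per-gene affine transforms with positive scale.
#'
#' @param matrix Numeric genes-by-cells matrix with unique gene and cell
#'   names (see [read_expression_matrix()]).
#' @param gene_set Character vector of signature genes; its intersection with
#'   the matrix genes must be non-empty.
#' @param sd_type Standard-deviation estimator: `"sample"` (n - 1, default)
#'   or `"population"` (n).
#' @return An object of class `"signature_score"`: `score` (named numeric,
#'   one value per cell), `genes_used`, `genes_missing`,
#'   `genes_zero_variance`.
#' @export
#' @examples
#' m <- rbind(g1 = c(1, 3))
#' colnames(m) <- c("c1", "c2")
#' score_cells(m, "g1")$score   # (-1, 1) / sqrt(2) * sqrt(2) -> -0.707, 0.707
score_cells <- function(matrix, gene_set, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) stop_fmt("matrix must have gene rownames")
  if (ncol(matrix) < 2L) stop_fmt("need at least 2 cells to standardize")
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, rownames(matrix))
  missing <- setdiff(gene_set, rownames(matrix))
  if (!length(present))
    stop_fmt("none of the %d signature genes are in the matrix", length(gene_set))
  if (length(missing))
    warning(sprintf("%d signature gene(s) not in the matrix were dropped",
                    length(missing)), call. = FALSE)
  sub <- matrix[present, , drop = FALSE]
  mu <- rowMeans(sub)
  n <- ncol(sub)
  ss <- rowSums((sub - mu)^2)
  s <- sqrt(ss / if (sd_type == "sample") (n - 1) else n)
  zero_var <- s <= 0 | !is.finite(s)
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene(s) dropped from the signature",
                    sum(zero_var)), call. = FALSE)
    sub <- sub[!zero_var, , drop = FALSE]
    mu <- mu[!zero_var]; s <- s[!zero_var]
    if (!nrow(sub)) stop_fmt("all signature genes have zero variance")
  }
  z <- (sub - mu) / s
  score <- colMeans(z)
  structure(list(score = score, genes_used = rownames(sub),
                 genes_missing = missing,
                 genes_zero_variance = present[zero_var],
                 sd_type = sd_type),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("signature_score: %d cells, %d gene(s) used (%d missing, %d zero-variance)\n",
              length(x$score), length(x$genes_used), length(x$genes_missing),
              length(x$genes_zero_variance)))
  print(summary(unname(x$score)))
  invisible(x)
}

#' Summarize signature scores per condition
#'
#' @param scores A [score_cells()] result or a named numeric vector of
#'   per-cell scores.
#' @param conditions Named character vector (cell -> condition label) or a
#'   vector aligned with the scores; every scored cell must be labeled.
#' @param order Optional character vector giving the reporting order of the
#'   conditions (e.g. control first, then time points); defaults to order of
#'   first appearance.
#' @return A data frame, one row per condition in the requested order: `n`,
#'   `mean`, `sd`, `median`, `q25`, `q75`.
#' @export
score_dynamics <- function(scores, conditions, order = NULL) {
  s <- if (inherits(scores, "signature_score")) scores$score else scores
  stopifnot(is.numeric(s))
  if (!is.null(names(conditions)) && !is.null(names(s))) {
    unlabeled <- setdiff(names(s), names(conditions))
    if (length(unlabeled))
      stop_fmt("unlabeled cell(s): %s", paste(head(unlabeled, 3), collapse = ", "))
    cond <- unname(conditions[names(s)])
  } else {
    if (length(conditions) != length(s))
      stop_fmt("conditions must label every cell (%d labels for %d cells)",
               length(conditions), length(s))
    cond <- as.character(conditions)
  }
  if (anyNA(cond)) stop_fmt("conditions contain NA")
  if (is.null(order)) order <- unique(cond)
  extra <- setdiff(cond, order)
  if (length(extra))
    stop_fmt("condition(s) missing from `order`: %s", paste(extra, collapse = ", "))
  rows <- lapply(order, function(g) {
    v <- s[cond == g]
    data.frame(condition = g, n = length(v),
               mean = mean(v), sd = sd(v), median = median(v),
               q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
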