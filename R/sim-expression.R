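#' Generate a synthetic expression matrix with a planted signature
#'
#' Draws log-normal-like expression counts for `n_genes` x `n_cells` and
#' plants a signature: half of the cells ("high" class) receive a
#' multiplicative `effect_size` on the signature genes. With
#' `effect_size = 1` the two classes are exchangeable.
#'
#' @param n_genes,n_cells Matrix dimensions (`n_cells >= 2`).
#' @param signature_genes Character vector of gene names carrying the
#'   effect; must be a subset of the generated gene names
#'   (`gene1..gene<n_genes>`), or an integer count, in which case the first
#'   so-many genes are used.
#' @param effect_size Multiplicative effect on signature genes in high cells
#'   (> 0).
#' @param seed Integer seed; output is reproducible from it.
#' @param sdlog Log-scale standard deviation of the base expression.
#' @return A list: `matrix` (genes x cells, named), `signature_genes`,
#'   `class` (named character per cell, `"high"`/`"low"`),
#'   `effect_size`.
#' @export
generate_expression_matrix <- function(n_genes, n_cells, signature_genes,
                                       effect_size, seed = 1L, sdlog = 0.8) {
  stopifnot(is_count(n_genes), n_genes >= 1,
            is_count(n_cells), n_cells >= 2,
            is_count(seed))
  if (effect_size <= 0) stop_fmt("effect_size must be > 0")
  genes <- paste0("gene", seq_len(n_genes))
  if (is.numeric(signature_genes) && length(signature_genes) == 1L) {
    stopifnot(signature_genes >= 1, signature_genes <= n_genes)
    signature_genes <- genes[seq_len(signature_genes)]
  }
  bad <- setdiff(signature_genes, genes)
  if (length(bad))
    stop_fmt("signature gene(s) not among generated genes: %s",
             paste(head(bad, 3), collapse = ", "))
  cells <- paste0("cell", seq_len(n_cells))
  with_seed(seed, {
    m <- matrix(rlnorm(n_genes * n_cells, meanlog = 1, sdlog = sdlog),
                n_genes, n_cells, dimnames = list(genes, cells))
    cls <- setNames(rep(c("low", "high"), length.out = n_cells), cells)
    cls <- setNames(sample(cls), cells)   # random class placement
    hi <- names(cls)[cls == "high"]
    m[signature_genes, hi] <- m[signature_genes, hi] * effect_size
    list(matrix = m, signature_genes = signature_genes, class = cls,
         effect_size = effect_size)
  })
}

#' Generate probe-candidate pools with known rule violations
#'
#' Emits random DNA sequences constructed either to pass every composition
#' rule of [check_composition_rules()] (and, optionally, the free-energy
#' band) or to violate one named rule, for testing the probe filter.
#'
#' @param n Number of sequences (0 gives an empty pool).
#' @param length_range Length range, within `[10, 60]`.
#' @param violate `NULL` for all-rules-passing sequences, or one of
#'   `"AAAA"`, `"GC"`, `"A_comp"`, `"C_comp"`, `"CCCC_first12"`,
#'   `"nonconsecC_first12"` to construct sequences violating that rule.
#' @param ensure_dg_band For all-passing pools, also require the
#'   per-nucleotide free-energy score to lie in the default band.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per sequence; exhaustion is an
#'   error (impossible constraint combination).
#' @return Character vector of sequences with attribute `violate`.
#' @export
generate_probe_pool <- function(n, length_range = c(26L, 32L), violate = NULL,
                                ensure_dg_band = TRUE, seed = 1L,
                                max_tries = 5000L) {
  stopifnot(is_count(n))
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  if (length_range[1] < 10L || length_range[2] > 60L ||
      length_range[1] > length_range[2])
    stop_fmt("length_range must be within [10, 60]")
  rules <- c("AAAA", "GC", "A_comp", "C_comp", "CCCC_first12",
             "nonconsecC_first12")
  if (!is.null(violate) && !violate %in% rules)
    stop_fmt("unknown rule '%s'; choose from: %s", violate,
             paste(rules, collapse = ", "))
  if (n == 0L) return(structure(character(0), violate = violate))
  # base composition biased toward rule-passing probes
  probs <- c(A = 0.18, C = 0.25, G = 0.30, T = 0.27)
  draw <- function(L) paste(sample(names(probs), L, TRUE, probs), collapse = "")
  out <- character(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        L <- sample(length_range[1]:length_range[2], 1L)
        s <- draw(L)
        fl <- check_composition_rules(s, len_min = length_range[1],
                                      len_max = length_range[2])
        if (is.null(violate)) {
          good <- all(fl) &&
            (!ensure_dg_band || dg_band_pass(dg37_score(s)))
        } else if (violate == "AAAA") {
          # plant an AAAA stack into an otherwise passing sequence
          if (!all(fl[setdiff(names(fl), "AAAA")])) next
          pos <- sample(seq_len(L - 3L), 1L)
          s <- paste0(substr(s, 1, pos - 1L), "AAAA", substr(s, pos + 4L, L))
          good <- grepl("AAAA", s, fixed = TRUE)
        } else {
          good <- !fl[[violate]]
        }
        if (good) { out[i] <- s; ok <- TRUE; break }
      }
      if (!ok)
        stop_fmt("could not construct a sequence %s after %d tries",
                 if (is.null(violate)) "passing all rules"
                 else sprintf("violating '%s'", violate), max_tries)
    }
  })
  structure(out, violate = violate)
}
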