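# Unified DNA/DNA nearest-neighbor free energies at 37 C (kcal/mol),
# SantaLucia (1998) unified parameter set; keys read 5'->3' on one strand.
NN_DG37 <- c(
  AA = -1.00, AT = -0.88, TA = -0.58, TT = -1.00,
  CA = -1.45, AC = -1.44, GT = -1.44, TG = -1.45,
  CT = -1.28, TC = -1.30, GA = -1.30, AG = -1.28,
  CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
NN_INIT_GC <- 0.98   # initiation with a terminal G.C pair
NN_INIT_AT <- 1.03   # initiation with a terminal A.T pair
NN_SYMMETRY <- 0.43  # self-complementary duplex correction

#' Default FLAP Y readout sequence
#'
#' The shared readout sequence appended to every gene-specific probe, to
#' which the fluorophore-carrying secondary oligo pre-hybridizes. The
#' default is the published Y readout; it is configuration, not a constant
#' of the method.
#' @export
FLAP_Y <- "AATGCATGTCGACGAGGTCCGAGTGTAA"

check_dna <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop_fmt("empty sequence")
  if (grepl("[^ACGT]", seq))
    stop_fmt("sequence contains non-ACGT character(s): %s",
             gsub("[ACGT]", "", seq))
  seq
}

revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

#' Probe composition rules
#'
#' Evaluates the per-candidate composition filter on one sequence:
#' length within `[len_min, len_max]`; GC fraction within
#' `[gc_min, gc_max]`; A fraction strictly below `a_max`; no `AAAA` stack
#' anywhere; C fraction within `[c_min, c_max]`; within the first 12
#' positions, no window of 6 consecutive nucleotides containing `CCCC`, and
#' none containing 4 or more C in total.
#'
#' @param seq DNA string (A/C/G/T only; anything else is an error).
#' @param len_min,len_max,gc_min,gc_max,a_max,c_min,c_max Rule bounds;
#'   defaults are the published filter (26-32 nt, GC 40-60% inclusive,
#'   A < 28% strict, C 22-28% inclusive).
#' @return Named logical vector of pass flags: `length`, `GC`, `A_comp`,
#'   `AAAA`, `C_comp`, `CCCC_first12`, `nonconsecC_first12`, plus the
#'   attribute `gc` (GC fraction).
#' @export
#' @examples
#' check_composition_rules("GCGCAAAAGCGCGCGCGCGCGCGCGC")[["AAAA"]]  # FALSE
check_composition_rules <- function(seq, len_min = 26L, len_max = 32L,
                                    gc_min = 0.40, gc_max = 0.60,
                                    a_max = 0.28, c_min = 0.22, c_max = 0.28) {
  seq <- check_dna(seq)
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  nA <- sum(ch == "A"); nC <- sum(ch == "C"); nG <- sum(ch == "G")
  prefix <- substr(seq, 1L, min(12L, L))
  np <- nchar(prefix)
  if (np >= 6L) {
    wins <- substring(prefix, 1:(np - 5L), 6:np)
    cccc_ok <- !any(grepl("CCCC", wins, fixed = TRUE))
    c4_ok <- all(vapply(wins, function(w)
      sum(strsplit(w, "")[[1]] == "C") < 4L, TRUE))
  } else {
    cccc_ok <- !grepl("CCCC", prefix, fixed = TRUE)
    c4_ok <- sum(strsplit(prefix, "")[[1]] == "C") < 4L
  }
  gc_fr <- (nG + nC) / L
  flags <- c(
    length = L >= len_min && L <= len_max,
    GC = gc_fr >= gc_min && gc_fr <= gc_max,
    A_comp = nA / L < a_max,
    AAAA = !grepl("AAAA", seq, fixed = TRUE),
    C_comp = nC / L >= c_min && nC / L <= c_max,
    CCCC_first12 = cccc_ok,
    nonconsecC_first12 = c4_ok)
  attr(flags, "gc") <- gc_fr
  flags
}

#' Nearest-neighbor duplex free energy at 37 C
#'
#' Stacking free energy of the perfect DNA/DNA duplex formed by `seq` and
#' its complement, from the unified nearest-neighbor table, including duplex
#' initiation terms and the self-complementarity correction.
#'
#' @param seq DNA string, length >= 2.
#' @return Free energy in kcal/mol (negative; more negative = more stable).
#' @export
dg37 <- function(seq) {
  seq <- check_dna(seq)
  L <- nchar(seq)
  if (L < 2L) stop_fmt("dg37 needs a sequence of length >= 2")
  stacks <- substring(seq, 1:(L - 1L), 2:L)
  g <- sum(NN_DG37[stacks])
  ends <- substr(seq, 1L, 1L)
  ends <- c(ends, substr(seq, L, L))
  g <- g + sum(ifelse(ends %in% c("G", "C"), NN_INIT_GC, NN_INIT_AT))
  if (identical(seq, revcomp(seq))) g <- g + NN_SYMMETRY
  g
}

#' Per-nucleotide duplex stability score
#'
#' The per-nucleotide nearest-neighbor free energy of `seq` expressed as a
#' fraction of a reference per-nucleotide value; the probe filter keeps
#' candidates whose score lies within `dg_band` of the target `dg_target`
#' (by default around 0.90, i.e. 90% of the reference stability).
#'
#' @param seq DNA string, length >= 2.
#' @param reference_per_nt Reference per-nucleotide free energy in kcal/mol
#'   (default -1.55, the stability of a GC-rich duplex).
#' @return Dimensionless score in `[0, Inf)`; larger = more stable per nt.
#' @export
dg37_score <- function(seq, reference_per_nt = -1.55) {
  if (reference_per_nt >= 0) stop_fmt("reference_per_nt must be negative")
  (dg37(seq) / nchar(check_dna(seq))) / reference_per_nt
}

dg_band_pass <- function(score, dg_target = 0.90, dg_band = 0.10) {
  abs(score - dg_target) <= dg_band
}

#' Design smFISH probes against a target transcript
#'
#' Enumerates every substring of length `len_min` to `len_max` of the target
#' (the mRNA sense sequence), keeps the candidates passing all composition
#' rules ([check_composition_rules()]) and the per-nucleotide free-energy
#' band ([dg37_score()]), then greedily selects probes by closeness to the
#' free-energy target subject to a minimum separation of `min_gap`
#' unhybridized nucleotides between the target footprints of selected
#' probes, up to `n_probes`. Each selected probe is emitted as the reverse
#' complement of its target window (the hybridizing strand) with the shared
#' FLAP readout appended.
#'
#' @param target Target transcript sequence (sense strand), length >= 26.
#' @param flap Readout sequence appended to each probe (default [FLAP_Y]).
#' @param n_probes Maximum number of probes to select (default 30).
#' @param min_gap Minimum nucleotides between adjacent selected footprints
#'   (default 2).
#' @param len_min,len_max Candidate length range.
#' @param dg_target,dg_band,reference_per_nt Free-energy band parameters
#'   (see [dg37_score()]).
#' @param target_id Identifier carried into the output.
#' @return A data frame of class `"probe_set"`, one row per candidate:
#'   `target`, `start`, `end` (0-based half-open on the target), `length`,
#'   `sequence` (target window), `probe` (reverse complement),
#'   `full_probe` (probe + FLAP), `gc`, `dg_score`, the per-rule pass flags
#'   (`rule_length`, `rule_GC`, `rule_A_comp`, `rule_AAAA`, `rule_C_comp`,
#'   `rule_CCCC_first12`, `rule_nonconsecC_first12`, `rule_dG_score`),
#'   `pass_all` and `selected`. A warning is issued
#'   when no candidate passes.
#' @export
design_probes <- function(target, flap = FLAP_Y, n_probes = 30L, min_gap = 2L,
                          len_min = 26L, len_max = 32L,
                          dg_target = 0.90, dg_band = 0.10,
                          reference_per_nt = -1.55,
                          target_id = "target") {
  target <- check_dna(target)
  L <- nchar(target)
  if (L < len_min)
    stop_fmt("target (%d nt) is shorter than the minimum probe length %d",
             L, len_min)
  if (nzchar(flap)) flap <- check_dna(flap)
  cand <- list()
  for (w in len_min:min(len_max, L)) {
    starts <- 0:(L - w)
    for (s in starts) {
      sq <- substr(target, s + 1L, s + w)
      flags <- check_composition_rules(sq, len_min = len_min, len_max = len_max)
      sc <- dg37_score(sq, reference_per_nt)
      row <- data.frame(
        target = target_id, start = s, end = s + w, length = w,
        sequence = sq, gc = attr(flags, "gc"), dg_score = sc,
        stringsAsFactors = FALSE)
      fl <- c(as.list(flags), list(dG_score = dg_band_pass(sc, dg_target, dg_band)))
      names(fl) <- paste0("rule_", names(fl))
      cand[[length(cand) + 1L]] <- cbind(row, as.data.frame(fl))
    }
  }
  out <- do.call(rbind, cand)
  rule_cols <- paste0("rule_", c("length", "GC", "A_comp", "AAAA", "C_comp",
                                 "CCCC_first12", "nonconsecC_first12", "dG_score"))
  out$pass_all <- rowSums(!out[rule_cols]) == 0L
  out$selected <- FALSE
  passing <- which(out$pass_all)
  if (!length(passing)) {
    warning(sprintf("no probe candidate passes all rules on '%s'", target_id),
            call. = FALSE)
  } else {
    ord <- passing[order(abs(out$dg_score[passing] - dg_target),
                         out$start[passing])]
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) >= n_probes) break
      ok <- all(out$start[i] >= out$end[sel] + min_gap |
                  out$end[i] + min_gap <= out$start[sel])
      if (ok) sel <- c(sel, i)
    }
    out$selected[sel] <- TRUE
  }
  out$probe <- revcomp(out$sequence)
  out$full_probe <- paste0(out$probe, flap)
  rownames(out) <- NULL
  attr(out, "flap") <- flap
  class(out) <- c("probe_set", "data.frame")
  out
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set on '%s': %d candidates, %d pass all rules, %d selected\n",
              x$target[1], nrow(x), sum(x$pass_all), sum(x$selected)))
  invisible(x)
}

#' Design probes for every record of a FASTA file
#'
#' @param fasta_path FASTA of target transcript sequences.
#' @param ... Passed to [design_probes()].
#' @return A single `probe_set` data frame covering all records.
#' @export
design_probes_fasta <- function(fasta_path, ...) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) stop_fmt("no sequences in %s", fasta_path)
  res <- lapply(seq_along(seqs), function(i)
    design_probes(as.character(seqs[[i]]), target_id = names(seqs)[i], ...))
  out <- do.call(rbind, res)
  class(out) <- c("probe_set", "data.frame")
  out
}
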