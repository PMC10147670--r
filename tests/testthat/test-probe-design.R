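test_that("composition rules follow the published filter exactly", {
  f <- check_composition_rules("GCGCAAAAGCGCGCGCGCGCGCGCGC")
  expect_false(f[["AAAA"]])
  # 26 nt with A and C fractions inside the stated bands
  sA <- paste(c(rep(c("A", "C", "G", "T"), 6), "G", "C"), collapse = "")
  f2 <- check_composition_rules(sA)
  expect_true(f2[["A_comp"]])   # 6/26 = 23.1% < 28%
  expect_true(f2[["C_comp"]])   # 7/26 = 26.9% in [22, 28]
  expect_true(f2[["length"]])
  expect_error(check_composition_rules("ACGTN"), "non-ACGT")
  # C-window rules act only on the first 12 positions
  late_c <- paste0(paste(rep("GATG", 3), collapse = ""),   # clean prefix
                   "CCCC", paste(rep("GAT", 4), collapse = ""))
  f3 <- check_composition_rules(late_c)
  expect_true(f3[["CCCC_first12"]])
  early_c <- paste0("GACCCCGATGAT", paste(rep("GATG", 4), collapse = ""))
  f4 <- check_composition_rules(early_c)
  expect_false(f4[["CCCC_first12"]])
  expect_false(f4[["nonconsecC_first12"]])
  # 4 nonconsecutive C within one 6-window of the prefix
  nc <- paste0("CACACCGATGAT", paste(rep("GATG", 4), collapse = ""))
  f5 <- check_composition_rules(nc)
  expect_true(f5[["CCCC_first12"]])
  expect_false(f5[["nonconsecC_first12"]])
})

test_that("rule flags agree with the naive re-scanning checker", {
  set.seed(77)
  seqs <- vapply(1:1000, function(i) {
    L <- sample(26:32, 1)
    paste(sample(c("A", "C", "G", "T"), L, TRUE,
                 prob = c(0.3, 0.25, 0.2, 0.25)), collapse = "")
  }, "")
  for (s in seqs) {
    got <- check_composition_rules(s)
    want <- oracle_probe_flags(s)
    expect_identical(unname(got[names(want)]), unname(want))
  }
})

test_that("nearest-neighbor free energy is stable under reverse complement", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    rc <- fishcall:::revcomp(s)
    expect_equal(dg37(s), dg37(rc), tolerance = 1e-12)
  }
  # GC-rich duplexes are more stable per nt than AT-rich ones
  expect_gt(abs(dg37(strrep("GC", 14)) / 28), abs(dg37(strrep("AT", 14)) / 28))
  # homopolymer falls outside the default stability band
  expect_false(fishcall:::dg_band_pass(dg37_score(strrep("A", 28))))
  expect_error(dg37("A"), "length")
})

test_that("probe design selects passing, well-spaced probes", {
  expect_error(design_probes(strrep("ACGT", 5)), "shorter")

  # an all-rules-passing window embedded in AAAA-poisoned context: every
  # passing candidate overlaps the planted region, so exactly one survives
  # the spacing rule and it covers the planted window
  win <- as.character(generate_probe_pool(1, length_range = c(28, 28),
                                          seed = 42))
  target <- paste0(strrep("A", 40), win, strrep("A", 40))
  ps <- design_probes(target, target_id = "t1")
  expect_true(any(ps$pass_all & ps$sequence == win))
  sel <- ps[ps$selected, ]
  expect_equal(nrow(sel), 1L)
  expect_gte(sel$start, 40 - 3)
  expect_lte(sel$end, 40 + nchar(win) + 3)
  # emitted probe is the reverse complement plus the FLAP readout
  expect_equal(sel$probe, fishcall:::revcomp(sel$sequence))
  expect_equal(sel$full_probe, paste0(fishcall:::revcomp(sel$sequence), FLAP_Y))

  # spacing: >= 2 nt between any two selected footprints on a long target
  set.seed(11)
  long <- paste(generate_probe_pool(14, length_range = c(30, 30), seed = 9),
                collapse = "")
  ps2 <- design_probes(long)
  sel2 <- ps2[ps2$selected, ]
  sel2 <- sel2[order(sel2$start), ]
  if (nrow(sel2) > 1)
    expect_true(all(sel2$start[-1] - sel2$end[-nrow(sel2)] >= 2))
  expect_true(all(sel2$pass_all))

  # no passing candidate: empty selection with a warning
  expect_warning(none <- design_probes(strrep("AT", 20)), "no probe candidate")
  expect_equal(sum(none$selected), 0L)
})

test_that("selection is a pure function and rule loosening is monotone", {
  set.seed(23)
  target <- paste(generate_probe_pool(6, length_range = c(30, 30), seed = 5),
                  collapse = "")
  a <- design_probes(target)
  b <- design_probes(target)
  expect_identical(a, b)

  n_pass <- function(...) {
    set.seed(99)
    seqs <- vapply(1:300, function(i)
      paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = ""), "")
    sum(vapply(seqs, function(s) all(check_composition_rules(s, ...)), TRUE))
  }
  base <- n_pass()
  expect_gte(n_pass(a_max = 0.40), base)      # loosen A rule
  expect_gte(n_pass(gc_min = 0.30), base)     # loosen GC lower bound
  expect_gte(n_pass(c_min = 0.10, c_max = 0.40), base)  # loosen C band
})

test_that("FASTA targets are designed per record", {
  fa <- withr::local_tempfile(fileext = ".fa")
  t1 <- paste(generate_probe_pool(4, length_range = c(30, 30), seed = 1),
              collapse = "")
  t2 <- paste(generate_probe_pool(4, length_range = c(30, 30), seed = 2),
              collapse = "")
  writeLines(c(">geneA", t1, ">geneB", t2), fa)
  ps <- design_probes_fasta(fa)
  expect_setequal(unique(ps$target), c("geneA", "geneB"))
  expect_gt(sum(ps$selected[ps$target == "geneA"]), 0)
})
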