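make_test_unit <- function(backbone, ids) {
  build_units(backbone, list(ids))[[1]]
}

test_that("an empty batch returns the subalignment itself, fully labeled", {
  set.seed(2)
  backbone <- random_alignment(6, 15, gap_prob = 0.2)
  unit <- make_test_unit(backbone, alignment_ids(backbone))
  ext <- extend_fallback(unit, setNames(character(0), character(0)))
  expect_identical(ext$alignment$seqs, unit$subalignment$seqs)
  expect_false(anyNA(ext$labels))
  expect_identical(ext$labels, unit$map)
})

test_that("the fallback adder reproduces a backbone row's gapped layout on an all-match model", {
  # gap-free backbone -> every column is a match state
  set.seed(6)
  backbone <- random_alignment(4, 12, gap_prob = 0)
  unit <- make_test_unit(backbone, alignment_ids(backbone))
  expect_equal(unit$hmm$M, 12L)
  rid <- alignment_ids(backbone)[2]
  q <- setNames(ungap(backbone)[rid], "copy")
  ext <- extend_fallback(unit, q)
  expect_identical(ext$alignment$seqs[["copy"]], backbone$seqs[[rid]])
})

test_that("Viterbi best-path probability matches exhaustive enumeration on tiny models", {
  set.seed(88)
  for (rep in 1:30) {
    hmm <- random_tiny_hmm()
    q <- paste0(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
                collapse = "")
    idx <- match(strsplit(q, "")[[1]], hmm$letters) - 1L
    vit <- msaextend:::viterbi_path_cpp(hmm$match_log, hmm$insert_log,
                                        hmm$trans_log, idx, log(0.2))
    expect_lt(abs(vit$logprob - log(oracle_viterbi_prob(hmm, q))), 1e-9)
  }
})

test_that("fallback extensions induce the subalignment and conserve every letter", {
  set.seed(14)
  for (rep in 1:8) {
    backbone <- random_alignment(sample(4:8, 1), sample(10:25, 1), gap_prob = 0.25)
    unit <- make_test_unit(backbone, alignment_ids(backbone))
    nq <- sample(1:5, 1)
    batch <- setNames(
      vapply(seq_len(nq), function(i)
        paste0(sample(c("A", "C", "G", "T"), sample(5:20, 1), replace = TRUE),
               collapse = ""), character(1)),
      paste0("q", seq_len(nq)))
    ext <- extend_fallback(unit, batch)
    expect_true(induces(ext$alignment, unit$subalignment))
    expect_identical(ungap(ext$alignment)[names(batch)], batch)
    lab <- ext$labels[!is.na(ext$labels)]
    expect_true(all(diff(lab) > 0))
    # insertion anchors point at the nearest preceding labeled column
    expect_true(all(is.na(ext$anchors) == !is.na(ext$labels)))
  }
})

test_that("the external MAFFT backend is validated and labeled correctly", {
  set.seed(26)
  sim <- simulate_sequences(sim_params(n = 12, root_length = 50), seed = 26)
  ids <- alignment_ids(sim$alignment)
  unit <- make_test_unit(sim$alignment, ids[1:8])
  batch <- ungap(sim$alignment)[ids[9:12]]
  ext <- extend_external(unit, batch)
  expect_true(induces(ext$alignment, unit$subalignment))
  expect_identical(sort(ungap(ext$alignment)[names(batch)]), sort(batch))
  lab <- ext$labels[!is.na(ext$labels)]
  expect_identical(as.integer(lab), unit$map)
})

test_that("outputs that break the extension contract are rejected", {
  set.seed(9)
  backbone <- random_alignment(4, 10, gap_prob = 0.1)
  unit <- make_test_unit(backbone, alignment_ids(backbone))
  # backend that silently drops the queries -> wrong sequence set
  expect_error(extend_external(unit, c(qq = "ACGTACGT"),
                               backend_cmd = "cp {backbone} {output}"),
               "expected sequences")
  # constraint-violating alignment: two backbone letters moved into one column
  cons <- alignment(c(x = "AC", y = "AC"), "nucleotide")
  u2 <- build_units(cons, list(c("x", "y")))[[1]]
  moved <- alignment(c(x = "A-C", y = "-AC", qq = "AGC"), "nucleotide",
                     normalize = FALSE)
  expect_error(extended_subalignment(moved, c(1L, NA, 2L), u2),
               "contract")
  # non-increasing labels are caught before anything else
  expect_error(extended_subalignment(moved, c(2L, NA, 1L), u2),
               "increasing")
})
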