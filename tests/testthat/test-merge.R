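# builds a full set of extended subalignments for a random backbone with
# the fallback adder, returning everything the merge needs
fallback_extensions <- function(backbone, queries, l = 4L, u = 8L) {
  tree <- kmer_guide_tree(backbone)
  units <- build_units(backbone, decompose_tree(tree, l = l, u = u))
  asg <- assign_queries(units, queries)
  ext <- list()
  for (i in seq_along(units)) {
    qs <- queries[asg$query[asg$unit == i]]
    ext[[i]] <- extend_fallback(units[[i]], qs)
  }
  list(units = units, extended = ext)
}

test_that("a single extended subalignment merges to itself", {
  set.seed(41)
  backbone <- random_alignment(5, 14, gap_prob = 0.2)
  unit <- build_units(backbone, list(alignment_ids(backbone)))[[1]]
  batch <- c(q1 = "ACGTTACG", q2 = "GGCATT")
  ext <- extend_fallback(unit, batch)
  out <- merge_extensions(list(ext), backbone, query_order = names(batch))
  expect_identical(drop_allgap_columns(out)$seqs[names(ext$alignment$seqs)],
                   drop_allgap_columns(ext$alignment)$seqs)
})

test_that("with no insertion columns the merge is the constraint plus rows", {
  cons <- alignment(c(a = "ACGT", b = "AC-T", c = "A-GT", d = "ACG-"),
                    "nucleotide")
  units <- build_units(cons, list(c("a", "b"), c("c", "d")))
  # queries identical to backbone rows of gap-free positions align into
  # match columns only on these tiny models
  e1 <- extend_fallback(units[[1]], c(q1 = "ACT"))
  e2 <- extend_fallback(units[[2]], c(q2 = "AGT"))
  if (!anyNA(c(e1$labels, e2$labels))) {
    out <- merge_extensions(list(e1, e2), cons)
    expect_equal(n_columns(out), n_columns(cons))
    expect_identical(out$seqs[alignment_ids(cons)], cons$seqs)
  } else succeed("queries opened insertion columns on this model")
})

test_that("the merged output induces the constraint and conserves letters on random fixtures", {
  set.seed(52)
  for (rep in 1:6) {
    backbone <- random_alignment(sample(8:16, 1), sample(15:30, 1),
                                 gap_prob = 0.2)
    nq <- sample(3:8, 1)
    queries <- setNames(
      vapply(seq_len(nq), function(i)
        paste0(sample(c("A", "C", "G", "T"), sample(8:25, 1), replace = TRUE),
               collapse = ""), character(1)),
      paste0("q", seq_len(nq)))
    fx <- fallback_extensions(backbone, queries)
    out <- merge_extensions(fx$extended, backbone, query_order = names(queries))
    expect_true(induces(out, backbone))
    expect_identical(ungap(out)[names(queries)], queries)
    expect_identical(alignment_ids(out),
                     c(alignment_ids(backbone), names(queries)))
    # restriction oracle: each subproblem's rows reproduce its extension
    for (e in fx$extended) {
      eids <- alignment_ids(e$alignment)
      restr <- induce_subalignment(out, eids)$alignment
      expect_identical(restr$seqs, drop_allgap_columns(e$alignment)$seqs)
    }
  }
})

test_that("duplicate or non-partitioning subproblem rows are rejected", {
  cons <- alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                    "nucleotide")
  units <- build_units(cons, list(c("a", "b"), c("c", "d")))
  e1 <- extend_fallback(units[[1]], c(q1 = "ACG"))
  e2 <- extend_fallback(units[[2]], c(q2 = "CGT"))
  expect_error(merge_extensions(list(e1, e1), cons), "more than one|partition")
  expect_error(merge_extensions(list(e1), cons), "partition")
})
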