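test_that("match columns and smoothed emissions follow the closed form", {
  aln <- alignment(c(a = "A", b = "A"), "nucleotide")
  hmm <- build_hmm(aln)
  expect_equal(hmm$M, 1L)
  expect_equal(unname(exp(hmm$match_log[1, "A"])), 3 / 7)  # (2+1)/(2+5)

  # a column with 3 gaps out of 4 rows is not a match column
  aln2 <- alignment(c(a = "AC", b = "A-", c = "A-", d = "A-"), "nucleotide")
  hmm2 <- build_hmm(aln2)
  expect_equal(hmm2$M, 1L)
  expect_equal(hmm2$match_columns, 1L)

  expect_error(build_hmm(alignment(c(a = "A---", b = "-C--", c = "--G-",
                                     d = "---T"), "nucleotide")),
               "degenerate")
})

test_that("emission and transition distributions are normalized", {
  set.seed(21)
  for (rep in 1:10) {
    hmm <- random_buildable_hmm(sample(2:6, 1), sample(2:10, 1))
    expect_true(all(abs(rowSums(exp(hmm$match_log)) - 1) < 1e-9))
    expect_lt(abs(sum(exp(hmm$bg_log)) - 1), 1e-9)
    for (k in 0:hmm$M) for (from in c("M", "I", "D")) {
      if (from == "D" && k == 0) next
      cols <- paste0(from, c("M", "I", "D"))
      s <- sum(exp(hmm$trans_log[k + 1, cols]))
      expect_lt(abs(s - 1), 1e-9)
    }
  }
})

test_that("transition probabilities equal hand-enumerated state-path counts on a toy alignment", {
  # columns: M I M M (gap fractions 0, .75, .25, 0 of 4 rows)
  aln <- alignment(c(r1 = "ACAA", r2 = "A-CA", r3 = "G--A", r4 = "T-AA"),
                   "nucleotide")
  hmm <- build_hmm(aln)
  expect_equal(hmm$M, 3L)
  expect_equal(hmm$match_columns, c(1L, 3L, 4L))
  # per-row paths: r1 M1 I1 M2 M3 ; r2 M1 M2 M3 ; r3 M1 D2 M3 ; r4 M1 M2 M3
  # node0: B->M1 x4 -> smoothed (4+1)/(4+3)
  expect_equal(unname(exp(hmm$trans_log[1, "MM"])), 5 / 7)
  # node1 from M: M->I 1, M->M 2, M->D 1 (of 4) -> (c+1)/(4+3)
  expect_equal(unname(exp(hmm$trans_log[2, "MM"])), 3 / 7)
  expect_equal(unname(exp(hmm$trans_log[2, "MI"])), 2 / 7)
  expect_equal(unname(exp(hmm$trans_log[2, "MD"])), 2 / 7)
  # node1 from I: one I1 -> M2 -> (1+1)/(1+3)
  expect_equal(unname(exp(hmm$trans_log[2, "IM"])), 2 / 4)
  # node2 from D: one D2 -> M3 -> (1+1)/(1+3)
  expect_equal(unname(exp(hmm$trans_log[3, "DM"])), 2 / 4)
  # node3 (last): targets are E and I only; all 4 rows end
  expect_equal(unname(exp(hmm$trans_log[4, "MM"])), 5 / 6)
})

test_that("forward probability equals the exhaustive path-sum on tiny models", {
  aln <- alignment(c(a = "A", b = "A"), "nucleotide")
  hmm <- build_hmm(aln)
  lf <- msaextend:::forward_logprob(hmm, "A")
  expect_lt(abs(lf - log(oracle_forward_prob(hmm, "A"))), 1e-9)

  set.seed(77)
  for (rep in 1:40) {
    hmm <- random_tiny_hmm()
    q <- paste0(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
                collapse = "")
    lf <- msaextend:::forward_logprob(hmm, q)
    expect_lt(abs(lf - log(oracle_forward_prob(hmm, q))), 1e-9)
  }
})

test_that("bitscores are deterministic and tolerate out-of-alphabet letters", {
  set.seed(8)
  hmm <- build_hmm(random_alignment(4, 8))
  q <- "ACGTAC"
  expect_identical(forward_bitscore(hmm, q), forward_bitscore(hmm, q))
  expect_warning(b <- forward_bitscore(hmm, "ACNGT"), "outside")
  expect_true(is.finite(b))
  expect_error(forward_bitscore(hmm, ""), "non-empty")
})

test_that("a subalignment's own sequences score higher against their own HMM than a disjoint clade's", {
  set.seed(31)
  sim <- simulate_sequences(sim_params(n = 40, root_length = 60), seed = 31)
  subsets <- decompose_tree(sim$tree, l = 8, u = 15)
  expect_gte(length(subsets), 2L)
  units <- build_units(sim$alignment, subsets)
  own <- c(); other <- c()
  for (i in seq_along(units)) {
    j <- if (i == 1) 2L else 1L
    for (id in units[[i]]$ids[1:3]) {
      q <- ungap(units[[i]]$subalignment)[[id]]
      own <- c(own, forward_bitscore(units[[i]]$hmm, q))
      other <- c(other, forward_bitscore(units[[j]]$hmm, q))
    }
  }
  expect_gt(mean(own), mean(other))
})

test_that("adjusted scores normalize, preserve argmax under equal sizes, and match direct evaluation", {
  expect_equal(adjusted_scores(3.2, 7L), 1)

  set.seed(13)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k, sd = 4)
    s <- sample(1:30, k, replace = TRUE)
    p <- adjusted_scores(b, s)
    expect_lt(abs(sum(p) - 1), 1e-9)
    peq <- adjusted_scores(b, rep(5L, k))
    expect_equal(which.max(peq), which.max(b))
  }

  # direct evaluation: s=(10,20), b=(5.0,4.2) -> weights (320, 367.565...)
  p <- adjusted_scores(c(5.0, 4.2), c(10L, 20L))
  w <- c(10 * 2^5, 20 * 2^4.2)
  expect_equal(p, w / sum(w), tolerance = 1e-12)
  expect_equal(which.max(p), 2L)

  expect_warning(pu <- adjusted_scores(c(-Inf, -Inf), c(1L, 3L)), "uniform")
  expect_equal(pu, c(0.5, 0.5))
})

test_that("the HMM debug dump is a readable table", {
  hmm <- build_hmm(alignment(c(a = "ACG", b = "ACG"), "nucleotide"))
  f <- withr::local_tempfile(fileext = ".tsv")
  dump_hmm(hmm, f)
  lines <- readLines(f)
  expect_true(any(grepl("^match_state", lines)))
  expect_true(any(grepl("^background", lines)))
})
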