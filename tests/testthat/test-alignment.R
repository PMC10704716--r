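test_that("aligned FASTA parsing normalizes case and gap dialect and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "a-C", ">y", "AgC"), f)
  aln <- read_alignment(f, "nucleotide")
  expect_equal(n_columns(aln), 3L)
  expect_equal(unname(aln$seqs), c("A-C", "AGC"))

  writeLines(c(">x", "A.C", ">y", "AGC"), f)
  expect_equal(read_alignment(f, "nucleotide")$seqs[["x"]], "A-C")

  writeLines(c(">x", "ACG", ">y", "ACGT"), f)
  expect_error(read_alignment(f, "nucleotide"), "same length")

  writeLines(c(">x", "ACG", ">x", "ACG"), f)
  expect_error(read_alignment(f, "nucleotide"), "duplicate")

  writeLines(character(0), f)
  expect_error(read_alignment(f, "nucleotide"), "empty")
})

test_that("write-then-read round trip reproduces alignments exactly", {
  set.seed(11)
  for (rep in 1:5) {
    aln <- random_alignment(sample(2:8, 1), sample(3:20, 1))
    f <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(aln, f)
    back <- read_alignment(f, "nucleotide")
    expect_identical(back$seqs, aln$seqs)
  }
})

test_that("induced subalignments drop all-gap columns and keep a recoverable column map", {
  parent <- alignment(c(x = "A-C", y = "-GC", z = "AG-"), "nucleotide")
  ind <- induce_subalignment(parent, c("x", "y"))
  expect_equal(unname(ind$alignment$seqs), c("A-C", "-GC"))
  expect_equal(ind$map, c(1L, 2L, 3L))

  ind1 <- induce_subalignment(parent, "x")
  expect_equal(ind1$alignment$seqs[["x"]], "AC")
  expect_equal(ind1$map, c(1L, 3L))

  expect_error(induce_subalignment(parent, "nope"), "not present")
})

test_that("induced subalignment equals a brute-force column filter and conserves letters", {
  set.seed(42)
  for (rep in 1:10) {
    parent <- random_alignment(8, 20)
    ids <- sample(alignment_ids(parent), sample(2:6, 1))
    ind <- induce_subalignment(parent, ids)
    # brute-force: restrict rows, keep columns with any letter
    m <- do.call(rbind, strsplit(unname(parent$seqs[ids]), ""))
    keep <- which(colSums(m != "-") > 0)
    expect_equal(ind$map, keep)
    expect_equal(unname(ind$alignment$seqs),
                 apply(m[, keep, drop = FALSE], 1, paste0, collapse = ""))
    # letters never created/destroyed/reordered
    expect_identical(ungap(ind$alignment), ungap(parent)[ids])
    # map recovers parent letters
    cm <- do.call(rbind, strsplit(unname(ind$alignment$seqs), ""))
    expect_identical(cm, m[, keep, drop = FALSE])
    # idempotence on its own id set
    again <- induce_subalignment(ind$alignment, ids)
    expect_identical(again$alignment$seqs, ind$alignment$seqs)
  }
})

test_that("induction test accepts all-gap padding but rejects moved letters", {
  constraint <- alignment(c(x = "AC", y = "AC"), "nucleotide")
  expect_true(induces(constraint, constraint))
  padded <- alignment(c(x = "A-C", y = "A-C", q = "AGC"), "nucleotide")
  expect_true(induces(padded, constraint))
  moved <- alignment(c(x = "A-C", y = "-AC", q = "AGC"), "nucleotide")
  expect_false(induces(moved, constraint))
  expect_error(induces(constraint, alignment(c(z = "AC"), "nucleotide")),
               "missing")
})

test_that("Newick guide trees are validated against backbone ids", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b),(c,d));", f)
  tree <- read_guide_tree(f, c("a", "b", "c", "d"))
  expect_s3_class(tree, "phylo")
  expect_error(read_guide_tree(f, c("a", "b", "c")), "does not match")
})
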