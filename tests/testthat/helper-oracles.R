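# Fixture builders and brute-force oracles, independent of the package's
# own algorithms: explicit path enumeration for HMM scores, naive nested
# loops for homology pairs, exhaustive scans for centroid edges and batch
# counts.

random_alignment <- function(nrow, ncol, gap_prob = 0.3,
                             alphabet = "nucleotide", ids = NULL) {
  ab <- c("A", "C", "G", "T")
  m <- matrix(sample(ab, nrow * ncol, replace = TRUE), nrow = nrow)
  gaps <- matrix(runif(nrow * ncol) < gap_prob, nrow = nrow)
  m[gaps] <- "-"
  # no empty rows
  for (r in seq_len(nrow)) if (all(m[r, ] == "-")) m[r, sample(ncol, 1)] <- "A"
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow))
  seqs <- setNames(apply(m, 1, paste0, collapse = ""), ids)
  alignment(seqs, alphabet)
}

# random re-gapping of the same ungapped sequences (for scorer tests)
random_gapping <- function(seqs, extra = 6L) {
  lens <- nchar(seqs)
  L <- max(lens) + sample.int(extra, 1L)
  rows <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    slots <- sort(sample.int(L, length(ch)))
    out <- rep("-", L)
    out[slots] <- ch
    paste0(out, collapse = "")
  }, character(1))
  alignment(rows, "nucleotide")
}

# exhaustive path-sum forward probability: enumerates every state path of
# the profile HMM that emits the query and sums path probabilities
oracle_forward_prob <- function(hmm, query) {
  idx <- match(strsplit(toupper(query), "")[[1]], hmm$letters) - 1L
  n <- length(idx)
  M <- hmm$M
  tr <- function(from, to, k) exp(hmm$trans_log[k + 1L, paste0(from, to)])
  em_m <- function(k, i) exp(hmm$match_log[k, idx[i] + 1L])
  em_i <- function(i) exp(hmm$insert_log[idx[i] + 1L])
  total <- 0
  rec <- function(st, k, i, p) {
    if (p == 0) return(invisible())
    if (k == M) {
      if (i == n) total <<- total + p * tr(st, "M", M)
      if (i < n) rec("I", M, i + 1L, p * tr(st, "I", M) * em_i(i + 1L))
    } else {
      if (i < n) rec("M", k + 1L, i + 1L, p * tr(st, "M", k) * em_m(k + 1L, i + 1L))
      if (i < n) rec("I", k, i + 1L, p * tr(st, "I", k) * em_i(i + 1L))
      rec("D", k + 1L, i, p * tr(st, "D", k))
    }
    invisible()
  }
  rec("M", 0L, 0L, 1)
  total
}

# exhaustive best-path (Viterbi) probability by the same enumeration
oracle_viterbi_prob <- function(hmm, query) {
  idx <- match(strsplit(toupper(query), "")[[1]], hmm$letters) - 1L
  n <- length(idx)
  M <- hmm$M
  tr <- function(from, to, k) exp(hmm$trans_log[k + 1L, paste0(from, to)])
  em_m <- function(k, i) exp(hmm$match_log[k, idx[i] + 1L])
  em_i <- function(i) exp(hmm$insert_log[idx[i] + 1L])
  best <- 0
  rec <- function(st, k, i, p) {
    if (p == 0) return(invisible())
    if (k == M) {
      cand <- p * tr(st, "M", M)
      if (i == n && cand > best) best <<- cand
      if (i < n) rec("I", M, i + 1L, p * tr(st, "I", M) * em_i(i + 1L))
    } else {
      if (i < n) rec("M", k + 1L, i + 1L, p * tr(st, "M", k) * em_m(k + 1L, i + 1L))
      if (i < n) rec("I", k, i + 1L, p * tr(st, "I", k) * em_i(i + 1L))
      rec("D", k + 1L, i, p * tr(st, "D", k))
    }
    invisible()
  }
  rec("M", 0L, 0L, 1)
  best
}

# random HMM from a random alignment, retrying draws with no match column
random_buildable_hmm <- function(nrow, ncol) {
  repeat {
    hmm <- tryCatch(build_hmm(random_alignment(nrow, ncol)),
                    error = function(e) NULL)
    if (!is.null(hmm)) return(hmm)
  }
}

# small random profile HMM built from a random alignment, keeping M small
random_tiny_hmm <- function(max_match = 4L) {
  repeat {
    aln <- random_alignment(sample(2:5, 1), sample(1:5, 1), gap_prob = 0.35)
    hmm <- tryCatch(build_hmm(aln), error = function(e) NULL)
    if (!is.null(hmm) && hmm$M <= max_match) return(hmm)
  }
}

# naive homology pair set as a character vector of canonical keys
oracle_pair_keys <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  keys <- character(0)
  upos <- matrix(NA_integer_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    cnt <- 0L
    for (j in seq_len(ncol(m))) if (m[r, j] != "-") {
      upos[r, j] <- cnt; cnt <- cnt + 1L
    }
  }
  for (j in seq_len(ncol(m))) {
    occ <- which(m[, j] != "-")
    if (length(occ) < 2) next
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      if (a >= b) next
      ra <- rownames(m)[occ[a]]; rb <- rownames(m)[occ[b]]
      ka <- paste0(ra, ":", upos[occ[a], j])
      kb <- paste0(rb, ":", upos[occ[b], j])
      keys <- c(keys, if (ka < kb) paste0(ka, "|", kb) else paste0(kb, "|", ka))
    }
  }
  keys
}

# smallest feasible batch count by exhaustive scan
oracle_min_batches <- function(unit_size, nq, cap) {
  for (k in seq_len(max(1L, nq))) {
    if (unit_size + ceiling(nq / k) <= cap) return(k)
  }
  stop("infeasible")
}

# balance of the best split over all edges, by independent tip descent
oracle_best_balance <- function(tree, eligible_min = 1L) {
  ntip <- length(tree$tip.label)
  sides <- lapply(seq_len(nrow(tree$edge)), function(e) {
    keep <- tryCatch(ape::extract.clade(tree, tree$edge[e, 2])$tip.label,
                     error = function(err) tree$tip.label[tree$edge[e, 2]])
    keep
  })
  a <- lengths(sides)
  valid <- a >= 1 & (ntip - a) >= 1
  elig <- valid & pmin(a, ntip - a) >= eligible_min
  cand <- if (any(elig)) which(elig) else which(valid)
  min(abs(2 * a[cand] - ntip))
}

# one seeded toy pipeline fixture, used across end-to-end tests
toy_fixture <- function(seed, n = 60L, root_length = 80L, scenario = "large_random",
                        sub_rate = 1.0, indel_rate = 0.02) {
  sim <- simulate_sequences(sim_params(n = n, root_length = root_length,
                                       sub_rate = sub_rate,
                                       indel_rate = indel_rate),
                            seed = seed)
  sel <- select_backbone(sim, scenario, seed = seed)
  list(sim = sim, sel = sel)
}
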