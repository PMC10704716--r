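# Synthetic sequence evolution with tracked true alignments.  Sequences
# evolve down a random non-ultrametric binary tree under uniform
# substitutions and a two-regime indel process: indel lengths are
# geometric, and with a small probability an event is promoted to a long
# regime with a much larger mean, emulating rare domain-scale gains and
# losses.  Every residue carries a site identity, so the true alignment
# of the leaves is tracked exactly rather than inferred.

#' Simulation parameters
#'
#' @param n Number of leaf taxa (default 200).
#' @param root_length Root sequence length (default 200).
#' @param sub_rate Substitution rate per site per unit branch length
#'   (default 1.0).
#' @param indel_rate Indel event rate per site per unit branch length
#'   (default 0.02).
#' @param short_mean Mean length of ordinary indels (geometric; default 2).
#' @param promote_prob Probability an indel event is promoted to the long
#'   regime (default 0.05).
#' @param long_mean Mean length of promoted (long) indels (default 15).
#' @param mean_branch Mean branch length, exponentially distributed so the
#'   tree is non-ultrametric (default 0.08).
#' @param alphabet `"nucleotide"` or `"protein"` (default nucleotide).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n = 200L, root_length = 200L, sub_rate = 1.0,
                       indel_rate = 0.02, short_mean = 2, promote_prob = 0.05,
                       long_mean = 15, mean_branch = 0.08,
                       alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(n >= 3L, root_length >= 1L, sub_rate >= 0, indel_rate >= 0,
            short_mean >= 1, long_mean >= 1,
            promote_prob >= 0, promote_prob <= 1, mean_branch > 0)
  structure(list(n = as.integer(n), root_length = as.integer(root_length),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 short_mean = short_mean, promote_prob = promote_prob,
                 long_mean = long_mean, mean_branch = mean_branch,
                 alphabet = alphabet),
            class = "sim_params")
}

rgeom_len <- function(mean_len) {
  if (mean_len <= 1) return(1L)
  stats::rgeom(1L, prob = 1 / mean_len) + 1L
}

#' Simulate sequences down a random tree with a tracked true alignment
#'
#' Residues are evolved root-to-tip: each site substitutes independently
#' with probability `1 - exp(-sub_rate * t)` on a branch of length `t`;
#' indel events arrive as Poisson with rate `indel_rate * t * length`,
#' each an insertion or deletion with equal probability, with geometric
#' length drawn from the short regime or (with `promote_prob`) the long
#' regime.  Site identities are threaded through, so homologies in the
#' returned alignment are exactly the residues descending from a common
#' ancestral site.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed fixing all randomness.
#' @return A list with `alignment` (the true `msa_alignment` on the
#'   leaves), `tree` (the model `ape::phylo`), `sequences` (ungapped leaf
#'   sequences) and `params`.
#' @export
simulate_sequences <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  ab <- if (params$alphabet == "nucleotide") c("A", "C", "G", "T")
        else alphabet_letters("protein")
  A <- length(ab)
  tree <- ape::rtree(params$n, br = NULL,
                     tip.label = sprintf("t%03d", seq_len(params$n)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / params$mean_branch)

  master <- seq_len(params$root_length)   # global column order
  next_id <- params$root_length + 1L
  splice_after <- function(anchor_id, new_ids) {
    if (anchor_id == 0L) pos <- 0L else pos <- match(anchor_id, master)
    master <<- append(master, new_ids, after = pos)
  }

  evolve_branch <- function(ids, letters, t) {
    len <- length(letters)
    # substitutions
    p_sub <- 1 - exp(-params$sub_rate * t)
    hit <- which(stats::runif(len) < p_sub)
    for (i in hit) letters[i] <- sample(setdiff(ab, letters[i]), 1L)
    # indels
    n_ev <- stats::rpois(1L, params$indel_rate * t * len)
    for (e in seq_len(n_ev)) {
      long <- stats::runif(1L) < params$promote_prob
      elen <- rgeom_len(if (long) params$long_mean else params$short_mean)
      if (stats::runif(1L) < 0.5) {                     # insertion
        pos <- sample.int(length(letters) + 1L, 1L) - 1L  # insert after pos
        new_ids <- next_id + seq_len(elen) - 1L
        next_id <<- next_id + elen
        anchor <- if (pos == 0L) {
          if (length(ids) == 0L) 0L else 0L
        } else ids[pos]
        if (pos == 0L) {
          # before the first residue: splice ahead of this lineage's start
          first <- if (length(ids)) match(ids[1L], master) - 1L else 0L
          master <<- append(master, new_ids, after = first)
        } else splice_after(anchor, new_ids)
        new_letters <- sample(ab, elen, replace = TRUE)
        ids <- append(ids, new_ids, after = pos)
        letters <- append(letters, new_letters, after = pos)
      } else {                                          # deletion
        if (length(letters) == 0L) break
        start <- sample.int(length(letters), 1L)
        drop <- start:min(length(letters), start + elen - 1L)
        if (length(drop) >= length(letters))
          stop("simulation error: a deletion removed an entire sequence; ",
               "lower indel_rate or long_mean", call. = FALSE)
        ids <- ids[-drop]; letters <- letters[-drop]
      }
    }
    if (length(letters) == 0L)
      stop("simulation error: empty sequence produced", call. = FALSE)
    list(ids = ids, letters = letters)
  }

  ntip <- params$n
  root <- ntip + 1L
  root_letters <- sample(ab, params$root_length, replace = TRUE)
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- list(ids = master, letters = root_letters)
  ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    node_seq[[ch]] <- evolve_branch(node_seq[[p]]$ids,
                                    node_seq[[p]]$letters,
                                    ord$edge.length[e])
  }

  leaf_seqs <- node_seq[seq_len(ntip)]
  used <- sort(unique(unlist(lapply(leaf_seqs, `[[`, "ids"))))
  cols <- master[master %in% used]
  col_of <- setNames(seq_along(cols), cols)
  m <- matrix(GAP, nrow = ntip, ncol = length(cols),
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip))
    m[i, col_of[as.character(leaf_seqs[[i]]$ids)]] <- leaf_seqs[[i]]$letters
  aln <- matrix_to_aln(m, params$alphabet, normalize = FALSE)
  list(alignment = aln, tree = tree, sequences = ungap(aln), params = params)
}

#' Select a backbone from a simulated dataset
#'
#' Implements the three selection protocols.  Full-length sequences are
#' those whose ungapped length is within 25% of the median.  With `F`
#' full-length sequences: the large random protocol samples
#' `min(cap_large, round(0.25 F))`; the small random protocol samples
#' `min(cap_small, round(0.1 F))` with a floor of 10; the clade protocol
#' picks the tree clade of at most `cap_clade` leaves whose size is
#' closest to 25% of the taxa (ties broken at random).  The remaining
#' sequences become queries, and the constraint alignment is the true
#' alignment induced on the backbone.
#'
#' @param sim Output of [simulate_sequences()] (or a list with
#'   `alignment` and `tree`).
#' @param scenario `"large_random"`, `"small_random"` or `"clade"`.
#' @param seed Integer seed for the random draws.
#' @param cap_large,cap_small,cap_clade Scenario size caps (paper-scale
#'   defaults 1000 / 100 / 1000; reduce for toy runs).
#' @return A list with `scenario`, `backbone_ids`, `query_ids`, `F`,
#'   `constraint` (induced `msa_alignment`) and `queries` (named ungapped
#'   sequences).
#' @export
select_backbone <- function(sim, scenario = c("large_random", "small_random",
                                              "clade"),
                            seed = 1L, cap_large = 1000L, cap_small = 100L,
                            cap_clade = 1000L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  aln <- sim$alignment
  ids <- alignment_ids(aln)
  n <- length(ids)
  lens <- nchar(ungap(aln))
  med <- stats::median(lens)
  full <- ids[abs(lens - med) <= 0.25 * med]
  F <- length(full)

  pick <- switch(scenario,
    large_random = {
      size <- min(cap_large, round(0.25 * F))
      size <- max(1L, size)
      sort(sample(full, size))
    },
    small_random = {
      size <- min(cap_small, round(0.1 * F))
      if (size < 10L) {
        size <- min(10L, n - 1L)
        pool <- if (F >= size) full else ids
        sort(sample(pool, size))
      } else sort(sample(full, size))
    },
    clade = {
      tree <- sim$tree
      ntip <- length(tree$tip.label)
      bip <- edge_bipartitions(tree)
      sizes <- lengths(bip$side)
      ok <- which(sizes <= cap_clade & sizes < ntip & sizes >= 2L)
      if (!length(ok))
        stop("no clade of admissible size for the clade scenario",
             call. = FALSE)
      target <- 0.25 * ntip
      dev <- abs(sizes[ok] - target)
      best <- ok[dev == min(dev)]
      chosen <- if (length(best) > 1L) best[sample.int(length(best), 1L)]
                else best
      sort(bip$side[[chosen]])
    })

  qids <- setdiff(ids, pick)
  if (!length(qids))
    stop("backbone selection left no query sequences", call. = FALSE)
  constraint <- induce_subalignment(aln, pick)$alignment
  list(scenario = scenario, backbone_ids = pick, query_ids = qids,
       F = F, constraint = constraint,
       queries = ungap(aln)[qids])
}
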