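# Guide-tree decomposition: repeatedly delete centroid edges until every
# leaf subset has between l and u members.  The subsets always partition
# the leaf set; undersized inputs and unsplittable subsets are retained
# whole so that no sequence is ever discarded.

# postorder edge table with per-edge leaf descendant sets; deterministic
# for a given Newick string
edge_bipartitions <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (is.null(desc[[p]])) desc[[p]] <- integer(0)
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  side <- lapply(seq_len(nrow(tree$edge)),
                 function(e) tree$tip.label[sort(desc[[tree$edge[e, 2L]]])])
  list(tree = tree, side = side)
}

#' Find the centroid edge of a guide tree
#'
#' The centroid edge is the edge whose removal splits the leaf set into
#' two parts of maximally balanced size.  Among edges whose smaller side
#' has at least `eligible_min` leaves (all edges if none qualifies), the
#' edge minimizing the size difference is returned; ties are broken by the
#' smallest edge index in a deterministic postorder enumeration.
#'
#' @param tree An `ape::phylo` tree with at least 2 leaves.
#' @param eligible_min Minimum leaf count required on both sides for an
#'   edge to be preferred (default 1, i.e. no restriction).
#' @return A list with `ids_a` (leaves below the edge), `ids_b` (the
#'   rest), `balance` (`abs(a - b)`) and `min_side`.
#' @export
centroid_edge <- function(tree, eligible_min = 1L) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree has fewer than 2 leaves; no edge to split",
                      call. = FALSE)
  bip <- edge_bipartitions(tree)
  a <- lengths(bip$side)
  b <- ntip - a
  valid <- b >= 1L              # skip the edge spanning the whole leaf set
  eligible <- valid & pmin(a, b) >= eligible_min
  cand <- if (any(eligible)) which(eligible) else which(valid)
  best <- cand[which.min(abs(a - b)[cand])]
  list(ids_a = bip$side[[best]],
       ids_b = setdiff(bip$tree$tip.label, bip$side[[best]]),
       balance = abs(a[best] - b[best]),
       min_side = min(a[best], b[best]))
}

#' Decompose a guide tree into bounded-size leaf subsets
#'
#' Any subset larger than `u` is split at its centroid edge, preferring
#' edges that keep both sides at least `l`; recursion stops once a subset
#' has at most `u` leaves.  Two fallbacks preserve the partition property:
#' (i) a whole tree with fewer than `l` leaves is returned as one subset;
#' (ii) a subset larger than `u` with no split leaving both sides at least
#' `l` is retained whole.
#'
#' @param tree An `ape::phylo` tree on the backbone ids.
#' @param l Lower subset size bound (default 10).
#' @param u Upper subset size bound (default 25).
#' @return A list of character vectors (leaf-id subsets) partitioning the
#'   leaf set, ordered deterministically.
#' @export
decompose_tree <- function(tree, l = 10L, u = 25L) {
  if (l < 1L || l > u) stop("need 1 <= l <= u", call. = FALSE)
  recurse <- function(tr) {
    ids <- tr$tip.label
    if (length(ids) <= u) return(list(sort(ids)))
    ce <- centroid_edge(tr, eligible_min = l)
    if (ce$min_side < l) return(list(sort(ids)))  # fallback (ii)
    sub <- function(keep) {
      if (length(keep) <= u) list(sort(keep))
      else recurse(ape::keep.tip(tr, keep))
    }
    c(sub(ce$ids_a), sub(ce$ids_b))
  }
  out <- recurse(tree)
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Build a fallback guide tree from k-mer distances
#'
#' When no user tree is supplied, a BIONJ tree is computed from Euclidean
#' distances between normalized k-mer frequency profiles of the ungapped
#' backbone sequences.  This is plumbing for the decomposition, not a
#' phylogenetic estimate.
#'
#' @param backbone An `msa_alignment`.
#' @param k K-mer length (default 3).
#' @return An `ape::phylo` tree on the backbone ids.
#' @export
kmer_guide_tree <- function(backbone, k = 3L) {
  seqs <- ungap(backbone)
  ids <- names(seqs)
  n <- length(seqs)
  if (n == 1L) stop("cannot build a tree on a single sequence", call. = FALSE)
  if (n <= 3L) {
    txt <- paste0("(", paste0(ids, ":1", collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  kmers <- lapply(seqs, function(s) {
    len <- nchar(s)
    kk <- min(k, len)
    substring(s, seq_len(len - kk + 1L), seq_len(len - kk + 1L) + kk - 1L)
  })
  vocab <- sort(unique(unlist(kmers)))
  prof <- t(vapply(kmers, function(km) {
    tab <- table(factor(km, levels = vocab))
    as.numeric(tab) / length(km)
  }, numeric(length(vocab))))
  rownames(prof) <- ids
  d <- stats::dist(prof)
  ape::bionj(d)
}
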