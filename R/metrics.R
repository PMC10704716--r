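# Sum-of-pairs alignment comparison in the FastSP style.  Homologies are
# pairs of letters from different sequences sharing a column; letters are
# keyed by (sequence id, 0-based ungapped position) so the pair sets of
# two alignments on the same sequences are directly comparable.

# encode every non-gap cell as an integer letter key; returns per-column
# lists of sorted keys
letter_keys <- function(m, id_rank, Lmax) {
  keys <- matrix(NA_real_, nrow = nrow(m), ncol = ncol(m))
  for (r in seq_len(nrow(m))) {
    nz <- which(m[r, ] != GAP)
    keys[r, nz] <- (id_rank[rownames(m)[r]] - 1) * Lmax + seq_along(nz) - 1
  }
  keys
}

pair_codes <- function(m, id_rank, Lmax) {
  keys <- letter_keys(m, id_rank, Lmax)
  K <- length(id_rank) * Lmax
  out <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- sort(keys[!is.na(keys[, j]), j])
    if (length(v) >= 2L) {
      pr <- utils::combn(v, 2L)
      out[[j]] <- pr[1L, ] * K + pr[2L, ]
    }
  }
  unlist(out)
}

#' Homology pairs of an alignment
#'
#' Every unordered pair of non-gap letters sharing a column contributes
#' one homology, keyed by sequence id and 0-based ungapped position.
#'
#' @param aln An `msa_alignment`.
#' @return A data.frame with columns `id1`, `pos1`, `id2`, `pos2`
#'   (canonical order: `id1 < id2` lexicographically).
#' @export
homology_pairs <- function(aln) {
  m <- aln_matrix(aln)
  ids <- sort(rownames(m))
  id_rank <- setNames(seq_along(ids), ids)
  Lmax <- max(1L, max(nchar(ungap(aln))))
  K <- length(ids) * Lmax
  codes <- pair_codes(m, id_rank, Lmax)
  if (length(codes) == 0L)
    return(data.frame(id1 = character(0), pos1 = integer(0),
                      id2 = character(0), pos2 = integer(0)))
  a <- codes %/% K; b <- codes %% K
  data.frame(id1 = ids[a %/% Lmax + 1], pos1 = as.integer(a %% Lmax),
             id2 = ids[b %/% Lmax + 1], pos2 = as.integer(b %% Lmax),
             stringsAsFactors = FALSE)
}

#' Compare an estimated alignment against a reference
#'
#' Both alignments are restricted to `restrict_ids` (all-gap columns
#' dropped) before scoring.  SPFN is the fraction of reference homology
#' pairs missing from the estimate; SPFP the fraction of estimated pairs
#' absent from the reference; the expansion score is the restricted
#' estimated length divided by the restricted reference length (1.0
#' optimal, above 1 under-aligned, below 1 over-aligned).
#'
#' @param reference Reference/true `msa_alignment`.
#' @param estimated Estimated `msa_alignment` on the same sequences.
#' @param restrict_ids Ids to score on (default: all shared ids); must be
#'   present in both alignments with identical ungapped sequences.
#' @return A list with `spfn`, `spfp`, `expansion`, `error` (mean of SPFN
#'   and SPFP), pair counts (`ref_pairs`, `est_pairs`, `shared_pairs`) and
#'   column counts (`ref_columns`, `est_columns`).
#' @export
compare_alignments <- function(reference, estimated,
                               restrict_ids = NULL) {
  if (is.null(restrict_ids))
    restrict_ids <- intersect(alignment_ids(reference),
                              alignment_ids(estimated))
  restrict_ids <- as.character(restrict_ids)
  ref_r <- induce_subalignment(reference, restrict_ids)$alignment
  est_r <- induce_subalignment(estimated, restrict_ids)$alignment
  ru <- ungap(ref_r)[restrict_ids]
  eu <- ungap(est_r)[restrict_ids]
  bad <- restrict_ids[ru != eu]
  if (length(bad))
    stop("alignments disagree on the raw sequences for: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)

  ids <- sort(restrict_ids)
  id_rank <- setNames(seq_along(ids), ids)
  Lmax <- max(1L, max(nchar(ru)))
  ref_codes <- pair_codes(aln_matrix(ref_r), id_rank, Lmax)
  est_codes <- pair_codes(aln_matrix(est_r), id_rank, Lmax)
  shared <- length(intersect(ref_codes, est_codes))
  nref <- length(ref_codes); nest <- length(est_codes)
  spfn <- if (nref == 0L) 0 else 1 - shared / nref
  spfp <- if (nest == 0L) 0 else 1 - shared / nest
  list(spfn = spfn, spfp = spfp,
       expansion = n_columns(est_r) / n_columns(ref_r),
       error = (spfn + spfp) / 2,
       ref_pairs = nref, est_pairs = nest, shared_pairs = shared,
       ref_columns = n_columns(ref_r), est_columns = n_columns(est_r))
}
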