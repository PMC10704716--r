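# Transitivity merge: columns of extended subalignments that carry the
# same backbone column are unified into one output column; insertion
# columns are emitted between their flanking backbone columns, never
# merged across subproblems.  Because every backbone and query sequence
# lives in exactly one subproblem, the merged alignment always induces
# the constraint alignment.

#' Merge extended subalignments into one alignment
#'
#' Output column order: for each anchor position `a` from 0 (before the
#' first backbone column) to L, all insertion columns anchored at `a` —
#' grouped by subproblem in ascending (unit, batch) order and in local
#' left-to-right order within a subproblem — followed by backbone column
#' `a + 1`.  Backbone rows are taken from the constraint; query rows keep
#' their letters in the global columns their labeled columns map to plus
#' their private insertion columns.
#'
#' @param extended List of `extended_subalignment` objects whose row sets
#'   are disjoint and whose backbone parts partition the constraint rows.
#' @param constraint The backbone `msa_alignment`.
#' @param query_order Optional character vector fixing the output order of
#'   the query rows (default: order of appearance across subproblems).
#' @return An `msa_alignment` with backbone rows first (constraint order)
#'   then query rows.
#' @export
merge_extensions <- function(extended, constraint, query_order = NULL) {
  L <- n_columns(constraint)
  bids <- alignment_ids(constraint)
  ord <- order(vapply(extended, `[[`, integer(1), "unit_index"),
               vapply(extended, `[[`, integer(1), "batch_index"))
  extended <- extended[ord]

  # batches of the same unit share that unit's backbone rows; across
  # units the backbone parts must partition the constraint rows
  unit_of <- vapply(extended, `[[`, integer(1), "unit_index")
  unit_back <- lapply(split(extended, unit_of), function(exts) {
    parts <- lapply(exts, function(e)
      sort(intersect(alignment_ids(e$alignment), bids)))
    if (length(unique(parts)) != 1L)
      stop("subproblems of one unit disagree on its backbone rows",
           call. = FALSE)
    parts[[1L]]
  })
  covered <- unlist(unit_back)
  if (anyDuplicated(covered))
    stop("a backbone row appears in more than one subproblem", call. = FALSE)
  if (!setequal(covered, bids))
    stop("subproblem backbone rows do not partition the constraint rows",
         call. = FALSE)
  qids_all <- unlist(lapply(extended, function(e)
    setdiff(alignment_ids(e$alignment), bids)))
  if (anyDuplicated(qids_all))
    stop("a query row appears in more than one subproblem", call. = FALSE)
  if (is.null(query_order)) query_order <- qids_all
  stopifnot(setequal(query_order, qids_all))

  # enumerate insertion columns per anchor, in (subproblem, local) order
  ins_by_anchor <- vector("list", L + 1L)   # anchors 0..L
  for (s in seq_along(extended)) {
    e <- extended[[s]]
    insc <- which(is.na(e$labels))
    for (j in insc) {
      a <- e$anchors[j] + 1L
      ins_by_anchor[[a]] <- rbind(ins_by_anchor[[a]],
                                  data.frame(sub = s, local = j))
    }
  }

  n_ins <- sum(vapply(ins_by_anchor, function(x) if (is.null(x)) 0L else nrow(x),
                      integer(1)))
  total_cols <- L + n_ins
  rows <- c(bids, query_order)
  out <- matrix(GAP, nrow = length(rows), ncol = total_cols,
                dimnames = list(rows, NULL))

  # global position of each backbone column and of each insertion column
  pos <- 0L
  backbone_pos <- integer(L)
  ins_pos <- lapply(seq_along(extended), function(s)
    rep(NA_integer_, n_columns(extended[[s]]$alignment)))
  for (a in 0:L) {
    blk <- ins_by_anchor[[a + 1L]]
    if (!is.null(blk)) {
      for (r in seq_len(nrow(blk))) {
        pos <- pos + 1L
        ins_pos[[blk$sub[r]]][blk$local[r]] <- pos
      }
    }
    if (a < L) { pos <- pos + 1L; backbone_pos[a + 1L] <- pos }
  }

  cm <- aln_matrix(constraint)
  out[bids, backbone_pos] <- cm

  for (s in seq_along(extended)) {
    e <- extended[[s]]
    em <- aln_matrix(e$alignment)
    eb <- intersect(rownames(em), bids)
    eq <- setdiff(rownames(em), bids)
    lab <- which(!is.na(e$labels))
    glob <- ifelse(is.na(e$labels), ins_pos[[s]], NA_integer_)
    glob[lab] <- backbone_pos[e$labels[lab]]
    # consistency: backbone letters in labeled columns must match the
    # constraint exactly (guaranteed by the induction contract)
    if (length(eb) && !identical(unname(em[eb, lab, drop = FALSE]),
                                 unname(out[eb, glob[lab], drop = FALSE])))
      stop("merge consistency error: subproblem ", s,
           " disagrees with the constraint in a backbone column",
           call. = FALSE)
    for (q in eq) out[q, glob] <- em[q, ]
  }

  matrix_to_aln(out, constraint$alphabet, normalize = FALSE)
}
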