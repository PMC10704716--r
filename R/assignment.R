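# Query routing and subproblem batching.  Every query goes to exactly one
# subalignment (the argmax of the size-adjusted HMM probability); each
# subalignment's query set is then cut into the smallest number of
# near-equal batches such that backbone + batch never exceeds the cap.

#' Build subalignment units from a decomposition
#'
#' For each leaf subset the induced subalignment, its column map into the
#' backbone, and its profile HMM are assembled into one unit.
#'
#' @param backbone An `msa_alignment` (the constraint alignment).
#' @param subsets List of character vectors partitioning the backbone ids.
#' @param pseudocount HMM smoothing constant (default 1.0).
#' @return A list of units, each with `index`, `ids`, `subalignment`,
#'   `map` (subalignment column -> backbone column) and `hmm`.
#' @export
build_units <- function(backbone, subsets, pseudocount = 1.0) {
  lapply(seq_along(subsets), function(i) {
    ind <- induce_subalignment(backbone, subsets[[i]])
    list(index = i,
         ids = subsets[[i]],
         subalignment = ind$alignment,
         map = ind$map,
         hmm = build_hmm(ind$alignment, pseudocount = pseudocount))
  })
}

#' Route queries to subalignment units
#'
#' Each query is scored against every unit's HMM with the forward
#' bitscore; the unit with the highest size-adjusted probability wins,
#' ties going to the smallest unit index.
#'
#' @param units List of units from [build_units()].
#' @param queries Named character vector of ungapped query sequences; ids
#'   must be disjoint from the backbone ids.
#' @return A data.frame with one row per query: `query`, `unit`,
#'   `bitscore` (against the chosen unit) and `probability` (adjusted).
#' @export
assign_queries <- function(units, queries) {
  stopifnot(length(units) >= 1L, length(queries) >= 1L)
  qids <- names(queries)
  bids <- unlist(lapply(units, `[[`, "ids"))
  clash <- intersect(qids, bids)
  if (length(clash))
    stop("query ids collide with backbone ids: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(qids))
    stop("duplicate query ids", call. = FALSE)
  sizes <- vapply(units, function(u) n_rows(u$subalignment), integer(1))
  rows <- lapply(qids, function(qid) {
    b <- vapply(units, function(u) forward_bitscore(u$hmm, queries[[qid]]),
                numeric(1))
    p <- adjusted_scores(b, sizes)
    best <- which.max(p)    # first maximum = smallest unit index on ties
    data.frame(query = qid, unit = best, bitscore = b[best],
               probability = p[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition a unit's queries into balanced batches
#'
#' If backbone-subset size plus query count fits within `cap`, one batch
#' is returned.  Otherwise the queries are split, in input order, into the
#' minimal number `k = ceiling(|Q| / (cap - unit_size))` of batches whose
#' sizes differ by at most one.
#'
#' @param unit_size Number of backbone sequences in the unit.
#' @param query_ids Character vector of query ids routed to the unit.
#' @param cap Maximum total sequences per subproblem (default 500).
#' @return A list of character vectors (possibly empty list when there are
#'   no queries).
#' @export
make_batches <- function(unit_size, query_ids, cap = 500L) {
  nq <- length(query_ids)
  if (nq == 0L) return(list())
  if (cap <= unit_size)
    stop("cap (", cap, ") must exceed the unit size (", unit_size,
         ") to fit any query", call. = FALSE)
  if (unit_size + nq <= cap) return(list(query_ids))
  k <- ceiling(nq / (cap - unit_size))
  base <- nq %/% k
  extra <- nq %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  split(query_ids, rep(seq_len(k), times = sizes))
}
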