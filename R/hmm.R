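# Profile hidden Markov models over subalignments.  Architecture: one
# match/insert/delete node triple per match column, an insert state before
# the first node, global (whole-query) scoring.  Alignment columns with a
# gap fraction below 0.5 become match columns; everything is add-pseudocount
# smoothed so the model is strictly positive and deterministic.

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")

#' Build a profile HMM from a subalignment
#'
#' Columns with gap fraction < 0.5 become match columns.  Match emissions
#' are Laplace-smoothed observed letter frequencies; transitions are
#' smoothed counts of the per-row state paths implied by the gap pattern;
#' insert emissions equal the background (smoothed overall letter
#' frequencies of the subalignment), which is also the null model.
#'
#' @param subalignment An `msa_alignment`.
#' @param pseudocount Additive smoothing constant (default 1.0).
#' @return An object of class `profile_hmm`.
#' @export
build_hmm <- function(subalignment, pseudocount = 1.0) {
  stopifnot(pseudocount > 0)
  ab <- alphabet_letters(subalignment$alphabet)
  A <- length(ab)
  m <- aln_matrix(subalignment)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("cannot build an HMM from an empty alignment", call. = FALSE)
  gapfrac <- colMeans(m == GAP)
  match_cols <- which(gapfrac < 0.5)
  M <- length(match_cols)
  if (M == 0L)
    stop("degenerate model: no column has gap fraction below 0.5",
         call. = FALSE)

  # background = smoothed overall letter frequencies
  letters_all <- m[m != GAP]
  bg_counts <- table(factor(letters_all[letters_all %in% ab], levels = ab))
  bg <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + A * pseudocount)
  names(bg) <- ab

  # match emissions
  emis <- matrix(0, nrow = M, ncol = A, dimnames = list(NULL, ab))
  for (k in seq_len(M)) {
    col <- m[, match_cols[k]]
    cc <- table(factor(col[col %in% ab], levels = ab))
    emis[k, ] <- (as.numeric(cc) + pseudocount) /
      (sum(cc) + A * pseudocount)
  }

  # per-row state paths from the gap pattern -> transition counts
  is_match <- seq_len(ncol(m)) %in% match_cols
  node_of <- cumsum(is_match)            # node index at each column
  counts <- matrix(0, nrow = M + 1L, ncol = 9L,
                   dimnames = list(NULL, TRANS_COLS))
  state_code <- c(M = 0L, I = 1L, D = 2L)
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    st <- character(0); nd <- integer(0)
    for (j in seq_len(ncol(m))) {
      if (is_match[j]) {
        st <- c(st, if (row[j] == GAP) "D" else "M")
        nd <- c(nd, node_of[j])
      } else if (row[j] != GAP) {
        st <- c(st, "I"); nd <- c(nd, node_of[j])
      }
    }
    st <- c("M", st, "M"); nd <- c(0L, nd, M + 1L)   # begin / end sentinels
    for (s in seq_len(length(st) - 1L)) {
      from <- st[s]; to <- st[s + 1L]
      counts[nd[s] + 1L, state_code[from] * 3L + state_code[to] + 1L] <-
        counts[nd[s] + 1L, state_code[from] * 3L + state_code[to] + 1L] + 1
    }
  }

  # smoothed log transition probabilities; invalid slots stay -Inf
  trans <- matrix(-Inf, nrow = M + 1L, ncol = 9L,
                  dimnames = list(NULL, TRANS_COLS))
  for (k in 0:M) {
    for (from in c("M", "I", "D")) {
      if (from == "D" && k == 0L) next            # D_0 does not exist
      targets <- if (k == M) c("M", "I") else c("M", "I", "D")
      idx <- state_code[from] * 3L + state_code[targets] + 1L
      cts <- counts[k + 1L, idx] + pseudocount
      trans[k + 1L, idx] <- log(cts / sum(cts))
    }
  }

  structure(list(M = M,
                 alphabet = subalignment$alphabet,
                 letters = ab,
                 match_log = log(emis),
                 insert_log = log(bg),
                 trans_log = trans,
                 bg_log = log(bg),
                 match_columns = match_cols,
                 n_seqs = nrow(m),
                 pseudocount = pseudocount),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match states, %s alphabet, built from %d sequences\n",
              x$M, x$alphabet, x$n_seqs))
  invisible(x)
}

encode_query <- function(hmm, query) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  idx <- match(q, hmm$letters) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

#' Forward bitscore of a query against a profile HMM
#'
#' Computes `log2 P(query | hmm) - log2 P(query | null)` with the
#' log-space forward algorithm over the full M/I/D state space (global
#' scoring: the model generates the whole query).  Letters outside the
#' alphabet are emitted at the uniform background value in both the model
#' and the null, so they do not move the score; a warning is issued.
#'
#' @param hmm A `profile_hmm`.
#' @param query Residue string (no gaps).
#' @return Bitscore (bits).
#' @export
forward_bitscore <- function(hmm, query) {
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  idx <- encode_query(hmm, query)
  if (any(idx < 0L))
    warning("query contains letters outside the declared alphabet; ",
            "treated as background", call. = FALSE)
  unk <- log(1 / length(hmm$letters))
  lf <- forward_logprob_cpp(hmm$match_log, hmm$insert_log, hmm$trans_log,
                            idx, unk)
  lnull <- sum(ifelse(idx >= 0L, hmm$bg_log[idx + 1L], unk))
  (lf - lnull) / log(2)
}

# natural-log forward probability (used by tests against the path-sum oracle)
forward_logprob <- function(hmm, query) {
  idx <- encode_query(hmm, query)
  forward_logprob_cpp(hmm$match_log, hmm$insert_log, hmm$trans_log, idx,
                      log(1 / length(hmm$letters)))
}

#' Size-adjusted subset probabilities from raw bitscores
#'
#' For a query scored against every subalignment HMM, the adjusted score
#' of subset i with `s_i` sequences and bitscore `b_i` is
#' `p_i = s_i * 2^b_i / sum_j s_j * 2^b_j`, computed stably in log space.
#' If every bitscore is `-Inf` the probabilities fall back to uniform with
#' a warning, so every query can still be routed somewhere.
#'
#' @param bitscores Numeric vector of per-subset bitscores `b_i`.
#' @param sizes Integer vector of subset sequence counts `s_i`.
#' @return Numeric vector of probabilities summing to 1.
#' @export
adjusted_scores <- function(bitscores, sizes) {
  stopifnot(length(bitscores) == length(sizes), length(sizes) >= 1L,
            all(sizes >= 1))
  w <- log2(sizes) + bitscores
  if (all(!is.finite(w))) {
    warning("all bitscores are -Inf; routing probabilities set uniform",
            call. = FALSE)
    return(rep(1 / length(w), length(w)))
  }
  mx <- max(w)
  p <- 2^(w - mx)
  p / sum(p)
}

#' Dump an HMM as plain-text tables
#'
#' Writes the match emission, background and transition probability
#' tables in a human-readable TSV layout for inspection.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# profile HMM: M=%d alphabet=%s n_seqs=%d",
                     hmm$M, hmm$alphabet, hmm$n_seqs), con)
  writeLines(paste(c("match_state", hmm$letters), collapse = "\t"), con)
  for (k in seq_len(hmm$M))
    writeLines(paste(c(k, sprintf("%.6f", exp(hmm$match_log[k, ]))),
                     collapse = "\t"), con)
  writeLines(paste(c("background", sprintf("%.6f", exp(hmm$bg_log))),
                   collapse = "\t"), con)
  writeLines(paste(c("node", TRANS_COLS), collapse = "\t"), con)
  for (k in 0:hmm$M)
    writeLines(paste(c(k, sprintf("%.6f", exp(hmm$trans_log[k + 1L, ]))),
                     collapse = "\t"), con)
  invisible(path)
}
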