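# Subproblem extension: add a batch of queries to one subalignment,
# producing an alignment that provably induces it.  Two backends: an
# external command (MAFFT-style `--add`) whose output is re-validated and
# never trusted, and a built-in Viterbi adder against the unit's HMM that
# needs no external binary.  The built-in adder does not infer
# query-query homology inside insertion regions: each query's insertions
# open private columns.

#' Construct an extended subalignment object
#'
#' Validates the extension contract: the alignment must induce the unit's
#' subalignment, and column labels (global backbone column indices, `NA`
#' for insertion columns) must be strictly increasing.  Anchors (the
#' nearest preceding labeled column's global index, 0 for the beginning)
#' are derived for the insertion columns.
#'
#' @param aln An `msa_alignment` over the unit's ids plus the batch ids.
#' @param labels Integer vector, one entry per column: the global backbone
#'   column the column carries, or `NA` for an insertion column.
#' @param unit The subalignment unit that was extended.
#' @param batch_index Index of the batch within the unit (default 1).
#' @return An object of class `extended_subalignment`.
#' @export
extended_subalignment <- function(aln, labels, unit, batch_index = 1L) {
  stopifnot(length(labels) == n_columns(aln))
  lab <- labels[!is.na(labels)]
  if (length(lab) && any(diff(lab) <= 0))
    stop("column labels must be strictly increasing", call. = FALSE)
  if (!induces(aln, unit$subalignment))
    stop("extension contract violated: output does not induce the ",
         "constraint subalignment (unit ", unit$index, ")", call. = FALSE)
  anchors <- rep(NA_integer_, length(labels))
  last <- 0L
  for (j in seq_along(labels)) {
    if (is.na(labels[j])) anchors[j] <- last else last <- labels[j]
  }
  structure(list(alignment = aln, labels = as.integer(labels),
                 anchors = anchors, unit_index = unit$index,
                 batch_index = batch_index),
            class = "extended_subalignment")
}

#' @export
print.extended_subalignment <- function(x, ...) {
  cat(sprintf(
    "<extended_subalignment> unit %d batch %d: %d rows x %d columns (%d insertion)\n",
    x$unit_index, x$batch_index, n_rows(x$alignment),
    n_columns(x$alignment), sum(is.na(x$labels))))
  invisible(x)
}

#' Add queries to a subalignment with the built-in Viterbi adder
#'
#' Each query is aligned to the unit's profile HMM by the Viterbi
#' algorithm.  Match-state letters are placed in the corresponding
#' subalignment columns; each insert-state run opens private insertion
#' columns immediately after the preceding match column (before the first
#' subalignment column for begin-state inserts).  The result induces the
#' unit's subalignment by construction, and is asserted to.
#'
#' @param unit A unit from [build_units()].
#' @param batch Named character vector of ungapped query sequences (may be
#'   empty).
#' @param batch_index Batch index within the unit (default 1).
#' @return An `extended_subalignment`.
#' @export
extend_fallback <- function(unit, batch, batch_index = 1L) {
  sub <- unit$subalignment
  L <- n_columns(sub)
  mc <- unit$hmm$match_columns            # local columns that are match states
  if (length(batch) && any(!nzchar(batch)))
    stop("empty query sequence in batch", call. = FALSE)

  # per query: letters at local match columns, plus insertion runs keyed by
  # the local column they anchor after (0 = before everything)
  placements <- lapply(batch, function(q) {
    idx <- encode_query(unit$hmm, q)
    vit <- viterbi_path_cpp(unit$hmm$match_log, unit$hmm$insert_log,
                            unit$hmm$trans_log, idx,
                            log(1 / length(unit$hmm$letters)))
    path <- vit$path
    qchars <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
    at_match <- rep(NA_character_, L)
    runs <- list()
    pos <- 0L
    for (s in seq_len(nrow(path))) {
      st <- path[s, 1L]; k <- path[s, 2L]
      if (st == 0L) {                     # match state k emits
        pos <- pos + 1L
        at_match[mc[k]] <- qchars[pos]
      } else if (st == 1L) {              # insert state k emits
        pos <- pos + 1L
        anchor <- if (k == 0L) 0L else mc[k]
        key <- as.character(anchor)
        runs[[key]] <- c(runs[[key]], qchars[pos])
      }
    }
    list(at_match = at_match, runs = runs)
  })

  # assemble columns: for anchor a in 0..L, every query's private insertion
  # run at a (query input order), then local column a+1
  sub_m <- aln_matrix(sub)
  bids <- alignment_ids(sub)
  qids <- names(batch)
  nb <- length(bids); nq <- length(qids)
  cols <- list(); labels <- integer(0)
  add_col <- function(letters, label) {
    cols[[length(cols) + 1L]] <<- letters
    labels[length(labels) + 1L] <<- label
  }
  for (a in 0:L) {
    key <- as.character(a)
    for (qi in seq_len(nq)) {
      run <- placements[[qi]]$runs[[key]]
      for (ch in run) {
        col <- rep(GAP, nb + nq); col[nb + qi] <- ch
        add_col(col, NA_integer_)
      }
    }
    if (a < L) {
      col <- c(sub_m[, a + 1L],
               vapply(placements, function(p) {
                 ifelse(is.na(p$at_match[a + 1L]), GAP, p$at_match[a + 1L])
               }, character(1)))
      if (nq == 0L) col <- sub_m[, a + 1L]
      add_col(col, unit$map[a + 1L])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- c(bids, qids)
  aln <- matrix_to_aln(m, sub$alphabet, normalize = FALSE)
  extended_subalignment(aln, labels, unit, batch_index)
}

#' Default external backend command template
#'
#' Mirrors MAFFT `--add` usage with the accurate L-INS-i settings; the
#' placeholders `{queries}`, `{backbone}` and `{output}` are substituted
#' with file paths at run time.
#' @return Character command template.
#' @export
default_backend_cmd <- function() {
  "mafft --localpair --maxiterate 1000 --quiet --add {queries} {backbone} > {output}"
}

#' Add queries to a subalignment with an external aligner
#'
#' Runs a user-configurable shell command (default: MAFFT L-INS-i
#' `--add`) with the unit's subalignment as the fixed alignment and the
#' batch as the sequences to add.  The output is never trusted: it is
#' re-validated against the induction contract and its columns are
#' labeled by matching the induced columns back to the subalignment.
#'
#' @param unit A unit from [build_units()].
#' @param batch Named character vector of ungapped query sequences.
#' @param backend_cmd Command template with `{backbone}`, `{queries}`,
#'   `{output}` placeholders (default [default_backend_cmd()]).
#' @param batch_index Batch index within the unit (default 1).
#' @param workdir Directory for the subproblem's files (default a fresh
#'   temporary directory).
#' @return An `extended_subalignment`.
#' @export
extend_external <- function(unit, batch, backend_cmd = default_backend_cmd(),
                            batch_index = 1L, workdir = tempfile("subproblem")) {
  if (length(batch) == 0L) return(extend_fallback(unit, batch, batch_index))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  f_back <- file.path(workdir, "backbone.fasta")
  f_qry <- file.path(workdir, "queries.fasta")
  f_out <- file.path(workdir, "extended.fasta")
  f_err <- file.path(workdir, "stderr.log")
  write_fasta(unit$subalignment, f_back)
  write_fasta(batch, f_qry)
  cmd <- backend_cmd
  cmd <- gsub("{backbone}", shQuote(f_back), cmd, fixed = TRUE)
  cmd <- gsub("{queries}", shQuote(f_qry), cmd, fixed = TRUE)
  cmd <- gsub("{output}", shQuote(f_out), cmd, fixed = TRUE)
  status <- system2("sh", c("-c", shQuote(cmd)), stderr = f_err)
  if (status != 0L)
    stop("external backend failed (exit ", status, ") for unit ",
         unit$index, " batch ", batch_index, "; stderr:\n",
         paste(readLines(f_err, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  out <- read_alignment(f_out, unit$subalignment$alphabet, normalize = TRUE)
  if (!setequal(alignment_ids(out),
                c(alignment_ids(unit$subalignment), names(batch))))
    stop("backend output does not contain exactly the expected sequences",
         call. = FALSE)
  if (!induces(out, unit$subalignment))
    stop("backend violated the constraint: output does not induce the ",
         "subalignment of unit ", unit$index, call. = FALSE)
  ind <- induce_subalignment(out, alignment_ids(unit$subalignment))
  labels <- rep(NA_integer_, n_columns(out))
  labels[ind$map] <- unit$map
  extended_subalignment(out, labels, unit, batch_index)
}
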