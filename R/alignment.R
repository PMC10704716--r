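#' @useDynLib msaextend, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GAP <- "-"

#' Residue alphabets
#'
#' Letter sets for the two supported alphabets.  Nucleotide covers both DNA
#' and RNA (T and U); amino acid is the standard 20-letter set.  Letters
#' outside the declared alphabet (ambiguity codes, X, ...) are carried
#' through unchanged and scored as ordinary letters by the error metrics;
#' the HMM scorer treats them as background-emitted.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Character vector of residue letters.
#' @export
alphabet_letters <- function(alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") c("A", "C", "G", "T", "U")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' Construct an alignment object
#'
#' An alignment is a named character vector of equal-length gapped strings
#' plus a declared alphabet.  Input is case-normalized to upper and the
#' `.` gap dialect is converted to `-`.
#'
#' @param seqs Named character vector, one gapped string per sequence.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param normalize Drop columns that are entirely gaps (default `TRUE`).
#' @return An object of class `msa_alignment`.
#' @export
alignment <- function(seqs, alphabet = c("nucleotide", "protein"),
                      normalize = TRUE) {
  alphabet <- match.arg(alphabet)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(seqs)
  seqs <- gsub(".", GAP, seqs, fixed = TRUE)
  if (length(seqs) == 0L)
    stop("alignment must contain at least one sequence", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("aligned records must all have the same length (found lengths ",
         paste(sort(L), collapse = ", "), ")", call. = FALSE)
  obj <- structure(list(seqs = seqs, alphabet = alphabet),
                   class = "msa_alignment")
  if (normalize) obj <- drop_allgap_columns(obj)
  obj
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns (%s)\n",
              n_rows(x), n_columns(x), x$alphabet))
  invisible(x)
}

#' Number of alignment columns
#' @param aln An `msa_alignment`.
#' @return Integer column count.
#' @export
n_columns <- function(aln) {
  if (length(aln$seqs) == 0L) return(0L)
  nchar(aln$seqs[[1L]])
}

#' Number of alignment rows
#' @param aln An `msa_alignment`.
#' @return Integer row count.
#' @export
n_rows <- function(aln) length(aln$seqs)

#' Sequence ids of an alignment
#' @param aln An `msa_alignment`.
#' @return Character vector of ids in row order.
#' @export
alignment_ids <- function(aln) names(aln$seqs)

# rows x cols character matrix view (rownames = ids)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), nrow = 0, ncol = 0)
  rownames(m) <- names(aln$seqs)
  m
}

matrix_to_aln <- function(m, alphabet, normalize = FALSE) {
  seqs <- apply(m, 1L, paste0, collapse = "")
  if (nrow(m) > 0 && ncol(m) == 0L) seqs <- setNames(rep("", nrow(m)), rownames(m))
  names(seqs) <- rownames(m)
  alignment(seqs, alphabet, normalize = normalize)
}

#' Remove columns that are entirely gaps
#' @param aln An `msa_alignment`.
#' @return The alignment without all-gap columns.
#' @export
drop_allgap_columns <- function(aln) {
  m <- aln_matrix(aln)
  if (ncol(m) == 0L) return(aln)
  keep <- colSums(m != GAP) > 0L
  m <- m[, keep, drop = FALSE]
  seqs <- setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
  if (ncol(m) == 0L) seqs <- setNames(rep("", nrow(m)), rownames(m))
  structure(list(seqs = seqs, alphabet = aln$alphabet), class = "msa_alignment")
}

#' Ungapped sequences of an alignment
#' @param aln An `msa_alignment`.
#' @return Named character vector of residue strings with gaps removed.
#' @export
ungap <- function(aln) {
  vapply(aln$seqs, function(s) gsub(GAP, "", s, fixed = TRUE), character(1))
}

#' Read an aligned FASTA file
#'
#' All records must have equal length.  Case is normalized to upper, `.`
#' gaps are converted to `-`, and ids are taken as the first whitespace
#' delimited token of each header.
#'
#' @param path File path.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param normalize Drop all-gap columns (default `TRUE`).
#' @return An `msa_alignment`.
#' @export
read_alignment <- function(path, alphabet = c("nucleotide", "protein"),
                           normalize = TRUE) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", trimws(names(ss)))
  alignment(seqs, alphabet, normalize = normalize)
}

#' Read unaligned FASTA sequences
#'
#' @param path File path.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector of ungapped upper-case residue strings.
#' @export
read_sequences <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[.-]", "", seqs)
  names(seqs) <- sub("\\s.*$", "", trimws(names(ss)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty sequence records in ", path, call. = FALSE)
  seqs
}

#' Write sequences or an alignment to FASTA
#'
#' @param x An `msa_alignment` or a named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "msa_alignment")) x$seqs else x
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Restrict an alignment to a subset of its rows
#'
#' Returns the induced subalignment: the rows for `ids` with columns that
#' became entirely gaps removed, together with the column map from child
#' columns back to parent columns (`NA`-free, strictly increasing).
#'
#' @param parent An `msa_alignment`.
#' @param ids Character vector of row ids to keep (subset of the parent's).
#' @return A list with elements `alignment` (the induced subalignment) and
#'   `map` (integer vector: for each child column, its 1-based parent
#'   column index).
#' @export
induce_subalignment <- function(parent, ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("ids must be non-empty", call. = FALSE)
  missing <- setdiff(ids, alignment_ids(parent))
  if (length(missing))
    stop("ids not present in alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- aln_matrix(parent)[ids, , drop = FALSE]
  keep <- which(colSums(m != GAP) > 0L)
  m <- m[, keep, drop = FALSE]
  seqs <- setNames(apply(m, 1L, paste0, collapse = ""), ids)
  if (length(keep) == 0L) seqs <- setNames(rep("", length(ids)), ids)
  child <- structure(list(seqs = seqs, alphabet = parent$alphabet),
                     class = "msa_alignment")
  list(alignment = child, map = as.integer(keep))
}

#' Does one alignment induce another?
#'
#' `candidate` induces `constraint` if restricting `candidate` to the
#' constraint's rows and removing all-gap columns on both sides yields
#' exactly the constraint (row order ignored).
#'
#' @param candidate An `msa_alignment` containing all constraint rows.
#' @param constraint An `msa_alignment`.
#' @return `TRUE` or `FALSE`.
#' @export
induces <- function(candidate, constraint) {
  cids <- alignment_ids(constraint)
  missing <- setdiff(cids, alignment_ids(candidate))
  if (length(missing))
    stop("constraint rows missing from candidate: ",
         paste(missing, collapse = ", "), call. = FALSE)
  restricted <- induce_subalignment(candidate, cids)$alignment
  ref <- drop_allgap_columns(constraint)
  identical(restricted$seqs[cids], ref$seqs[cids])
}

#' Read a Newick guide tree
#'
#' Leaf labels must match the backbone ids byte-exactly after whitespace
#' trimming.
#'
#' @param path Newick file path.
#' @param backbone_ids Optional character vector; if given the leaf set is
#'   validated against it.
#' @return An `ape::phylo` tree.
#' @export
read_guide_tree <- function(path, backbone_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in guide tree", call. = FALSE)
  if (!is.null(backbone_ids)) {
    if (!setequal(tree$tip.label, backbone_ids))
      stop("guide tree leaf set does not match backbone ids (",
           length(setdiff(backbone_ids, tree$tip.label)), " missing, ",
           length(setdiff(tree$tip.label, backbone_ids)), " extra)",
           call. = FALSE)
  }
  tree
}
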