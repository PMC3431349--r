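# BLOSUM62 cached from the Biostrings data set on first use.
.sialevo_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.sialevo_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sialevo_env$BLOSUM62 <- e$BLOSUM62
  }
  .sialevo_env$BLOSUM62
}

#' Scoring parameters for pairwise local alignment
#'
#' Defaults follow protein-BLAST conventions: BLOSUM62 with affine gap
#' penalties of 11 (open) and 1 (extend); opening a gap costs
#' `gap_open + gap_extend` for its first residue.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped) or
#'   a symmetric numeric matrix.
#' @param gap_open,gap_extend positive gap penalties.
#' @return object of class `score_params`.
#' @export
score_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("unknown substitution matrix: ", matrix)
    mat <- get_blosum62()
  } else {
    mat <- matrix
    if (!isTRUE(all.equal(mat, t(mat)))) stop("substitution matrix must be symmetric")
  }
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "score_params")
}

#' Best local alignment score of two ungapped protein sequences
#'
#' Smith-Waterman local alignment under an affine gap model, the package's
#' stand-in for BLAST bit scores in reciprocal-best-hit assignment (only the
#' similarity ranking matters there).
#'
#' @param a,b ungapped protein strings.
#' @param params a [score_params()].
#' @return numeric score (symmetric in `a`, `b`).
#' @export
pairwise_score <- function(a, b, params = score_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
}

# All-vs-all score matrix, queries x references (vectorized per reference).
local_score_matrix <- function(queries, references, params = score_params()) {
  qset <- Biostrings::AAStringSet(toupper(queries))
  out <- vapply(references, function(r) {
    Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(toupper(r)), type = "local",
      substitutionMatrix = params$matrix, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
  }, numeric(length(queries)))
  out <- matrix(out, nrow = length(queries),
                dimnames = list(names(queries), names(references)))
  out
}

# index of the best score; ties broken by lexicographic order of the names,
# with a warning.
best_hit <- function(scores, what) {
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    warning("tied best scores for ", what, "; breaking by id order")
    best <- best[order(names(scores)[best])]
  }
  best[1L]
}

#' Reciprocal-best-hit subfamily assignment
#'
#' Each query is scored against every labelled reference; it inherits the
#' subgroup of its best-scoring reference iff it is, in turn, that
#' reference's best-scoring query among all queries (a reciprocal best hit).
#' Queries failing the reciprocity check are reported with `mutual = FALSE`
#' and subgroup `"unassigned"`.
#'
#' @param queries named character vector of ungapped query sequences.
#' @param references named character vector of ungapped reference sequences.
#' @param ref_labels named character vector: subgroup label per reference id.
#' @param params a [score_params()].
#' @return data.frame with columns `id`, `subgroup`, `best_ref`, `mutual`,
#'   `score`, in the order of `queries`.
#' @export
rbh_assign <- function(queries, references, ref_labels,
                       params = score_params()) {
  if (is.null(names(queries)) || is.null(names(references)))
    stop("queries and references must be named")
  if (!all(names(references) %in% names(ref_labels)))
    stop("every reference needs a subgroup label")
  S <- local_score_matrix(queries, references, params)
  # put rows/cols in stable order so the result is permutation-invariant
  S <- S[order(rownames(S)), order(colnames(S)), drop = FALSE]
  best_ref <- vapply(rownames(S), function(q)
    colnames(S)[best_hit(S[q, ], paste("query", q))], character(1))
  best_query <- vapply(colnames(S), function(r)
    rownames(S)[best_hit(S[, r], paste("reference", r))], character(1))
  mutual <- best_query[best_ref] == rownames(S)
  out <- data.frame(
    id = rownames(S),
    subgroup = ifelse(mutual, unname(ref_labels[best_ref]), "unassigned"),
    best_ref = unname(best_ref),
    mutual = unname(mutual),
    score = S[cbind(rownames(S), best_ref)],
    stringsAsFactors = FALSE)
  out[match(names(queries), out$id), , drop = FALSE]
}

#' Subfamily-specific residues by frequency contrast
#'
#' Operationalizes the subfamily-logo idea as frequency thresholds: at each
#' alignment column the most frequent unambiguous residue of the in-group is
#' called specific iff it occurs in at least `in_threshold` of the in-group
#' sequences and at most `out_threshold` of the out-group sequences
#' (gap-inclusive denominators, so a gappy column cannot reach a high
#' in-group frequency).
#'
#' @param aln a `sial_aln`.
#' @param group_in,group_out disjoint, non-empty character vectors of
#'   sequence ids.
#' @param in_threshold,out_threshold frequency thresholds (defaults 0.7 and
#'   0.2).
#' @param ref_id optional reference sequence id; when given, calls are also
#'   reported in that sequence's residue coordinates (`NA` where it has a
#'   gap).
#' @return data.frame with columns `column`, `residue`, `freq_in`,
#'   `freq_out` and (if `ref_id` is given) `ref_pos`.
#' @export
subfamily_specific_residues <- function(aln, group_in, group_out,
                                        in_threshold = 0.7,
                                        out_threshold = 0.2,
                                        ref_id = NULL) {
  if (!length(group_in) || !length(group_out)) stop("groups must be non-empty")
  if (length(intersect(group_in, group_out)))
    stop("groups must be disjoint")
  check_ids(aln, c(group_in, group_out))
  min_mat <- aln$mat[group_in, , drop = FALSE]
  mout <- aln$mat[group_out, , drop = FALSE]
  L <- alignment_length(aln)
  res <- character(L); fin <- numeric(L); fout <- numeric(L)
  for (j in seq_len(L)) {
    col_in <- min_mat[, j]
    tab <- table(col_in[col_in %in% AA_LETTERS])
    if (!length(tab)) { res[j] <- NA_character_; next }
    r <- names(tab)[which.max(tab)]
    res[j] <- r
    fin[j] <- sum(col_in == r) / length(group_in)
    fout[j] <- sum(mout[, j] == r) / length(group_out)
  }
  keep <- !is.na(res) & fin >= in_threshold & fout <= out_threshold
  out <- data.frame(column = which(keep), residue = res[keep],
                    freq_in = fin[keep], freq_out = fout[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(ref_id)) {
    cm <- coordinate_map(aln, ref_id)
    out$ref_pos <- if (nrow(out)) column_to_residue(cm, out$column) else integer(0)
  }
  out
}
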