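SUBGROUPS <- c("NEU1", "NEU2", "NEU3", "NEU4", "NEU5", "unknown")
TAXON_GROUPS <- c("mammals", "vertebrates", "deuterostomes", "early_metazoa",
                  "unknown")

#' Construct a labelled protein multiple alignment
#'
#' The central data container: equal-length aligned protein sequences with
#' per-sequence subgroup and taxonomic-group labels.  Taxon groups are
#' nested (mammals are vertebrates are deuterostomes); membership queries
#' should go through [taxon_members()].
#'
#' @param seqs named character vector of aligned sequences (upper case is
#'   enforced); gaps are `-` only.
#' @param metadata optional data.frame with columns `id`, `subgroup`
#'   (`NEU1`..`NEU5` or `unknown`) and `taxon_group` (`mammals`,
#'   `vertebrates`, `deuterostomes`, `early_metazoa` or `unknown`).
#'   Sequences without a row are labelled `unknown`.
#' @return an object of class `sial_aln`.
#' @export
sial_alignment <- function(seqs, metadata = NULL) {
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " differ in length from the first sequence (", lens[1L], ")")
  }
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("'.' gap characters are not accepted; use '-' only")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  ok <- c(AA_LETTERS, AA_AMBIGUOUS, GAP_CHAR)
  bad_chars <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad_chars))
    stop("invalid residue characters: ", paste(bad_chars, collapse = " "))

  meta <- data.frame(id = ids, subgroup = "unknown", taxon_group = "unknown",
                     stringsAsFactors = FALSE)
  if (!is.null(metadata) && nrow(metadata)) {
    need <- c("id", "subgroup", "taxon_group")
    if (!all(need %in% names(metadata)))
      stop("metadata needs columns: ", paste(need, collapse = ", "))
    bad_sub <- setdiff(unique(metadata$subgroup), SUBGROUPS)
    if (length(bad_sub))
      stop("unknown subgroup token(s): ", paste(bad_sub, collapse = ", "),
           "; valid tokens: ", paste(SUBGROUPS, collapse = ", "))
    bad_tax <- setdiff(unique(metadata$taxon_group), TAXON_GROUPS)
    if (length(bad_tax))
      stop("unknown taxon_group token(s): ", paste(bad_tax, collapse = ", "),
           "; valid tokens: ", paste(TAXON_GROUPS, collapse = ", "))
    missing_ids <- setdiff(metadata$id, ids)
    if (length(missing_ids)) {
      warning("metadata ids absent from alignment, skipped: ",
              paste(missing_ids, collapse = ", "))
      metadata <- metadata[metadata$id %in% ids, , drop = FALSE]
    }
    idx <- match(metadata$id, meta$id)
    meta$subgroup[idx] <- metadata$subgroup
    meta$taxon_group[idx] <- metadata$taxon_group
  }
  structure(list(mat = mat, metadata = meta), class = "sial_aln")
}

#' @export
print.sial_aln <- function(x, ...) {
  cat("Protein multiple alignment:", nrow(x$mat), "sequences x",
      ncol(x$mat), "columns\n")
  tab <- table(x$metadata$subgroup)
  cat("  subgroups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.matrix.sial_aln <- function(x, ...) x$mat

#' Number of sequences / alignment length
#' @param aln a `sial_aln`.
#' @return integer.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Sequence ids of an alignment
#' @param aln a `sial_aln`.
#' @export
alignment_ids <- function(aln) rownames(aln$mat)

#' Ungapped sequence(s)
#'
#' @param aln a `sial_aln`.
#' @param ids sequence ids (default all).
#' @return named character vector of sequences with gaps removed.
#' @export
ungapped_sequences <- function(aln, ids = alignment_ids(aln)) {
  check_ids(aln, ids)
  out <- apply(aln$mat[ids, , drop = FALSE], 1L,
               function(r) paste(r[r != GAP_CHAR], collapse = ""))
  stats::setNames(as.character(out), ids)
}

check_ids <- function(aln, ids) {
  bad <- setdiff(ids, alignment_ids(aln))
  if (length(bad)) stop("unknown sequence id(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Members of a subgroup
#' @param aln a `sial_aln`.
#' @param subgroup one of `NEU1`..`NEU5` or `unknown`.
#' @return character vector of sequence ids.
#' @export
subgroup_members <- function(aln, subgroup) {
  subgroup <- match.arg(subgroup, SUBGROUPS)
  aln$metadata$id[aln$metadata$subgroup == subgroup]
}

#' Members of a (nested) taxonomic group
#'
#' Taxon groups are nested: `mammals` are contained in `vertebrates`, which
#' are contained in `deuterostomes`; `early_metazoa` is the outgroup and is
#' not nested.  Membership is resolved accordingly from each sequence's
#' most-specific label.
#'
#' @param aln a `sial_aln`.
#' @param taxon_group one of `mammals`, `vertebrates`, `deuterostomes`,
#'   `early_metazoa`.
#' @return character vector of sequence ids.
#' @export
taxon_members <- function(aln, taxon_group) {
  taxon_group <- match.arg(taxon_group, setdiff(TAXON_GROUPS, "unknown"))
  lab <- aln$metadata$taxon_group
  keep <- switch(taxon_group,
    mammals = lab == "mammals",
    vertebrates = lab %in% c("mammals", "vertebrates"),
    deuterostomes = lab %in% c("mammals", "vertebrates", "deuterostomes"),
    early_metazoa = lab == "early_metazoa")
  aln$metadata$id[keep]
}

#' Read a FASTA protein multiple alignment
#'
#' @param path FASTA file.
#' @param metadata optional metadata data.frame or path to a metadata TSV
#'   (see [read_metadata()]).
#' @return a `sial_aln`.
#' @export
read_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- stats::setNames(as.character(set),
                          sub("\\s.*$", "", names(set)))
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  sial_alignment(seqs, metadata)
}

#' Write an alignment to FASTA
#' @param aln a `sial_aln`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(aln$mat), "\n", seqs), path)
  invisible(path)
}

#' Read per-sequence metadata
#'
#' Tab-separated with header columns `id`, `subgroup`, `taxon_group`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "subgroup", "taxon_group")
  if (!all(need %in% names(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Write a result table as TSV
#'
#' Tables carry a `# key: value` comment header (used by the pipeline to
#' embed the configuration hash); [read_result_table()] ignores it.
#'
#' @param df data.frame.
#' @param path output file.
#' @param comments optional named character vector written as `# name: value`
#'   header lines.
#' @export
write_result_table <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", names(comments), ": ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read / write trees in newick format
#'
#' Thin wrappers with the package's error conventions; branch lengths
#' round-trip to at least six decimals.
#'
#' @param path newick file.
#' @return `read_tree`: an `ape::phylo`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' @rdname read_tree
#' @param tree an `ape::phylo`.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
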