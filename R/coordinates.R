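#' Residue/column coordinate map for one sequence
#'
#' Maps 1-based residue positions of a sequence (its ungapped numbering, the
#' convention used for reference coordinates such as the human NEU2 residue
#' numbering) to 1-based global alignment columns, and back.  Gap columns
#' have no residue; ambiguity letters are residues and are numbered.
#'
#' @param aln a `sial_aln`.
#' @param seq_id sequence id.
#' @return object of class `coord_map`: list with `seq_id`,
#'   `col_of_residue` (integer vector indexed by residue) and
#'   `residue_of_col` (integer vector of length L, `NA` at gap columns).
#' @export
coordinate_map <- function(aln, seq_id) {
  check_ids(aln, seq_id)
  row <- aln$mat[seq_id, ]
  nongap <- which(row != GAP_CHAR)
  residue_of_col <- rep(NA_integer_, length(row))
  residue_of_col[nongap] <- seq_along(nongap)
  structure(list(seq_id = seq_id,
                 col_of_residue = nongap,
                 residue_of_col = residue_of_col),
            class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  cat("Coordinate map for", x$seq_id, ":", length(x$col_of_residue),
      "residues over", length(x$residue_of_col), "columns\n")
  invisible(x)
}

#' Alignment column of a residue
#' @param cmap a `coord_map`.
#' @param residue 1-based residue position(s).
#' @return integer column(s).
#' @export
residue_to_column <- function(cmap, residue) {
  if (any(residue < 1L | residue > length(cmap$col_of_residue)))
    stop("residue position out of range for ", cmap$seq_id,
         " (length ", length(cmap$col_of_residue), ")")
  cmap$col_of_residue[residue]
}

#' Residue at an alignment column
#' @param cmap a `coord_map`.
#' @param column 1-based alignment column(s).
#' @return integer residue position(s); `NA` where the sequence has a gap.
#' @export
column_to_residue <- function(cmap, column) {
  if (any(column < 1L | column > length(cmap$residue_of_col)))
    stop("column out of range (alignment length ",
         length(cmap$residue_of_col), ")")
  cmap$residue_of_col[column]
}

#' Per-column site coverage
#'
#' Fraction of sequences carrying an unambiguous residue (not a gap, not an
#' ambiguity letter) at each requested column.
#'
#' @param aln a `sial_aln`.
#' @param columns columns to evaluate (default all).
#' @return numeric vector in \[0, 1\].
#' @export
site_coverage <- function(aln, columns = seq_len(alignment_length(aln))) {
  L <- alignment_length(aln)
  if (any(columns < 1L | columns > L))
    stop("column out of range (alignment length ", L, ")")
  sub <- aln$mat[, columns, drop = FALSE]
  counted <- matrix(sub %in% AA_LETTERS, nrow = nrow(sub))
  colSums(counted) / nrow(sub)
}

#' Columns passing a coverage threshold
#'
#' @param aln a `sial_aln`.
#' @param min_coverage coverage threshold in \[0, 1\].
#' @param strict if `TRUE`, keep columns with coverage strictly greater than
#'   the threshold (the "more than 70%" rule); if `FALSE`, greater-or-equal
#'   (the "at least 50%" rule).
#' @return ascending integer vector of retained columns.
#' @export
filter_columns <- function(aln, min_coverage, strict = FALSE) {
  if (min_coverage < 0 || min_coverage > 1)
    stop("min_coverage must be in [0, 1]")
  cov <- site_coverage(aln)
  if (strict) which(cov > min_coverage) else which(cov >= min_coverage)
}
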