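PHOSPHO_RESIDUES <- c("S", "T", "Y")

#' Map predicted phosphorylation sites to alignment columns
#'
#' Sites are `(seq_id, residue_pos, residue)` rows, e.g. parsed predictor
#' output for one representative protein per subfamily.  Each site is
#' validated against its sequence and projected to its global alignment
#' column; columns hit by several proteins (equivalent positions) collapse
#' to one.
#'
#' @param sites data.frame with columns `seq_id`, `residue_pos`, `residue`
#'   (residue must be one of S, T, Y).
#' @param aln a `sial_aln`.
#' @return ascending integer vector of distinct alignment columns.
#' @export
map_sites_to_columns <- function(sites, aln) {
  if (!nrow(sites)) return(integer(0))
  need <- c("seq_id", "residue_pos", "residue")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  if (!all(sites$residue %in% PHOSPHO_RESIDUES))
    stop("site residues must be S, T or Y")
  cols <- integer(nrow(sites))
  for (id in unique(sites$seq_id)) {
    check_ids(aln, id)
    cm <- coordinate_map(aln, id)
    idx <- which(sites$seq_id == id)
    pos <- sites$residue_pos[idx]
    if (any(pos > length(cm$col_of_residue)))
      stop("site position beyond sequence length for ", id)
    cc <- residue_to_column(cm, pos)
    actual <- aln$mat[id, cc]
    bad <- actual != sites$residue[idx]
    if (any(bad))
      stop("site residue mismatch for ", id, " at position ",
           paste(pos[bad], collapse = ", "), " (found ",
           paste(actual[bad], collapse = ", "), ")")
    cols[idx] <- cc
  }
  sort(unique(cols))
}

#' Background frequency of phosphorylatable residues
#'
#' The fraction of Ser/Thr/Tyr among all residues of the alignment.  The
#' denominator counts every non-gap, unambiguous residue across all
#' sequences (gap cells are not sites; ambiguity letters are excluded).
#'
#' @param aln a `sial_aln`.
#' @return list with `p` (fraction) and `total_sites` (denominator).
#' @export
background_frequency <- function(aln) {
  v <- as.vector(aln$mat)
  total <- sum(v %in% AA_LETTERS)
  if (total == 0L) stop("alignment has no residues")
  k <- sum(v %in% PHOSPHO_RESIDUES)
  list(p = k / total, total_sites = total)
}

#' Conservation of phosphorylatable residues at a column
#'
#' Percentage of group sequences carrying S, T or Y at the column,
#' regardless of which of the three was predicted.  With
#' `denominator = "nongap"` (the default) sequences with a gap or an
#' ambiguity letter at the column are left out of the denominator, which is
#' the convention the family's published per-group percentages follow (e.g.
#' a 40-member subgroup with 3 gapped sequences is scored out of 37);
#' `"all"` keeps every group member in the denominator.
#'
#' @param aln a `sial_aln`.
#' @param column 1-based alignment column.
#' @param group sequence ids (defaults to all sequences).
#' @param denominator `"nongap"` or `"all"`.
#' @return percentage in \[0, 100\].
#' @export
column_conservation <- function(aln, column, group = alignment_ids(aln),
                                denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  if (!length(group)) stop("group must be non-empty")
  check_ids(aln, group)
  if (column < 1L || column > alignment_length(aln))
    stop("column out of range")
  col <- aln$mat[group, column]
  n <- if (denominator == "all") length(group) else sum(col %in% AA_LETTERS)
  if (n == 0L) return(0)
  100 * sum(col %in% PHOSPHO_RESIDUES) / n
}

#' One-sided binomial conservation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(N, p)`, evaluated by
#' exact summation of the binomial mass (no normal approximation): the
#' chance of seeing at least `k` phosphorylatable residues in a column of
#' `N` sequences when they occur at the background rate `p`.
#'
#' @param k observed count of S/T/Y residues in the column.
#' @param N number of sequences.
#' @param p background S/T/Y frequency, strictly between 0 and 1.
#' @return p-value.
#' @export
binomial_conservation_test <- function(k, N, p) {
  if (k < 0 || k > N) stop("k must be in [0, N]")
  if (p <= 0 || p >= 1) stop("background frequency p must be in (0, 1)")
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = N, prob = p, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Point-probability rule: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table (the classical two-sided convention).
#'
#' @param tab 2x2 matrix of non-negative counts, or the four counts
#'   `c(a, b, c, d)` row-wise.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(dim(tab) != 2L)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0L) return(1)
  stats::fisher.test(tab)$p.value
}

#' Group-vs-rest contingency table at a column
#'
#' Rows: the group of interest vs its complement; columns: phosphorylatable
#' (S/T/Y) vs not.  With `denominator = "nongap"` (default) gapped and
#' ambiguous cells are dropped; with `"all"` they count as
#' non-phosphorylatable.
#'
#' @param aln a `sial_aln`.
#' @param column alignment column.
#' @param group sequence ids of the group of interest.
#' @param complement ids of the comparison set (default: all others).
#' @param denominator `"nongap"` or `"all"`.
#' @return 2x2 integer matrix `[group/rest x phospho/other]`.
#' @export
build_group_contingency <- function(aln, column, group,
                                    complement = setdiff(alignment_ids(aln), group),
                                    denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  if (!length(group)) stop("group must be non-empty")
  if (length(intersect(group, complement)))
    stop("group and complement must be disjoint")
  check_ids(aln, c(group, complement))
  count_row <- function(ids) {
    col <- aln$mat[ids, column]
    a <- sum(col %in% PHOSPHO_RESIDUES)
    n <- if (denominator == "all") length(ids) else sum(col %in% AA_LETTERS)
    c(a, n - a)
  }
  out <- rbind(count_row(group), count_row(complement))
  dimnames(out) <- list(c("group", "rest"), c("phospho", "other"))
  out
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param m family size (default: the number of p-values).
#' @return corrected p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Per-column conservation statistics for mapped phospho columns
#'
#' For every column: the global S/T/Y count `k` and binomial test against
#' the alignment-wide background (N = number of sequences, as in the
#' original protocol), conservation percentages globally, per subgroup and
#' per nested taxonomic group, and group-vs-rest Fisher tests.  Binomial
#' p-values are Bonferroni-corrected over the columns; each Fisher grouping
#' scheme forms its own correction family of the same size.
#'
#' @param aln a `sial_aln` with subgroup/taxon metadata.
#' @param columns alignment columns to test (e.g. from
#'   [map_sites_to_columns()]).
#' @param denominator passed to [column_conservation()] and
#'   [build_group_contingency()].
#' @param m Bonferroni family size (default `length(columns)`).
#' @return data.frame of class `phospho_stats`, one row per column.
#' @export
phospho_column_stats <- function(aln, columns,
                                 denominator = c("nongap", "all"),
                                 m = length(columns)) {
  denominator <- match.arg(denominator)
  if (!length(columns)) stop("no columns to test")
  bg <- background_frequency(aln)
  N <- n_sequences(aln)
  ids <- alignment_ids(aln)
  # a grouping scheme needs both a non-empty group and a non-empty rest
  proper <- function(n) n > 0L && n < n_sequences(aln)
  subgroups <- setdiff(intersect(SUBGROUPS, unique(aln$metadata$subgroup)),
                       "unknown")
  subgroups <- subgroups[vapply(subgroups, function(sg)
    proper(length(subgroup_members(aln, sg))), TRUE)]
  taxa <- setdiff(TAXON_GROUPS, "unknown")
  taxa <- taxa[vapply(taxa, function(tx)
    proper(length(taxon_members(aln, tx))), TRUE)]

  out <- data.frame(column = columns)
  out$k <- vapply(columns, function(j)
    sum(aln$mat[, j] %in% PHOSPHO_RESIDUES), integer(1))
  out$N <- N
  out$background_p <- bg$p
  out$cons_total <- vapply(columns, function(j)
    column_conservation(aln, j, ids, denominator), numeric(1))
  out$p_binomial_raw <- vapply(out$k, binomial_conservation_test,
                               numeric(1), N = N, p = bg$p)
  out$p_binomial_adj <- bonferroni(out$p_binomial_raw, m)

  add_group <- function(out, tag, members) {
    cons <- vapply(columns, function(j)
      column_conservation(aln, j, members, denominator), numeric(1))
    praw <- vapply(columns, function(j)
      fisher_exact_2x2(build_group_contingency(aln, j, members,
                                               denominator = denominator)),
      numeric(1))
    out[[paste0("cons_", tag)]] <- cons
    out[[paste0("p_fisher_raw_", tag)]] <- praw
    out[[paste0("p_fisher_adj_", tag)]] <- bonferroni(praw, m)
    out
  }
  for (sg in subgroups)
    out <- add_group(out, sg, subgroup_members(aln, sg))
  for (tx in taxa)
    out <- add_group(out, tx, taxon_members(aln, tx))
  attr(out, "subgroups") <- subgroups
  attr(out, "taxa") <- taxa
  class(out) <- c("phospho_stats", class(out))
  out
}

#' Flag conserved and group-specific phospho columns
#'
#' Applies the published relevance rules: a column is globally conserved at
#' the 60 (90) level when its Bonferroni-corrected binomial p-value is below
#' `alpha` and its overall conservation reaches `cons60` (`cons90`)
#' percent; it is specific to a subgroup or taxonomic group when that
#' group's corrected Fisher p-value is below `alpha` and its conservation in
#' the group reaches `cons60`.
#'
#' @param stats a [phospho_column_stats()] table.
#' @param alpha significance level after correction (default 0.01).
#' @param cons60,cons90 conservation cutoffs in percent.
#' @return the table with added columns `flag_global60`, `flag_global90`,
#'   `specific_subgroups`, `specific_taxa` (comma-separated labels, empty
#'   when none).
#' @export
classify_sites <- function(stats, alpha = 0.01, cons60 = 60, cons90 = 90) {
  stats$flag_global60 <- stats$p_binomial_adj < alpha & stats$cons_total >= cons60
  stats$flag_global90 <- stats$p_binomial_adj < alpha & stats$cons_total >= cons90
  collect <- function(tags) {
    if (!length(tags)) return(rep("", nrow(stats)))
    hit <- vapply(tags, function(tag)
      stats[[paste0("p_fisher_adj_", tag)]] < alpha &
        stats[[paste0("cons_", tag)]] >= cons60,
      logical(nrow(stats)))
    hit <- matrix(hit, nrow = nrow(stats))
    apply(hit, 1L, function(h) paste(tags[h], collapse = ","))
  }
  stats$specific_subgroups <- collect(attr(stats, "subgroups"))
  stats$specific_taxa <- collect(attr(stats, "taxa"))
  stats
}

#' Conservation heatmap matrix (columns x groups)
#'
#' The columns-by-groups matrix of conservation percentages behind the
#' usual heatmap display of phospho-site conservation.
#'
#' @param stats a [phospho_column_stats()] table.
#' @return numeric matrix; rows named by alignment column.
#' @export
conservation_matrix <- function(stats) {
  tags <- c("total", attr(stats, "subgroups"), attr(stats, "taxa"))
  out <- vapply(tags, function(tag) stats[[paste0("cons_", tag)]],
                numeric(nrow(stats)))
  out <- matrix(out, nrow = nrow(stats),
                dimnames = list(stats$column, tags))
  out
}
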