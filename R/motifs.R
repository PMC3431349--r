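# Sequence signatures of the sialidase beta-propeller: the Asp-box
# (S-x-D-x-G-x-x-[W/F]) repeated on the loops between the third and fourth
# strand of blades I-V, and the [T/F]-Y-R-[I/V]-P motif near the N-terminus.
MOTIF_PATTERNS <- list(
  aspbox = list(regex = "S.D.G..[WF]", length = 8L),
  nterm  = list(regex = "[TF]YR[IV]P", length = 5L)
)

#' Scan an ungapped protein sequence for a named motif
#'
#' All match start positions are reported, including overlapping ones
#' (left to right).
#'
#' @param seq ungapped protein string.
#' @param pattern_name `"aspbox"` or `"nterm"`.
#' @return data.frame with columns `pattern_name`, `start`, `end`,
#'   `matched_text` (zero rows when there is no hit).
#' @export
scan_motif <- function(seq, pattern_name = c("aspbox", "nterm")) {
  pattern_name <- match.arg(pattern_name)
  if (grepl(GAP_CHAR, seq, fixed = TRUE))
    stop("scan_motif() requires an ungapped sequence; de-gap first")
  seq <- toupper(seq)
  pat <- MOTIF_PATTERNS[[pattern_name]]
  # zero-width lookahead so overlapping starts are all found
  m <- gregexpr(paste0("(?=", pat$regex, ")"), seq, perl = TRUE)[[1L]]
  starts <- as.integer(m)
  if (length(starts) == 0L || (length(starts) == 1L && starts == -1L))
    return(data.frame(pattern_name = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE))
  ends <- starts + pat$length - 1L
  data.frame(pattern_name = rep(pattern_name, length(starts)),
             start = starts, end = ends,
             matched_text = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

# Motif hits for every sequence of a set, in alignment coordinates.
motif_hits_in_alignment <- function(aln, ids, pattern_name) {
  out <- lapply(ids, function(id) {
    cm <- coordinate_map(aln, id)
    hits <- scan_motif(ungapped_sequences(aln, id), pattern_name)
    if (!nrow(hits)) return(NULL)
    data.frame(seq_id = id, hits,
               col_start = residue_to_column(cm, hits$start),
               col_end = residue_to_column(cm, hits$end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Motif conservation per aligned location within a subgroup
#'
#' Scans every subgroup member for the motif, projects hits into alignment
#' coordinates, clusters hits whose aligned spans overlap by at least one
#' column, and reports per cluster the fraction of subgroup sequences with
#' an intact motif there.
#'
#' @param aln a `sial_aln`.
#' @param subgroup subgroup label, or a character vector of sequence ids.
#' @param pattern_name motif name (default `"aspbox"`).
#' @return data.frame with one row per aligned motif location: `location`,
#'   `col_start`, `col_end`, `n_with_motif`, `fraction`.
#' @export
aspbox_conservation <- function(aln, subgroup, pattern_name = "aspbox") {
  ids <- if (length(subgroup) == 1L && subgroup %in% SUBGROUPS)
    subgroup_members(aln, subgroup) else subgroup
  if (!length(ids)) stop("subgroup is empty")
  check_ids(aln, ids)
  hits <- motif_hits_in_alignment(aln, ids, pattern_name)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(location = integer(0), col_start = integer(0),
                      col_end = integer(0), n_with_motif = integer(0),
                      fraction = numeric(0)))
  hits <- hits[order(hits$col_start, hits$col_end), ]
  # greedy interval merging: overlap of >= 1 column joins a cluster
  cluster <- integer(nrow(hits))
  cur <- 1L
  cur_end <- hits$col_end[1L]
  cluster[1L] <- 1L
  if (nrow(hits) > 1L) for (i in 2:nrow(hits)) {
    if (hits$col_start[i] <= cur_end) {
      cluster[i] <- cur
      cur_end <- max(cur_end, hits$col_end[i])
    } else {
      cur <- cur + 1L
      cluster[i] <- cur
      cur_end <- hits$col_end[i]
    }
  }
  agg <- lapply(split(hits, cluster), function(h) {
    data.frame(col_start = min(h$col_start), col_end = max(h$col_end),
               n_with_motif = length(unique(h$seq_id)),
               fraction = length(unique(h$seq_id)) / length(ids))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(location = seq_len(nrow(out)), out, row.names = NULL)
  out
}

#' Default catalytic residues (human NEU2 numbering)
#'
#' The six residues essential for catalysis in the family: the arginine
#' triad, the Tyr/Glu nucleophile pair and the Asp acid/base catalyst.
#'
#' @return data.frame with columns `position`, `residue`.
#' @export
default_catalytic_residues <- function() {
  data.frame(position = c(21L, 46L, 218L, 237L, 304L, 334L),
             residue = c("R", "D", "E", "R", "R", "Y"),
             stringsAsFactors = FALSE)
}

#' Check conservation of reference residues across the alignment
#'
#' For each sequence and each reference position, `TRUE` iff the sequence
#' carries the same amino acid in the aligned column (identity, not a
#' similarity class).
#'
#' @param aln a `sial_aln`.
#' @param ref_id reference sequence id.
#' @param ref_positions 1-based residue positions on the reference.
#' @param ref_residues optional expected residues; defaults to the
#'   reference's own residues at those positions.
#' @return logical matrix, sequences x positions; columns named
#'   `<residue><position>`.
#' @export
check_catalytic_residues <- function(aln, ref_id, ref_positions,
                                     ref_residues = NULL) {
  cm <- coordinate_map(aln, ref_id)
  cols <- residue_to_column(cm, ref_positions)
  ref_chars <- aln$mat[ref_id, cols]
  if (is.null(ref_residues)) ref_residues <- ref_chars
  if (length(ref_residues) != length(ref_positions))
    stop("ref_residues must match ref_positions in length")
  sub <- aln$mat[, cols, drop = FALSE]
  out <- sub == rep(toupper(ref_residues), each = nrow(sub))
  dimnames(out) <- list(alignment_ids(aln),
                        paste0(ref_residues, ref_positions))
  out
}

#' Default inter-blade loop definitions (human NEU2 numbering)
#'
#' The loops emerging around the catalytic crevice, numbered 0-9 from the
#' N- to the C-terminus; the overlapping Loop 0 / Loop 1 pair is retained
#' as given.
#'
#' @return data.frame with columns `name`, `ref_start`, `ref_end`.
#' @export
default_loop_definitions <- function() {
  data.frame(
    name = paste0("Loop", 0:9),
    ref_start = c(16L, 15L, 42L, 107L, 183L, 238L, 261L, 299L, 329L, 357L),
    ref_end   = c(18L, 18L, 49L, 122L, 190L, 243L, 274L, 306L, 332L, 359L),
    stringsAsFactors = FALSE)
}

#' Loop lengths of every sequence, in reference-anchored windows
#'
#' A loop is defined by residue coordinates on a reference sequence.  For
#' every other sequence its length is the number of its residues falling in
#' the alignment window strictly between the aligned flanking reference
#' residues (`ref_start - 1` and `ref_end + 1`), so insertions relative to
#' the reference are counted.  Loops touching a reference terminus fall back
#' to the window of the loop residues themselves, with a warning.
#'
#' @param aln a `sial_aln`.
#' @param ref_id reference sequence id.
#' @param loops data.frame with columns `name`, `ref_start`, `ref_end`
#'   (default [default_loop_definitions()]).
#' @return integer matrix, sequences x loops.
#' @export
loop_lengths <- function(aln, ref_id, loops = default_loop_definitions()) {
  cm <- coordinate_map(aln, ref_id)
  ref_len <- length(cm$col_of_residue)
  if (any(loops$ref_start > loops$ref_end))
    stop("loop ref_start must be <= ref_end")
  if (any(loops$ref_start < 1L | loops$ref_end > ref_len))
    stop("loop coordinates out of range for reference ", ref_id)
  out <- matrix(0L, nrow = n_sequences(aln), ncol = nrow(loops),
                dimnames = list(alignment_ids(aln), loops$name))
  for (j in seq_len(nrow(loops))) {
    s <- loops$ref_start[j]; e <- loops$ref_end[j]
    if (s > 1L && e < ref_len) {
      win <- (residue_to_column(cm, s - 1L) + 1L):(residue_to_column(cm, e + 1L) - 1L)
    } else {
      warning("loop ", loops$name[j],
              " touches the reference terminus; using the unflanked window")
      win <- residue_to_column(cm, s):residue_to_column(cm, e)
    }
    sub <- aln$mat[, win, drop = FALSE]
    out[, j] <- as.integer(rowSums(sub != GAP_CHAR))
  }
  out
}

#' Mean loop length per subgroup
#'
#' @param aln a `sial_aln`.
#' @param ref_id reference sequence id.
#' @param loops loop definition table.
#' @return data.frame, subgroups x loops, of mean lengths.
#' @export
mean_loop_lengths <- function(aln, ref_id, loops = default_loop_definitions()) {
  len <- loop_lengths(aln, ref_id, loops)
  groups <- split(aln$metadata$id, aln$metadata$subgroup)
  groups <- groups[vapply(groups, length, 1L) > 0]
  out <- t(vapply(groups, function(ids) colMeans(len[ids, , drop = FALSE]),
                  numeric(ncol(len))))
  as.data.frame(out)
}

#' Map exon junctions onto alignment columns
#'
#' @param junctions ascending 1-based residue indices of the exon-exon
#'   boundaries (the residue containing each junction).
#' @param cmap the sequence's [coordinate_map()].
#' @return ascending integer vector of alignment columns, one per junction.
#' @export
map_exon_junctions <- function(junctions, cmap) {
  if (!length(junctions)) return(integer(0))
  if (is.unsorted(junctions, strictly = TRUE))
    stop("junctions must be strictly ascending")
  if (any(junctions > length(cmap$col_of_residue)))
    stop("junction beyond sequence length for ", cmap$seq_id)
  residue_to_column(cmap, junctions)
}
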