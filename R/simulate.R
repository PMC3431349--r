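#' Simulate a protein alignment along a tree
#'
#' Forward simulation under the reversible model with discrete-gamma rate
#' variation: each site draws a rate category once, root states are drawn
#' from the stationary frequencies, and child states are drawn through the
#' branch transition matrices.  No indels are generated (gaps enter only
#' through planted features downstream).
#'
#' @param tree `ape::phylo` with branch lengths; tip labels become sequence
#'   ids.
#' @param model a [substitution_model()].
#' @param gamma optional [discrete_gamma()] rates.
#' @param n_sites number of columns.
#' @param seed optional seed.
#' @return a `sial_aln` with attribute `site_rates` (the per-site category
#'   rate multipliers).
#' @export
simulate_alignment <- function(tree, model = wag_model(), gamma = NULL,
                               n_sites, seed = NULL) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rates <- if (is.null(gamma)) rep(1, n_sites) else
    sample(gamma$rates, n_sites, replace = TRUE)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_sites)
  attr(tree, "order") <- NULL
  tr <- ape::reorder.phylo(tree, "postorder")
  root <- tr$edge[nrow(tr$edge), 1L]
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  urates <- unique(rates)
  # preorder = reversed postorder edges
  for (k in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    t_len <- tr$edge.length[k]
    if (t_len == 0) { states[child, ] <- states[parent, ]; next }
    for (r in urates) {
      P <- transition_matrix(model, t_len, r)
      for (s in unique(states[parent, rates == r])) {
        idx <- which(rates == r & states[parent, ] == s)
        states[child, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  seqs <- vapply(seq_len(n_tip), function(i)
    paste(AA_LETTERS[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  aln <- sial_alignment(seqs)
  attr(aln, "site_rates") <- rates
  aln
}

#' Plant group-specific phosphorylatable columns
#'
#' Overwrites chosen columns so that in-group sequences carry a residue of
#' the class (S/T/Y by default) with probability `freq_in` and out-group
#' sequences with probability `freq_out`; the remaining cells get a residue
#' drawn from the stationary frequencies outside the class.  Creates the
#' planted signal the conservation classifier must detect.
#'
#' @param aln a `sial_aln`.
#' @param group in-group sequence ids (or a subgroup label).
#' @param residue_class residues of the planted class.
#' @param freq_in,freq_out in/out-group class frequencies,
#'   `0 <= freq_out < freq_in <= 1`.
#' @param n_columns number of columns to plant (ignored when `columns` is
#'   given).
#' @param columns explicit columns to plant.
#' @param seed optional seed.
#' @return list with the modified alignment (`aln`) and the `truth`
#'   data.frame of planted columns.
#' @export
plant_specific_columns <- function(aln, group,
                                   residue_class = PHOSPHO_RESIDUES,
                                   freq_in = 0.95, freq_out = 0.02,
                                   n_columns = 1L, columns = NULL,
                                   seed = NULL) {
  if (!(freq_out < freq_in) || freq_in > 1 || freq_out < 0)
    stop("need 0 <= freq_out < freq_in <= 1")
  if (length(group) == 1L && group %in% SUBGROUPS)
    group <- subgroup_members(aln, group)
  check_ids(aln, group)
  if (!is.null(seed)) set.seed(seed)
  L <- alignment_length(aln)
  if (is.null(columns)) {
    if (n_columns > L) stop("n_columns exceeds alignment length")
    columns <- sort(sample.int(L, n_columns))
  }
  ids <- alignment_ids(aln)
  in_grp <- ids %in% group
  other <- setdiff(AA_LETTERS, residue_class)
  p_other <- WAG_FREQS[match(other, AA_LETTERS)]
  p_class <- WAG_FREQS[match(residue_class, AA_LETTERS)]
  for (j in columns) {
    hit <- stats::runif(length(ids)) < ifelse(in_grp, freq_in, freq_out)
    aln$mat[hit, j] <- sample(residue_class, sum(hit), replace = TRUE,
                              prob = p_class)
    aln$mat[!hit, j] <- sample(other, sum(!hit), replace = TRUE,
                               prob = p_other)
  }
  list(aln = aln,
       truth = data.frame(column = columns, freq_in = freq_in,
                          freq_out = freq_out,
                          group = paste(group, collapse = ",")))
}

# Overwrite an aligned block with a motif realisation ("x" = random residue)
# in the given sequences.
plant_motif_block <- function(mat, rows, start_col, template) {
  cols <- start_col + seq_along(template) - 1L
  for (i in rows) {
    filled <- vapply(template, function(ch) {
      if (ch == "x") sample(AA_LETTERS, 1L) else ch
    }, character(1))
    mat[i, cols] <- filled
  }
  mat
}

ASPBOX_TEMPLATE <- c("S", "x", "D", "x", "G", "x", "x", "W")
NTERM_TEMPLATE <- c("F", "Y", "R", "I", "P")

#' Scenario configuration for the synthetic sialidase family
#'
#' Defaults mirror the real study dataset: 83 sequences partitioned
#' 37/8/19/11/8 into NEU1..NEU5 clades (the analyzed set, after the four
#' poorly aligning sequences are dropped from the 40/8/20/11/8 initial
#' assignment), about 1000 alignment columns, WAG
#' substitution with gamma rate variation, five Asp-box locations (1 and 5
#' conserved mainly in the NEU1-like clade), frozen catalytic columns, a
#' long loop insertion private to the NEU5-like clade plus a hypervariable
#' insertion in NEU3/NEU4, and per-clade exon structures with 6/2/2/3/4
#' exons.
#'
#' @param n_per_subgroup named sizes of the five clades.
#' @param n_core_sites ungapped core columns simulated on the tree.
#' @param gamma_shape gamma shape for the simulation.
#' @param clade_depth height of each within-clade coalescent subtree
#'   (substitutions/site).
#' @param seed master seed; every draw in the generator descends from it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_per_subgroup = c(NEU1 = 37L, NEU2 = 8L,
                                               NEU3 = 19L, NEU4 = 11L,
                                               NEU5 = 8L),
                            n_core_sites = 900L, gamma_shape = 2.6845,
                            clade_depth = 0.15, seed = 1L) {
  stopifnot(all(n_per_subgroup >= 2L), n_core_sites >= 860L)
  structure(list(n_per_subgroup = n_per_subgroup,
                 n_core_sites = as.integer(n_core_sites),
                 gamma_shape = gamma_shape, clade_depth = clade_depth,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Backbone joining the five clades; stem lengths chosen so mean
# between-clade path lengths land in the 1-3 substitutions/site range the
# family shows (NEU1 far from all, NEU3/NEU4 closest, NEU5 intermediate).
scenario_backbone <- function() {
  ape::read.tree(text = paste0(
    "(((NEU2:0.45,(NEU3:0.40,NEU4:0.40):0.10):0.30,NEU5:0.75):0.40,",
    "NEU1:1.15);"))
}

# Full tree: backbone tips replaced by scaled coalescent clades.
scenario_tree <- function(cfg) {
  backbone <- scenario_backbone()
  tr <- backbone
  for (sg in names(cfg$n_per_subgroup)) {
    n <- cfg$n_per_subgroup[[sg]]
    clade <- ape::rcoal(n, tip.label = sprintf("%s_%02d", sg, seq_len(n)))
    clade$edge.length <- clade$edge.length * cfg$clade_depth /
      max(ape::node.depth.edgelength(clade))
    tr <- ape::bind.tree(tr, clade, where = which(tr$tip.label == sg))
  }
  tr
}

#' Generate the full synthetic family scenario
#'
#' Builds the whole dataset bundle every pipeline stage consumes: a rooted
#' five-clade tree, sequences evolved under the model, planted motifs,
#' frozen catalytic columns, subgroup- and taxon-conserved phosphorylatable
#' columns, clade-private loop insertions (the only source of gaps), exon
#' structures per clade, metadata with nested taxon labels, and truth
#' tables for every planted feature.  Byte-identical under the same
#' configuration and seed.
#'
#' @param cfg a [scenario_config()].
#' @param model substitution model (default [wag_model()]).
#' @return list of class `sial_scenario` with elements `aln`, `tree`,
#'   `sites`, `exons`, `loops`, `catalytic`, `reference_id`, `truth`.
#' @export
generate_family_scenario <- function(cfg = scenario_config(),
                                     model = wag_model()) {
  set.seed(cfg$seed)
  gamma <- discrete_gamma(cfg$gamma_shape, 5L)
  tree <- scenario_tree(cfg)
  aln <- simulate_alignment(tree, model, gamma, cfg$n_core_sites)
  mat <- aln$mat
  ids <- rownames(mat)
  sg_of <- sub("_[0-9]+$", "", ids)
  clades <- split(ids, sg_of)

  # --- metadata: nested taxon groups inside each clade -------------------
  # splits chosen so the nested group totals echo the real dataset
  # (21 mammals, 52 vertebrates, 74 deuterostomes, 9 early metazoans)
  taxon_split <- list(
    NEU1 = c(mammals = 5, vertebrates = 10, deuterostomes = 14, early_metazoa = 8),
    NEU2 = c(mammals = 5, vertebrates = 3, deuterostomes = 0, early_metazoa = 0),
    NEU3 = c(mammals = 6, vertebrates = 11, deuterostomes = 2, early_metazoa = 0),
    NEU4 = c(mammals = 5, vertebrates = 5, deuterostomes = 1, early_metazoa = 0),
    NEU5 = c(mammals = 0, vertebrates = 2, deuterostomes = 5, early_metazoa = 1))
  meta <- do.call(rbind, lapply(names(clades), function(sg) {
    n <- length(clades[[sg]])
    lab <- rep(names(taxon_split[[sg]]), times = taxon_split[[sg]])[seq_len(n)]
    data.frame(id = clades[[sg]], subgroup = sg, taxon_group = lab,
               stringsAsFactors = FALSE)
  }))

  # --- catalytic columns frozen in every sequence ------------------------
  catalytic <- default_catalytic_residues()
  mat[, catalytic$position] <-
    rep(catalytic$residue, each = nrow(mat))

  # --- N-terminal motif, near-universal ----------------------------------
  nterm_rows <- which(stats::runif(length(ids)) < 0.95)
  mat <- plant_motif_block(mat, nterm_rows, 8L, NTERM_TEMPLATE)

  # --- Asp-boxes at five locations; 2 and 3 family-wide, 1 and 5 mainly
  #     NEU1 (NEU5 partially), 4 intermediate ------------------------------
  aspbox_starts <- c(120L, 160L, 400L, 600L, 750L)
  aspbox_prob <- list(
    c(NEU1 = 0.95, NEU2 = 0.10, NEU3 = 0.10, NEU4 = 0.10, NEU5 = 0.70),
    c(NEU1 = 0.95, NEU2 = 0.95, NEU3 = 0.95, NEU4 = 0.95, NEU5 = 0.95),
    c(NEU1 = 0.95, NEU2 = 0.95, NEU3 = 0.95, NEU4 = 0.95, NEU5 = 0.95),
    c(NEU1 = 0.90, NEU2 = 0.60, NEU3 = 0.60, NEU4 = 0.60, NEU5 = 0.60),
    c(NEU1 = 0.95, NEU2 = 0.10, NEU3 = 0.10, NEU4 = 0.10, NEU5 = 0.70))
  aspbox_truth <- NULL
  for (b in seq_along(aspbox_starts)) {
    for (sg in names(clades)) {
      rows <- clades[[sg]][stats::runif(length(clades[[sg]])) <
                             aspbox_prob[[b]][[sg]]]
      mat <- plant_motif_block(mat, rows, aspbox_starts[b], ASPBOX_TEMPLATE)
      aspbox_truth <- rbind(aspbox_truth,
                            data.frame(box = b, col_start = aspbox_starts[b],
                                       subgroup = sg, n_planted = length(rows)))
    }
  }

  # --- planted phosphorylatable columns ----------------------------------
  # avoid feature blocks when drawing columns
  reserved <- c(catalytic$position, 8:12,
                unlist(lapply(aspbox_starts, function(s) s:(s + 7L))))
  free_cols <- setdiff(seq_len(ncol(mat)), reserved)
  draw_cols <- function(n) {
    picked <- sample(free_cols, n)
    free_cols <<- setdiff(free_cols, picked)
    sort(picked)
  }
  plant <- function(aln_mat, cols, rows_in, freq_in, freq_out) {
    tmp <- sial_alignment(stats::setNames(
      apply(aln_mat, 1L, paste, collapse = ""), rownames(aln_mat)))
    res <- plant_specific_columns(tmp, rows_in, freq_in = freq_in,
                                  freq_out = freq_out, columns = cols)
    res$aln$mat
  }
  truth_phospho <- NULL
  note <- function(cols, kind, group)
    data.frame(column = cols, kind = kind, group = group,
               stringsAsFactors = FALSE)

  glob90 <- draw_cols(4L)
  mat <- plant(mat, glob90, ids, 0.95, 0)  # freq_out irrelevant: all in-group
  truth_phospho <- rbind(truth_phospho, note(glob90, "global90", "all"))
  glob60 <- draw_cols(2L)
  mat <- plant(mat, glob60, ids, 0.75, 0)
  truth_phospho <- rbind(truth_phospho, note(glob60, "global60", "all"))

  sg_counts <- c(NEU1 = 4L, NEU2 = 3L, NEU3 = 2L, NEU4 = 1L, NEU5 = 3L)
  for (sg in names(sg_counts)) {
    cols <- draw_cols(sg_counts[[sg]])
    mat <- plant(mat, cols, clades[[sg]], 0.95, 0.02)
    truth_phospho <- rbind(truth_phospho, note(cols, "subgroup", sg))
  }
  taxon_targets <- c("mammals", "vertebrates", "deuterostomes")
  meta_aln <- sial_alignment(stats::setNames(
    apply(mat, 1L, paste, collapse = ""), ids), meta)
  for (tx in taxon_targets) {
    cols <- draw_cols(1L)
    mat <- plant(mat, cols, taxon_members(meta_aln, tx), 0.95, 0.02)
    truth_phospho <- rbind(truth_phospho, note(cols, "taxon", tx))
  }
  # unplanted columns also enter the tested set; note they are background
  # only in the sense of "not planted" -- tree-correlated evolution leaves
  # some of them strongly conserved, exactly as in real alignments
  unplanted_cols <- draw_cols(10L)
  truth_phospho <- rbind(truth_phospho,
                         note(unplanted_cols, "unplanted", "background"))

  # --- loop insertions (the only gaps): private blocks per clade ---------
  # NEU5 gets a long loop-6-like insertion; NEU3+NEU4 a hypervariable one;
  # all clades but NEU1 a short loop-3-like insertion (so NEU1 loops run
  # shorter, as in the family).
  insertions <- list(
    list(after = 450L, width = 8L, clades = c("NEU2", "NEU3", "NEU4", "NEU5")),
    list(after = 560L, width = 30L, clades = "NEU5"),
    list(after = 640L, width = 40L, clades = c("NEU3", "NEU4")))
  insertions <- insertions[order(vapply(insertions, `[[`, 1L, "after"),
                                 decreasing = TRUE)]
  for (ins in insertions) {
    rows_in <- unlist(clades[ins$clades], use.names = FALSE)
    block <- matrix(GAP_CHAR, nrow(mat), ins$width)
    rownames(block) <- rownames(mat)
    fill <- matrix(sample(AA_LETTERS, length(rows_in) * ins$width,
                          replace = TRUE, prob = WAG_FREQS),
                   length(rows_in), ins$width)
    block[rows_in, ] <- fill
    mat <- cbind(mat[, seq_len(ins$after), drop = FALSE], block,
                 mat[, (ins$after + 1L):ncol(mat), drop = FALSE])
  }
  colnames(mat) <- NULL

  aln <- sial_alignment(stats::setNames(
    apply(mat, 1L, paste, collapse = ""), ids), meta)

  # shift truth columns past the inserted blocks (insertions were applied
  # right-to-left on core coordinates)
  shift_col <- function(cols) {
    out <- cols
    for (ins in insertions)
      out <- out + ifelse(cols > ins$after, ins$width, 0L)
    out
  }
  truth_phospho$column <- shift_col(truth_phospho$column)
  aspbox_truth$col_start <- shift_col(aspbox_truth$col_start)
  catalytic_cols <- shift_col(catalytic$position)

  # --- reference sequence and loop definitions ---------------------------
  reference_id <- clades$NEU2[1L]
  cm <- coordinate_map(aln, reference_id)
  ref_res <- function(col) column_to_residue(cm, col)
  loops <- data.frame(
    name = c("Loop3", "Loop6", "LoopHV"),
    ref_start = c(ref_res(shift_col(449L)), ref_res(shift_col(559L)),
                  ref_res(shift_col(639L))),
    ref_end = c(ref_res(shift_col(452L)), ref_res(shift_col(562L)),
                ref_res(shift_col(642L))),
    stringsAsFactors = FALSE)

  # --- phospho site list: one predicted site per truth column, emitted
  #     from a clade representative when possible (else any carrier) -------
  reps <- vapply(clades, `[`, character(1), 1L)
  sites <- NULL
  for (col in sort(unique(truth_phospho$column))) {
    carriers <- ids[aln$mat[, col] %in% PHOSPHO_RESIDUES]
    if (!length(carriers)) next
    sid <- if (any(reps %in% carriers)) reps[reps %in% carriers][1L] else
      carriers[1L]
    pos <- column_to_residue(coordinate_map(aln, sid), col)
    sites <- rbind(sites, data.frame(seq_id = sid, residue_pos = pos,
                                     residue = aln$mat[sid, col],
                                     stringsAsFactors = FALSE))
  }

  # --- exon structures: 6/2/2/3/4 exons per clade ------------------------
  exon_counts <- c(NEU1 = 6L, NEU2 = 2L, NEU3 = 2L, NEU4 = 3L, NEU5 = 4L)
  exons <- do.call(rbind, lapply(names(clades), function(sg) {
    do.call(rbind, lapply(clades[[sg]], function(id) {
      len <- sum(aln$mat[id, ] != GAP_CHAR)
      nj <- exon_counts[[sg]] - 1L
      if (nj == 0L) return(NULL)
      junc <- round(len * seq_len(nj) / (nj + 1L))
      data.frame(seq_id = id, junction = as.integer(junc),
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    aln = aln, tree = tree, sites = sites, exons = exons, loops = loops,
    catalytic = data.frame(position = catalytic_cols,
                           residue = catalytic$residue),
    reference_id = reference_id,
    truth = list(subgroup = stats::setNames(sg_of, ids),
                 phospho = truth_phospho, aspbox = aspbox_truth,
                 tree = tree, exon_counts = exon_counts)),
    class = "sial_scenario")
}

#' Write a scenario bundle to a directory
#'
#' Emits `alignment.fasta`, `metadata.tsv`, `phosphosites.tsv`, `exons.tsv`,
#' `loops.tsv`, `catalytic.tsv`, `tree.nwk` and `truth/*.tsv`.
#'
#' @param scenario a [generate_family_scenario()] result.
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_alignment(scenario$aln, file.path(dir, "alignment.fasta"))
  write_result_table(scenario$aln$metadata, file.path(dir, "metadata.tsv"))
  write_result_table(scenario$sites, file.path(dir, "phosphosites.tsv"))
  write_result_table(scenario$exons, file.path(dir, "exons.tsv"))
  write_result_table(scenario$loops, file.path(dir, "loops.tsv"))
  write_result_table(scenario$catalytic, file.path(dir, "catalytic.tsv"))
  write_tree(scenario$tree, file.path(dir, "tree.nwk"))
  write_result_table(scenario$truth$phospho,
                     file.path(dir, "truth", "phospho.tsv"))
  write_result_table(scenario$truth$aspbox,
                     file.path(dir, "truth", "aspbox.tsv"))
  writeLines(scenario$reference_id, file.path(dir, "reference_id.txt"))
  invisible(dir)
}
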