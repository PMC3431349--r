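#' Pipeline configuration
#'
#' Flat key/value configuration shared by all stages.  Paths point at a
#' scenario-style bundle (see [write_scenario()]); stage parameters default
#' to the protocol constants: coverage thresholds 0.70 (divergence, strict)
#' and 0.50 (phylogeny, inclusive), significance level 0.01 after
#' Bonferroni, conservation cutoffs 60/90 percent, gamma shape 5 for
#' divergences and an estimated shape for the tree.
#'
#' @param input_dir directory holding the input bundle.
#' @param out_dir output directory.
#' @param ... overrides of any default listed below.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "sialevo_out", ...) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir,
    alignment = NULL, metadata = NULL, sites = NULL, exons = NULL,
    loops = NULL, catalytic = NULL, reference_id = NULL,
    coverage_divergence = 0.70, coverage_tree = 0.50,
    alpha = 0.01, cons60 = 60, cons90 = 90,
    gamma_shape_divergence = 5, gamma_shape_tree = 2.6845,
    n_rate_categories = 5L,
    in_threshold = 0.7, out_threshold = 0.2,
    bootstrap_B = 0L, divergence_boot = 100L,
    tree_search = "both",
    seed = 1L, verbose = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  for (f in c("alignment", "metadata", "sites", "exons", "loops",
              "catalytic")) {
    if (is.null(cfg[[f]]) && !is.null(cfg$input_dir))
      cfg[[f]] <- file.path(cfg$input_dir, paste0(
        switch(f, alignment = "alignment.fasta", metadata = "metadata.tsv",
               sites = "phosphosites.tsv", exons = "exons.tsv",
               loops = "loops.tsv", catalytic = "catalytic.tsv")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments ignored.
#' Values are coerced to numeric where possible.
#'
#' @param path configuration file.
#' @param ... overrides applied on top of the file (e.g. from CLI flags).
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  do.call(pipeline_config, utils::modifyList(parsed, list(...)))
}

config_hash <- function(cfg) {
  # fingerprint the analysis inputs/parameters, not where results land
  keep <- cfg[setdiff(names(cfg), c("verbose", "out_dir"))]
  txt <- paste(names(keep), vapply(keep, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small stable polynomial hash; enough to fingerprint a run
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipe_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[sialevo] ", ...)
  invisible(NULL)
}

load_bundle <- function(cfg) {
  if (is.null(cfg$alignment)) stop("no alignment configured")
  meta <- if (!is.null(cfg$metadata) && file.exists(cfg$metadata))
    read_metadata(cfg$metadata) else NULL
  aln <- read_alignment(cfg$alignment, meta)
  ref <- cfg$reference_id
  if (is.null(ref) && !is.null(cfg$input_dir)) {
    rf <- file.path(cfg$input_dir, "reference_id.txt")
    if (file.exists(rf)) ref <- readLines(rf)[1L]
  }
  list(aln = aln, reference_id = ref)
}

stage_writer <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  function(df, name) {
    write_result_table(df, file.path(cfg$out_dir, name),
                       comments = c(config_hash = hash,
                                    seed = as.character(cfg$seed)))
  }
}

run_stage_assign <- function(cfg, bundle, emit) {
  aln <- bundle$aln
  labelled <- aln$metadata[aln$metadata$subgroup != "unknown", ]
  if (!nrow(labelled)) stop("assign stage needs labelled reference sequences")
  # one reference per subgroup (its first member) keeps the score matrix small
  refs_ids <- vapply(split(labelled$id, labelled$subgroup), `[`, character(1), 1L)
  seqs <- ungapped_sequences(aln)
  res <- rbh_assign(seqs, seqs[refs_ids],
                    stats::setNames(aln$metadata$subgroup[
                      match(refs_ids, aln$metadata$id)], refs_ids))
  emit(res, "assignment.tsv")
  res
}

run_stage_divergence <- function(cfg, bundle, emit) {
  aln <- bundle$aln
  gamma <- discrete_gamma(cfg$gamma_shape_divergence, cfg$n_rate_categories)
  sgs <- setdiff(intersect(SUBGROUPS, unique(aln$metadata$subgroup)), "unknown")
  rows <- NULL
  for (i in seq_along(sgs)) for (j in seq_along(sgs)) {
    if (j <= i) next
    dv <- between_group_divergence(aln, sgs[i], sgs[j],
                                   gamma = gamma,
                                   min_coverage = cfg$coverage_divergence,
                                   strict = TRUE,
                                   n_boot = cfg$divergence_boot,
                                   seed = cfg$seed)
    rows <- rbind(rows, data.frame(group_a = sgs[i], group_b = sgs[j],
                                   mean = dv$mean, se = dv$se,
                                   n_pairs = dv$n_pairs,
                                   n_columns = dv$n_columns))
    pipe_log(cfg, "divergence ", sgs[i], " vs ", sgs[j], ": ",
             format(dv$mean, digits = 4))
  }
  emit(rows, "divergence.tsv")
  rows
}

run_stage_tree <- function(cfg, bundle, emit) {
  aln <- bundle$aln
  gamma <- discrete_gamma(cfg$gamma_shape_tree, cfg$n_rate_categories)
  cols <- filter_columns(aln, cfg$coverage_tree, strict = FALSE)
  if (cfg$bootstrap_B > 0) {
    tr <- bootstrap_support(aln, gamma = gamma, B = cfg$bootstrap_B,
                            seed = cfg$seed, columns = cols,
                            start = cfg$tree_search)
  } else {
    tr <- optimize_tree(aln, gamma = gamma, columns = cols,
                        start = cfg$tree_search)
  }
  write_tree(tr, file.path(cfg$out_dir, "tree.nwk"))
  emit(data.frame(loglik = attr(tr, "loglik"), n_columns = length(cols)),
       "tree_stats.tsv")
  tr
}

run_stage_phospho <- function(cfg, bundle, emit) {
  aln <- bundle$aln
  sites <- read_result_table(cfg$sites)
  cols <- map_sites_to_columns(sites, aln)
  stats <- classify_sites(phospho_column_stats(aln, cols),
                          alpha = cfg$alpha, cons60 = cfg$cons60,
                          cons90 = cfg$cons90)
  emit(as.data.frame(stats), "phospho_stats.tsv")
  hm <- conservation_matrix(stats)
  emit(data.frame(column = rownames(hm), hm, check.names = FALSE),
       "phospho_heatmap.tsv")
  stats
}

run_stage_features <- function(cfg, bundle, emit) {
  aln <- bundle$aln
  ref <- bundle$reference_id
  out <- list()
  sgs <- setdiff(intersect(SUBGROUPS, unique(aln$metadata$subgroup)), "unknown")
  asp <- do.call(rbind, lapply(sgs, function(sg) {
    hits <- aspbox_conservation(aln, sg)
    if (!nrow(hits)) return(NULL)
    data.frame(subgroup = sg, hits)
  }))
  if (is.null(asp))
    asp <- data.frame(subgroup = character(0), location = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      n_with_motif = integer(0), fraction = numeric(0))
  emit(asp, "aspbox_conservation.tsv")
  out$aspbox <- asp
  if (!is.null(ref)) {
    cat_tab <- if (!is.null(cfg$catalytic) && file.exists(cfg$catalytic))
      read_result_table(cfg$catalytic) else default_catalytic_residues()
    cc <- check_catalytic_residues(aln, ref, cat_tab$position, cat_tab$residue)
    emit(data.frame(id = rownames(cc), cc, check.names = FALSE),
         "catalytic_conservation.tsv")
    out$catalytic <- cc
    loops <- if (!is.null(cfg$loops) && file.exists(cfg$loops))
      read_result_table(cfg$loops) else default_loop_definitions()
    ll <- loop_lengths(aln, ref, loops)
    emit(data.frame(id = rownames(ll), ll, check.names = FALSE),
         "loop_lengths.tsv")
    out$loops <- ll
  }
  if (!is.null(cfg$exons) && file.exists(cfg$exons)) {
    ex <- read_result_table(cfg$exons)
    rows <- do.call(rbind, lapply(split(ex, ex$seq_id), function(e) {
      cm <- coordinate_map(aln, e$seq_id[1L])
      data.frame(seq_id = e$seq_id[1L],
                 junction = sort(e$junction),
                 column = map_exon_junctions(sort(e$junction), cm))
    }))
    emit(rows, "exon_columns.tsv")
    out$exons <- rows
  }
  out
}

#' Run one pipeline stage (or the whole analysis)
#'
#' Stages: `simulate` (write a synthetic bundle into `input_dir`), `assign`
#' (reciprocal-best-hit subfamily assignment), `divergence` (between-group
#' WAG+Gamma divergences), `tree` (ML tree, optionally bootstrapped),
#' `phospho` (phospho-site conservation statistics), `features` (motifs,
#' catalytic residues, loops, exon junctions), or `all` (assign, divergence,
#' tree, phospho, features in order).  Every output table embeds the
#' configuration hash; on failure the stage's partial outputs are removed.
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @return the stage's main result, invisibly.
#' @export
run_stage <- function(stage = c("all", "simulate", "assign", "divergence",
                                "tree", "phospho", "features"),
                      cfg = pipeline_config()) {
  stage <- match.arg(stage)
  if (stage == "simulate") {
    if (is.null(cfg$input_dir)) stop("simulate stage needs input_dir")
    pipe_log(cfg, "simulating scenario (seed ", cfg$seed, ")")
    sc <- generate_family_scenario(scenario_config(seed = cfg$seed))
    write_scenario(sc, cfg$input_dir)
    return(invisible(sc))
  }
  bundle <- load_bundle(cfg)
  emit <- stage_writer(cfg)
  written <- character(0)
  emit_tracked <- function(df, name) {
    written <<- c(written, file.path(cfg$out_dir, name))
    emit(df, name)
  }
  runner <- function() {
    switch(stage,
      assign = run_stage_assign(cfg, bundle, emit_tracked),
      divergence = run_stage_divergence(cfg, bundle, emit_tracked),
      tree = run_stage_tree(cfg, bundle, emit_tracked),
      phospho = run_stage_phospho(cfg, bundle, emit_tracked),
      features = run_stage_features(cfg, bundle, emit_tracked),
      all = {
        res <- list()
        res$assign <- run_stage_assign(cfg, bundle, emit_tracked)
        res$divergence <- run_stage_divergence(cfg, bundle, emit_tracked)
        res$tree <- run_stage_tree(cfg, bundle, emit_tracked)
        res$phospho <- run_stage_phospho(cfg, bundle, emit_tracked)
        res$features <- run_stage_features(cfg, bundle, emit_tracked)
        res
      })
  }
  res <- tryCatch(runner(), error = function(e) {
    unlink(written)
    stop("stage '", stage, "' failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  pipe_log(cfg, "stage '", stage, "' complete; outputs in ", cfg$out_dir)
  invisible(res)
}
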