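check_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining and BioNJ trees from a distance matrix
#'
#' Standard agglomerative distance methods used as starting topologies for
#' the likelihood search.  Negative branch-length estimates are clamped to
#' zero.
#'
#' @param D symmetric distance matrix with zero diagonal and taxon
#'   dimnames.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(D) {
  check_dist_matrix(D)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' @rdname nj_tree
#' @export
bionj_tree <- function(D) {
  check_dist_matrix(D)
  tr <- ape::bionj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Coordinate-wise branch-length optimization against a likelihood engine:
# golden-section search on each edge in turn until a full pass improves the
# log-likelihood by less than tol.
optimize_bl_engine <- function(tree, lik, tol = 1e-4, max_passes = 10L,
                               edge_tol = 1e-4, upper = 10) {
  ll <- lik(tree)
  for (pass in seq_len(max_passes)) {
    ll_before <- ll
    for (k in seq_along(tree$edge.length)) {
      f <- function(t) {
        tree$edge.length[k] <- t
        lik(tree)
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = edge_tol)
      if (opt$objective > ll) {
        tree$edge.length[k] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - ll_before < tol) break
  }
  attr(tree, "loglik") <- ll
  tree
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise scalar maximization of the pruning log-likelihood, edge
#' by edge, iterated until a pass gains less than `tol` log units.
#'
#' @param tree `ape::phylo`.
#' @param aln a `sial_aln`.
#' @param model,gamma substitution model and optional gamma rates.
#' @param columns columns to use.
#' @param tol pass-level log-likelihood tolerance.
#' @param max_passes cap on passes over the edges.
#' @return the tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = wag_model(),
                                    gamma = NULL,
                                    columns = seq_len(alignment_length(aln)),
                                    tol = 1e-4, max_passes = 10L) {
  lik <- lik_engine(aln, model, gamma, columns)
  optimize_bl_engine(tree, lik, tol = tol, max_passes = max_passes)
}

#' Maximum-likelihood tree search (NJ/BioNJ start, NNI hill-climb)
#'
#' Reproduces the classic heuristic: starting topologies from
#' neighbor-joining and/or BioNJ on the pairwise ML distance matrix, branch
#' lengths optimized coordinate-wise, then nearest-neighbour-interchange
#' hill-climbing.  Each round scores all NNI neighbours at the current
#' branch lengths, re-optimizes the most promising one, and accepts it when
#' it improves the log-likelihood by more than `tol`; the search stops at a
#' local optimum.  Deterministic given its inputs.
#'
#' @param aln a `sial_aln`.
#' @param model,gamma substitution model and gamma rates.
#' @param start `"both"` (default), `"nj"` or `"bionj"`; with `"both"` the
#'   higher-likelihood start tree is kept.
#' @param columns columns to use (e.g. the 50 percent coverage set).
#' @param tol minimal log-likelihood gain to accept a rearrangement.
#' @param max_rounds cap on NNI rounds.
#' @param bl_passes branch-length passes per optimization.
#' @return an `ape::phylo` with attribute `loglik`.
#' @export
optimize_tree <- function(aln, model = wag_model(), gamma = NULL,
                          start = c("both", "nj", "bionj"),
                          columns = seq_len(alignment_length(aln)),
                          tol = 1e-4, max_rounds = 20L, bl_passes = 3L) {
  start <- match.arg(start)
  if (n_sequences(aln) < 4L) stop("need at least 4 taxa")
  D <- ml_distance_matrix(aln, model, gamma, columns)
  lik <- lik_engine(aln, model, gamma, columns)
  starts <- switch(start,
                   nj = list(nj_tree(D)),
                   bionj = list(bionj_tree(D)),
                   both = list(nj_tree(D), bionj_tree(D)))
  starts <- lapply(starts, optimize_bl_engine, lik = lik,
                   max_passes = bl_passes)
  lls <- vapply(starts, attr, numeric(1), which = "loglik")
  best <- starts[[which.max(lls)]]
  best_ll <- max(lls)

  for (round in seq_len(max_rounds)) {
    cands <- phangorn::nni(best)
    # quick screen at current branch lengths, then polish the front-runner
    screen <- vapply(seq_along(cands), function(ci) lik(cands[[ci]]),
                     numeric(1))
    improved <- FALSE
    for (ci in order(screen, decreasing = TRUE)[seq_len(min(2L, length(cands)))]) {
      cand <- optimize_bl_engine(cands[[ci]], lik, max_passes = bl_passes)
      if (attr(cand, "loglik") > best_ll + tol) {
        best <- cand
        best_ll <- attr(cand, "loglik")
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  attr(best, "loglik") <- best_ll
  best
}

#' Bootstrap supports for the ML tree
#'
#' Columns are resampled with replacement `B` times; the full search is
#' re-run on every replicate and each internal bipartition of the
#' point-estimate tree is annotated with the percentage of replicate trees
#' containing it (stored in `node.label`).
#'
#' @param aln a `sial_aln`.
#' @param model,gamma substitution model and gamma rates.
#' @param B number of bootstrap replicates.
#' @param seed seed for the resampling.
#' @param columns columns to use.
#' @param ... passed to [optimize_tree()].
#' @return the point-estimate `phylo` with `node.label` supports in
#'   \[0, 100\] and attribute `boot_trees`.
#' @export
bootstrap_support <- function(aln, model = wag_model(), gamma = NULL,
                              B = 1000L, seed = 1L,
                              columns = seq_len(alignment_length(aln)), ...) {
  if (B < 1L) stop("B must be >= 1")
  main <- optimize_tree(aln, model, gamma, columns = columns, ...)
  set.seed(seed)
  boots <- lapply(seq_len(B), function(b) {
    idx <- sample(columns, replace = TRUE)
    optimize_tree(aln, model, gamma, columns = idx, ...)
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- pmin(100, pmax(0, 100 * counts / B))
  main$node.label <- round(support, 1)
  attr(main, "boot_trees") <- boots
  main
}

#' Estimate the discrete-gamma shape on a fixed tree
#'
#' Scalar maximization of the tree log-likelihood over the gamma shape,
#' keeping topology and branch lengths fixed.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param aln a `sial_aln`.
#' @param model substitution model.
#' @param n_categories rate categories (default 5).
#' @param columns columns to use.
#' @param interval search interval for the shape.
#' @return the shape estimate, with the achieved log-likelihood as
#'   attribute `loglik`.
#' @export
estimate_gamma_shape <- function(tree, aln, model = wag_model(),
                                 n_categories = 5L,
                                 columns = seq_len(alignment_length(aln)),
                                 interval = c(0.05, 50)) {
  f <- function(a) tree_log_likelihood(tree, aln, model,
                                       discrete_gamma(a, n_categories),
                                       columns)
  opt <- stats::optimize(f, interval, maximum = TRUE, tol = 1e-4)
  # guard the interval ends (rate-homogeneous data push the shape upward)
  cand <- c(interval[1], opt$maximum, interval[2])
  ll <- vapply(cand, f, numeric(1))
  structure(cand[which.max(ll)], loglik = max(ll))
}
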