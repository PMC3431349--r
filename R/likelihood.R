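# Site-pattern compression: unique columns and their multiplicities.
# states: L x n integer matrix (columns = sequences, NA = missing).
compress_patterns <- function(states) {
  key <- apply(states, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.vector(table(key)[key[first]])
  list(states = states[first, , drop = FALSE], weights = weights)
}

# Tip partial-likelihood matrix: 20 x npatterns, indicator columns
# (all ones for missing data).
tip_partials <- function(tip_states) {
  np <- length(tip_states)
  L <- matrix(0, 20L, np)
  miss <- is.na(tip_states)
  L[, miss] <- 1
  if (any(!miss)) L[cbind(tip_states[!miss], which(!miss))] <- 1
  L
}

# Precomputed likelihood engine for a fixed alignment/columns/model/gamma.
# Tip partials and pattern weights are built once; the returned closure
# evaluates the pruning log-likelihood of any tree over those tips (it is
# called thousands of times during branch-length optimization and NNI
# search, so everything tree-independent lives out here).
lik_engine <- function(aln, model, gamma, columns) {
  ids <- alignment_ids(aln)
  states <- vapply(ids, function(id) encode_states(aln$mat[id, columns]),
                   integer(length(columns)))
  states <- matrix(states, ncol = length(ids), dimnames = list(NULL, ids))
  cp <- compress_patterns(states)
  np <- nrow(cp$states)
  tips_by_id <- lapply(ids, function(id) tip_partials(cp$states[, id]))
  names(tips_by_id) <- ids
  rates <- if (is.null(gamma)) 1 else gamma$rates
  weights <- cp$weights
  pi <- model$pi

  function(tree) {
    miss <- setdiff(tree$tip.label, ids)
    if (length(miss))
      stop("tree tips absent from alignment: ", paste(miss, collapse = ", "))
    if (is.null(tree$edge.length)) stop("tree must have branch lengths")
    attr(tree, "order") <- NULL  # rearranged trees may carry a stale order
    tr <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tr$tip.label)
    n_node <- n_tip + tr$Nnode
    edge <- tr$edge
    elen <- tr$edge.length
    root <- edge[nrow(edge), 1L]
    tip_mats <- tips_by_id[tr$tip.label]
    evl <- model$evec_left; evr <- model$evec_right; lam <- model$lambda
    cat_ll <- matrix(0, np, length(rates))
    for (ci in seq_along(rates)) {
      r <- rates[ci]
      partials <- vector("list", n_node)
      logscale <- numeric(np)
      for (k in seq_len(nrow(edge))) {
        parent <- edge[k, 1L]; child <- edge[k, 2L]
        Lc <- if (child <= n_tip) tip_mats[[child]] else partials[[child]]
        P <- evl %*% (exp(lam * (elen[k] * r)) * evr)
        P[P < 0] <- 0
        contrib <- P %*% Lc
        if (is.null(partials[[parent]])) {
          partials[[parent]] <- contrib
        } else {
          acc <- partials[[parent]] * contrib
          # rescale columns only when underflow threatens (cheap min check)
          if (min(acc) < 1e-120) {
            mx <- pmax(apply(acc, 2L, max), 1e-300)
            acc <- sweep(acc, 2L, mx, "/")
            logscale <- logscale + log(mx)
          }
          partials[[parent]] <- acc
        }
      }
      site_lik <- as.vector(pi %*% partials[[root]])
      cat_ll[, ci] <- log(pmax(site_lik, 1e-300)) + logscale
    }
    mx <- cat_ll[, 1L]
    for (ci in seq_len(ncol(cat_ll))[-1L]) mx <- pmax(mx, cat_ll[, ci])
    site_ll <- mx + log(rowMeans(exp(cat_ll - mx)))
    sum(site_ll * weights)
  }
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Log-likelihood of an alignment on a tree under the substitution model
#' with discrete-gamma rate variation (per-site likelihoods averaged over
#' the equiprobable categories).  Gaps and ambiguity letters are missing
#' data (partial likelihood 1); site patterns are compressed; column
#' rescaling guards against underflow.  The value is invariant to the
#' (arbitrary) rooting of an unrooted tree because the model is reversible.
#'
#' @param tree an `ape::phylo` whose tip labels all occur in the alignment.
#' @param aln a `sial_aln`.
#' @param model a [substitution_model()].
#' @param gamma optional [discrete_gamma()] rates (NULL = single rate).
#' @param columns columns to use (e.g. a coverage-filtered set).
#' @return total log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, aln, model = wag_model(), gamma = NULL,
                                columns = seq_len(alignment_length(aln))) {
  lik_engine(aln, model, gamma, columns)(tree)
}
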