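# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and the library calls the package wraps) so that
# implementation and expectation come from different routes.

# Quadratic affine-gap Smith-Waterman, direct dynamic programming.
# Gap of length g costs open + g * extend (first gap residue pays both).
sw_score_oracle <- function(a, b, submat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[a[i - 1], b[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# Exact upper-tail binomial probability by term-by-term summation of the
# binomial mass written out from factorials (no distribution functions).
binom_upper_oracle <- function(k, N, p) {
  if (k <= 0) return(1)
  terms <- vapply(k:N, function(i)
    exp(lgamma(N + 1) - lgamma(i + 1) - lgamma(N - i + 1) +
          i * log(p) + (N - i) * log(1 - p)), numeric(1))
  min(1, sum(terms))
}

# Two-sided Fisher p-value by full enumeration of all tables with the
# observed margins, summing those with point probability <= observed
# (within a numerical fudge for ties).
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (n == 0) return(1)
  point <- function(x) exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, point, numeric(1))
  p_obs <- point(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Additive distance matrix of a tree (path lengths), computed from the
# edge list by accumulating root-to-tip paths -- no cophenetic() call.
tree_path_dists <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  # depth of every node from an arbitrary root by edge walking
  depth <- rep(NA_real_, nn)
  parent_of <- rep(NA_integer_, nn)
  plen <- rep(NA_real_, nn)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth[root] <- 0
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + tree$edge.length[k]
        parent_of[ch] <- p
        done <- FALSE
      }
    }
    if (done) break
  }
  ancestors <- function(v) {
    out <- v
    while (!is.na(parent_of[v])) { v <- parent_of[v]; out <- c(out, v) }
    out
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- ancestors(i); aj <- ancestors(j)
    mrca <- ai[ai %in% aj][1]
    D[i, j] <- D[j, i] <- depth[i] + depth[j] - 2 * depth[mrca]
  }
  D
}

# Mean between-clade path distance from a tree over two tip sets.
mean_group_path <- function(tree, tips_a, tips_b) {
  D <- tree_path_dists(tree)
  mean(D[tips_a, tips_b])
}
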