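test_that("NJ recovers additive matrices exactly", {
  # three-point formulas on a triplet
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  d <- stats::setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                       tr3$tip.label)
  expect_equal(d[["a"]], (5 + 9 - 10) / 2)
  expect_equal(d[["b"]], (5 + 10 - 9) / 2)
  expect_equal(d[["c"]], (9 + 10 - 5) / 2)
  # random additive matrices from random trees: exact topology and lengths
  set.seed(19)
  for (i in 1:10) {
    tr <- ape::rtree(5 + (i %% 4))
    D <- tree_path_dists(tr)
    rec <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(rec, ape::unroot(tr))), 0)
    expect_equal(tree_path_dists(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  # quartet oracle: best of the three resolved topologies
  for (i in 1:10) {
    tr <- ape::rtree(4)
    D <- tree_path_dists(tr)
    rec <- nj_tree(D)
    tips <- rownames(D)
    # four-point oracle: the true split minimizes the cross-pair sum
    cands <- list(c(1, 2), c(1, 3), c(1, 4))
    scores <- vapply(cands, function(p) {
      q <- setdiff(1:4, p)
      D[p[1], p[2]] + D[q[1], q[2]]
    }, numeric(1))
    oracle_pair <- tips[cands[[which.min(scores)]]]
    # split reconstructed by NJ: two tips attached to one internal node
    ur <- ape::unroot(rec)
    tab <- table(ur$edge[ur$edge[, 2] <= 4, 1])
    nd <- as.integer(names(tab)[tab == 2][1])
    rec_pair <- ur$tip.label[ur$edge[ur$edge[, 1] == nd &
                                       ur$edge[, 2] <= 4, 2]]
    agree <- setequal(rec_pair, oracle_pair) ||
      setequal(rec_pair, setdiff(tips, oracle_pair))
    expect_true(agree)
  }
  Dbad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(Dbad), "3 taxa")
  Dasym <- matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3)
  expect_error(nj_tree(Dasym), "symmetric")
})

test_that("BioNJ also reconstructs additive data", {
  set.seed(37)
  tr <- ape::rtree(6)
  D <- tree_path_dists(tr)
  rec <- bionj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(rec, ape::unroot(tr))), 0)
})

test_that("branch-length optimization never decreases the likelihood", {
  m <- wag_model()
  g <- discrete_gamma(2, 4)
  tr <- ape::read.tree(
    text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.12,e:0.4);")
  set.seed(41)
  aln <- simulate_alignment(tr, m, g, 150)
  start <- tr
  start$edge.length <- rep(0.5, length(start$edge.length))
  ll0 <- tree_log_likelihood(start, aln, m, g)
  opt <- optimize_branch_lengths(start, aln, m, g)
  expect_gt(attr(opt, "loglik"), ll0)
  # near the generating lengths, and reproducible
  opt2 <- optimize_branch_lengths(start, aln, m, g)
  expect_equal(opt$edge.length, opt2$edge.length)
})

test_that("tree search improves on its start tree and is deterministic", {
  m <- wag_model()
  g <- discrete_gamma(1, 4)
  tr <- ape::read.tree(text = paste0(
    "(((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15):0.1,(e:0.2,f:0.2):0.1);"))
  set.seed(43)
  aln <- simulate_alignment(tr, m, g, 200)
  D <- ml_distance_matrix(aln, m, g)
  ll_start <- tree_log_likelihood(nj_tree(D), aln, m, g)
  fit <- optimize_tree(aln, m, g, start = "nj")
  expect_gte(attr(fit, "loglik"), ll_start)
  fit2 <- optimize_tree(aln, m, g, start = "nj")
  expect_equal(ape::write.tree(fit), ape::write.tree(fit2))
  expect_equal(attr(fit, "loglik"), attr(fit2, "loglik"))
})

test_that("bootstrap supports separate clear clades and respect bounds", {
  m <- wag_model()
  tr <- ape::read.tree(text = paste0(
    "((a:0.05,b:0.05):0.5,(c:0.05,d:0.05):0.5,(e:0.05,f:0.05):0.5);"))
  set.seed(47)
  aln <- simulate_alignment(tr, m, NULL, 150)
  bs <- bootstrap_support(aln, m, NULL, B = 20, seed = 3, start = "nj")
  expect_true(all(bs$node.label >= 0 & bs$node.label <= 100))
  # the cherries are unambiguous at this depth
  cherries <- bs$node.label[-1]  # drop the root pseudo-node
  expect_true(all(cherries >= 95))
  bs2 <- bootstrap_support(aln, m, NULL, B = 20, seed = 3, start = "nj")
  expect_equal(bs$node.label, bs2$node.label)
  # B = 1: supports are all-or-nothing
  bs1 <- bootstrap_support(aln, m, NULL, B = 1, seed = 5, start = "nj")
  expect_true(all(bs1$node.label %in% c(0, 100)))
})

test_that("gamma-shape estimation behaves across regimes", {
  m <- wag_model()
  tr <- ape::read.tree(
    text = "((a:0.3,b:0.3):0.2,(c:0.3,d:0.3):0.2,(e:0.3,f:0.3):0.2);")
  # strong rate variation: estimate should sit well below the cap
  set.seed(53)
  aln <- simulate_alignment(tr, wag_model(), discrete_gamma(1, 5), 800)
  a_hat <- estimate_gamma_shape(tr, aln, m)
  expect_gt(a_hat, 0.4)
  expect_lt(a_hat, 3)
  # logL at the estimate beats probed alternatives
  ll_at <- function(a) tree_log_likelihood(tr, aln, m, discrete_gamma(a, 5))
  expect_gte(attr(a_hat, "loglik") + 1e-6, max(vapply(c(0.3, 1, 5),
                                                      ll_at, numeric(1))))
  # rate-homogeneous data push the estimate to the upper bound
  set.seed(59)
  aln0 <- simulate_alignment(tr, wag_model(), NULL, 400)
  a0 <- estimate_gamma_shape(tr, aln0, m, interval = c(0.05, 20))
  expect_gt(as.numeric(a0), 15)
})
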