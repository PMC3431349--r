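test_that("local alignment scores match the DP oracle and are symmetric", {
  submat <- sialevo:::get_blosum62()
  expect_equal(pairwise_score("HEAGAWGHEE", "PAWHEAE"),
               sw_score_oracle("HEAGAWGHEE", "PAWHEAE", submat))
  # self-alignment equals the diagonal sum
  s <- "MKVLHEAGW"
  expect_equal(pairwise_score(s, s),
               sum(diag(submat[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  set.seed(11)
  letters20 <- rownames(submat)[1:20]
  for (i in 1:12) {
    a <- paste(sample(letters20, sample(8:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(letters20, sample(8:20, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_score(a, b), pairwise_score(b, a))
    expect_equal(pairwise_score(a, b), sw_score_oracle(a, b, submat))
  }
  expect_error(pairwise_score("", "AC"), "non-empty")
  expect_error(score_params(gap_open = 0), "positive")
})

test_that("RBH assigns identical queries to their reference, mutually", {
  refs <- c(r1 = "MKVLHEAGWKKV", r2 = "TTTYYYPPPQQQ")
  labels <- c(r1 = "NEU1", r2 = "NEU2")
  queries <- c(q1 = "MKVLHEAGWKKV", q2 = "TTTYYYPPPQQA")
  res <- rbh_assign(queries, refs, labels)
  expect_equal(res$subgroup, c("NEU1", "NEU2"))
  expect_true(all(res$mutual))
  expect_equal(res$best_ref, c("r1", "r2"))
})

test_that("RBH is permutation-invariant and warns on ties", {
  refs <- c(r1 = "MKVLHEAGWKKV", r2 = "TTTYYYPPPQQQ")
  labels <- c(r1 = "NEU1", r2 = "NEU2")
  queries <- c(q1 = "MKVLHEAGWKKI", q2 = "TTTYYYPPPQQA", q3 = "MKVAHEAGWKKV")
  res1 <- rbh_assign(queries, refs, labels)
  res2 <- rbh_assign(rev(queries), rev(refs), labels)
  expect_equal(res1[order(res1$id), c("subgroup", "best_ref", "mutual")],
               res2[order(res2$id), c("subgroup", "best_ref", "mutual")],
               ignore_attr = TRUE)
  # two references with identical sequence force a tie for any query
  refs_tie <- c(rb = "MKVLHEAGWKKV", ra = "MKVLHEAGWKKV")
  expect_warning(
    out <- rbh_assign(c(q = "MKVLHEAGWKKV"), refs_tie,
                      c(ra = "NEU1", rb = "NEU1")),
    "tied")
  expect_equal(out$best_ref, "ra")  # lexicographic tie-break
})

test_that("simulated families assign to the correct clade", {
  m <- wag_model()
  tr <- ape::read.tree(text = paste0(
    "((A_1:0.05,A_2:0.05):0.6,(B_1:0.05,B_2:0.05):0.6);"))
  set.seed(21)
  aln <- simulate_alignment(tr, m, NULL, 300)
  seqs <- ungapped_sequences(aln)
  res <- rbh_assign(seqs[c("A_2", "B_2")], seqs[c("A_1", "B_1")],
                    c(A_1 = "NEU1", B_1 = "NEU2"))
  expect_equal(res$subgroup, c("NEU1", "NEU2"))
  expect_true(all(res$mutual))
})

test_that("subfamily-specific residue calls obey the thresholds", {
  seqs <- c(i1 = "EAAC", i2 = "EAAC", i3 = "EACC",
            o1 = "DAAC", o2 = "DACC", o3 = "DAAC")
  aln <- sial_alignment(seqs)
  res <- subfamily_specific_residues(aln, paste0("i", 1:3), paste0("o", 1:3))
  # column 1: E fixed in-group, absent out-group
  expect_true(1 %in% res$column)
  r1 <- res[res$column == 1, ]
  expect_equal(r1$residue, "E")
  expect_equal(r1$freq_in, 1)
  expect_equal(r1$freq_out, 0)
  # columns where groups agree are never called
  expect_false(2 %in% res$column)
  expect_false(4 %in% res$column)
  # identical groups -> no calls at any out_threshold < in_threshold
  aln_same <- sial_alignment(c(i1 = "EAAC", i2 = "EAAC",
                               o1 = "EAAC", o2 = "EAAC"))
  expect_equal(nrow(subfamily_specific_residues(
    aln_same, c("i1", "i2"), c("o1", "o2"),
    in_threshold = 0.7, out_threshold = 0.2)), 0L)
})

test_that("specific-residue calls are monotone in both thresholds", {
  set.seed(31)
  n <- 10
  mat <- replicate(30, sample(c("E", "D", "A"), 2 * n, replace = TRUE))
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- c(paste0("i", 1:n), paste0("o", 1:n))
  aln <- sial_alignment(seqs)
  n_calls <- function(it, ot) nrow(subfamily_specific_residues(
    aln, paste0("i", 1:n), paste0("o", 1:n), it, ot))
  for (ot in c(0.1, 0.3)) {
    counts <- vapply(c(0.3, 0.5, 0.7, 0.9), n_calls, integer(1), ot = ot)
    expect_true(all(diff(counts) <= 0))  # raising in_threshold never adds calls
  }
  for (it in c(0.5, 0.7)) {
    counts <- vapply(c(0.4, 0.3, 0.2, 0.1), n_calls, integer(1), it = it)
    expect_true(all(diff(counts) <= 0))  # lowering out_threshold never adds calls
  }
})

test_that("calls are reported in reference coordinates when asked", {
  seqs <- c(i1 = "E-AC", i2 = "EAAC", o1 = "DAAC", o2 = "D-AC")
  aln <- sial_alignment(seqs)
  res <- subfamily_specific_residues(aln, c("i1", "i2"), c("o1", "o2"),
                                     in_threshold = 0.9, out_threshold = 0.1,
                                     ref_id = "i1")
  r1 <- res[res$column == 1, ]
  expect_equal(r1$ref_pos, 1L)
})
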