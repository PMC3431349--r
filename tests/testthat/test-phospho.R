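make_phospho_aln <- function() {
  # 10 sequences, 8 columns; metadata splits them 5 (NEU1) / 5 (NEU2);
  # column 1 is NEU1-private S, column 5 near-universal Y (one gap)
  seqs <- c(a1 = "SATAYAAC", a2 = "SATAYA-C", a3 = "SATA-AAC",
            a4 = "SATAYAAC", a5 = "SATAYAAC",
            b1 = "AASAYAAC", b2 = "AAAAYAAC", b3 = "AATAYAAC",
            b4 = "AATAYAAC", b5 = "AATAYAAC")
  meta <- data.frame(id = names(seqs),
                     subgroup = rep(c("NEU1", "NEU2"), each = 5),
                     taxon_group = c("mammals", "mammals", "vertebrates",
                                     "vertebrates", "deuterostomes",
                                     rep("early_metazoa", 5)))
  sial_alignment(seqs, meta)
}

test_that("site mapping collapses equivalent positions and validates residues", {
  aln <- make_phospho_aln()
  sites <- data.frame(seq_id = c("a1", "b1", "a2"),
                      residue_pos = c(1L, 3L, 5L),
                      residue = c("S", "S", "Y"))
  # a1 residue 1 -> column 1; b1 residue 3 -> column 3; a2 residue 5 -> column 5
  expect_equal(map_sites_to_columns(sites, aln), c(1L, 3L, 5L))
  # two sites from different proteins on the same column collapse
  sites2 <- rbind(sites, data.frame(seq_id = "a3", residue_pos = 3L,
                                    residue = "T"))
  expect_equal(map_sites_to_columns(sites2, aln), c(1L, 3L, 5L))
  expect_equal(map_sites_to_columns(sites[0, ], aln), integer(0))
  bad <- data.frame(seq_id = "a1", residue_pos = 2L, residue = "S")
  expect_error(map_sites_to_columns(bad, aln), "mismatch")
  expect_error(map_sites_to_columns(
    data.frame(seq_id = "a1", residue_pos = 1L, residue = "A"), aln),
    "S, T or Y")
})

test_that("background frequency counts S/T/Y over non-gap residues", {
  aln <- sial_alignment(c(x = "STY"))
  bg <- background_frequency(aln)
  expect_equal(bg$p, 1)
  expect_equal(bg$total_sites, 3L)
  aln2 <- sial_alignment(c(x = "ACD-", y = "AC-D"))
  expect_equal(background_frequency(aln2)$p, 0)
  expect_equal(background_frequency(aln2)$total_sites, 6L)
  # independent recount on the shared fixture
  aln3 <- make_phospho_aln()
  v <- as.vector(as.matrix(aln3))
  expect_equal(background_frequency(aln3)$total_sites, sum(v != "-"))
  expect_equal(background_frequency(aln3)$p,
               sum(v %in% c("S", "T", "Y")) / sum(v != "-"))
})

test_that("column conservation honours both denominator conventions", {
  aln <- make_phospho_aln()
  ids <- alignment_ids(aln)
  # column 5: Y in 9 sequences, gap in a3 -> 100% non-gap, 90% gap-inclusive
  expect_equal(column_conservation(aln, 5, ids, "nongap"), 100)
  expect_equal(column_conservation(aln, 5, ids, "all"), 90)
  # all-S column in a 10-sequence group
  big <- sial_alignment(stats::setNames(rep("S", 10), paste0("s", 1:10)))
  expect_equal(column_conservation(big, 1), 100)
  expect_error(column_conservation(aln, 1, character(0)), "non-empty")
  # the published percentages arise from the same counts:
  # 82 of 83 phosphorylatable -> 98.80; 35 of 37 -> 94.59
  seqs83 <- stats::setNames(c(rep("S", 82), "A"), paste0("p", 1:83))
  expect_equal(round(column_conservation(sial_alignment(seqs83), 1), 2), 98.80)
  seqs37 <- stats::setNames(c(rep("S", 35), "A", "A", rep("-", 3)),
                            paste0("p", 1:40))
  expect_equal(round(column_conservation(sial_alignment(seqs37), 1), 2), 94.59)
})

test_that("binomial conservation test equals the exact summation oracle", {
  expect_equal(binomial_conservation_test(0, 83, 0.023), 1)
  expect_equal(binomial_conservation_test(83, 83, 0.023), 0.023^83)
  expect_equal(binomial_conservation_test(50, 83, 0.023),
               binom_upper_oracle(50, 83, 0.023), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    N <- sample(5:120, 1)
    k <- sample.int(N, 1)
    p <- runif(1, 0.005, 0.6)
    expect_equal(binomial_conservation_test(k, N, p),
                 binom_upper_oracle(k, N, p), tolerance = 1e-10)
  }
  # strictly decreasing in k
  ps <- vapply(0:20, binomial_conservation_test, numeric(1), N = 20, p = 0.1)
  expect_true(all(diff(ps) < 0))
  expect_error(binomial_conservation_test(3, 10, 0), "in \\(0, 1\\)")
  expect_error(binomial_conservation_test(11, 10, 0.1), "\\[0, N\\]")
})

test_that("Fisher test equals full enumeration on all tables with margins <= 12", {
  # proportional rows -> 1; disjoint diagonal -> 2/252
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  for (r1 in 0:12) for (c1 in 0:12) {
    r2 <- 12 - r1
    for (a in max(0, c1 - r2):min(r1, c1)) {
      tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(tab),
                   fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   tolerance = 1e-9)
    }
  }
  # invariance under simultaneous row and column swaps
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[2:1, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("contingency tables count phosphorylatable vs other per group", {
  aln <- make_phospho_aln()
  grp <- paste0("a", 1:5)
  # column 1: S in all of the group; A throughout the complement
  expect_equal(unname(build_group_contingency(aln, 1, grp)),
               matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  # column 5 has a gap in a3: nongap drops it, all counts it as other
  expect_equal(unname(build_group_contingency(aln, 5, grp, denominator = "nongap")),
               matrix(c(4, 0, 5, 0), 2, byrow = TRUE))
  expect_equal(unname(build_group_contingency(aln, 5, grp, denominator = "all")),
               matrix(c(4, 1, 5, 0), 2, byrow = TRUE))
  # all-S in group of 10, all-A outside in group of 20
  seqs <- c(stats::setNames(rep("S", 10), paste0("g", 1:10)),
            stats::setNames(rep("A", 20), paste0("h", 1:20)))
  aln2 <- sial_alignment(seqs)
  expect_equal(unname(build_group_contingency(aln2, 1, paste0("g", 1:10))),
               matrix(c(10, 0, 0, 20), 2, byrow = TRUE))
  expect_error(build_group_contingency(aln, 1, character(0)), "non-empty")
  expect_error(build_group_contingency(aln, 1, grp, grp), "disjoint")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 84), 0.84)
  expect_equal(bonferroni(0.5, m = 3), 1)
  set.seed(2)
  p <- runif(30)
  expect_true(all(bonferroni(p, m = 50) >= p))
  expect_true(all(bonferroni(p, m = 50) <= 1))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("column stats and flags follow the published relevance rules", {
  aln <- make_phospho_aln()
  stats <- phospho_column_stats(aln, c(1L, 3L, 5L, 7L))
  expect_equal(stats$k, c(5L, 9L, 9L, 0L))
  expect_true(all(stats$p_binomial_adj >= stats$p_binomial_raw - 1e-15))
  expect_true(all(stats$p_binomial_adj <= 1))
  flagged <- classify_sites(stats, alpha = 0.05)
  # column 5 is fully conserved (non-gap) in both groups: global flag only
  row5 <- flagged[flagged$column == 5, ]
  expect_true(row5$flag_global60)
  expect_true(row5$flag_global90)
  expect_equal(row5$specific_subgroups, "")
  # column 1 is NEU1-only: subgroup-specific, not global
  row1 <- flagged[flagged$column == 1, ]
  expect_equal(row1$specific_subgroups, "NEU1")
  # cons90 flags imply cons60 flags across all rows
  expect_true(all(!flagged$flag_global90 | flagged$flag_global60))
  hm <- conservation_matrix(stats)
  expect_equal(dim(hm)[1], 4L)
  expect_true(all(hm >= 0 & hm <= 100))
})
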