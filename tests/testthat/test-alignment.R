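test_that("FASTA round trip preserves records and enforces upper case", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first sequence", "acdef-ghik", ">s2", "ACDEFWGHIK"), path)
  aln <- read_alignment(path)
  expect_equal(n_sequences(aln), 2L)
  expect_equal(alignment_length(aln), 10L)
  expect_equal(unname(ungapped_sequences(aln, "s1")), "ACDEFGHIK")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(read_alignment(out)$mat, aln$mat)
})

test_that("ragged, empty and dialect-mixing inputs are rejected by name", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">long", "ACDEFGHIKL", ">short", "ACDEFGHIK"), path)
  expect_error(read_alignment(path), "short")
  writeLines(character(0), path)
  expect_error(read_alignment(path), "empty|records")
  expect_error(sial_alignment(c(a = "AC.D", b = "ACDD")), "'\\.'")
  expect_error(sial_alignment(c(a = "AC1D", b = "ACDD")), "invalid residue")
  expect_error(sial_alignment(c(a = "ACD", a = "ACD")), "duplicate")
})

test_that("metadata tokens are validated and missing ids fall back to unknown", {
  aln_seqs <- c(h1 = "ACDEF", h2 = "ACDEY", h3 = "ACDEW")
  meta <- data.frame(id = c("h1", "h2"), subgroup = c("NEU1", "NEU5"),
                     taxon_group = c("mammals", "early_metazoa"))
  aln <- sial_alignment(aln_seqs, meta)
  expect_equal(aln$metadata$subgroup, c("NEU1", "NEU5", "unknown"))
  bad <- data.frame(id = "h1", subgroup = "NEU9", taxon_group = "mammals")
  expect_error(sial_alignment(aln_seqs, bad), "valid tokens")
  extra <- data.frame(id = c("h1", "ghost"), subgroup = c("NEU1", "NEU2"),
                      taxon_group = c("mammals", "mammals"))
  expect_warning(sial_alignment(aln_seqs, extra), "ghost")
})

test_that("taxon groups are nested: mammals within vertebrates within deuterostomes", {
  meta <- data.frame(id = c("a", "b", "c", "d"),
                     subgroup = "NEU1",
                     taxon_group = c("mammals", "vertebrates",
                                     "deuterostomes", "early_metazoa"))
  aln <- sial_alignment(c(a = "AC", b = "AC", c = "AC", d = "AC"), meta)
  expect_equal(taxon_members(aln, "mammals"), "a")
  expect_equal(taxon_members(aln, "vertebrates"), c("a", "b"))
  expect_equal(taxon_members(aln, "deuterostomes"), c("a", "b", "c"))
  expect_equal(taxon_members(aln, "early_metazoa"), "d")
})

test_that("coordinate maps are strictly increasing and round trip", {
  aln <- sial_alignment(c(r = "A-CD", s = "ACDE"))
  cm <- coordinate_map(aln, "r")
  expect_equal(unname(residue_to_column(cm, 1:3)), c(1L, 3L, 4L))
  expect_true(is.na(column_to_residue(cm, 2)))
  expect_equal(column_to_residue(cm, residue_to_column(cm, 1:3)), 1:3)
  expect_error(coordinate_map(aln, "nope"), "unknown sequence")
  expect_error(residue_to_column(cm, 4), "out of range")
  # property: mapped residues equal ungapped length, over random alignments
  set.seed(1)
  for (i in 1:20) {
    chars <- sample(c("A", "C", "D", "-"), 30, replace = TRUE)
    a <- sial_alignment(c(x = paste(chars, collapse = ""),
                          y = paste(rev(chars), collapse = "")))
    cmx <- coordinate_map(a, "x")
    expect_equal(length(cmx$col_of_residue), sum(chars != "-"))
    expect_true(all(diff(cmx$col_of_residue) > 0))
  }
})

test_that("site coverage counts unambiguous residues only", {
  aln <- sial_alignment(c(a = "AAXA", b = "A-AA", c = "AA-A", d = "AABA"))
  # column 3 holds X, A, gap, B: only the plain residue counts
  expect_equal(site_coverage(aln), c(1, 0.75, 0.25, 1))
  expect_error(site_coverage(aln, 9), "out of range")
})

test_that("coverage filtering matches hand computation and is monotone", {
  # coverages (1, .6, .8, .4, 1) over five sequences
  rows <- c("AAAAA", "AAAAA", "AAA-A", "A-A-A", "A---A")
  names(rows) <- paste0("s", 1:5)
  aln <- sial_alignment(rows)
  expect_equal(unname(site_coverage(aln)), c(1, 0.6, 0.8, 0.4, 1))
  expect_equal(filter_columns(aln, 0.7, strict = TRUE), c(1L, 3L, 5L))
  expect_equal(filter_columns(aln, 0, strict = FALSE), 1:5)
  expect_equal(filter_columns(aln, 1, strict = FALSE), c(1L, 5L))
  # monotone non-increasing in the threshold
  lens <- vapply(seq(0, 1, by = 0.1),
                 function(th) length(filter_columns(aln, th)), integer(1))
  expect_true(all(diff(lens) <= 0))
  # residue-count bookkeeping: column non-gap counts sum to ungapped lengths
  expect_equal(sum(site_coverage(aln) * n_sequences(aln)),
               sum(nchar(ungapped_sequences(aln))))
})

test_that("result tables and trees round trip through disk", {
  df <- data.frame(id = c("a", "b"), value = c(1.5, -2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(df, path, comments = c(config_hash = "cafe0123"))
  expect_equal(read_result_table(path), df)
  expect_match(readLines(path)[1], "cafe0123")

  tr <- ape::rtree(5)
  tpath <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, tpath)
  back <- read_tree(tpath)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))),
               0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  writeLines("((a,b,(c);", tpath)
  expect_error(read_tree(tpath), "malformed|parenthes")
})
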