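---
title: "Models and methods behind sialevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sialevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sialevo)
```

# Scope

`sialevo` packages the comparative-analysis workflow used to study the
metazoan sialidase (neuraminidase) family NEU1–NEU5: assigning candidate
protein sequences to subfamilies, quantifying between-subfamily divergence
under an empirical amino-acid substitution model, testing the conservation
of phosphorylatable residues, scanning for the family's sequence signatures
(Asp-boxes, the N-terminal motif, the six catalytic residues, the
inter-blade loops, exon junctions), and reconstructing the family phylogeny.
The multiple sequence alignment is an *input*: the package neither aligns
sequences nor mines databases, and it does not predict phosphorylation
sites — predictor output is consumed as a table.

Because the workflow is meant to be testable end to end without any
download, the package also contains a first-class synthetic-data generator
whose default scenario mimics the structure of the sialidase dataset.

# The substitution model

All evolutionary computations use a reversible amino-acid model: rate
matrix $Q_{ij} = s_{ij}\pi_j$ for $i \ne j$, with symmetric
exchangeabilities $s_{ij}$ and stationary frequencies $\pi$, scaled so that
$-\sum_i \pi_i Q_{ii} = 1$ — branch lengths are expected substitutions per
site. The shipped constants are the published WAG estimates; `wag_model()`
builds the scaled matrix and its symmetric eigendecomposition, from which
`transition_matrix()` forms $P(t) = e^{Qt}$ for any branch length in one
$20\times 20$ reconstruction. Invariants enforced by tests: zero row sums,
detailed balance $\pi_iQ_{ij} = \pi_jQ_{ji}$, stochastic $P(t)$, the
semigroup law $P(t_1)P(t_2) = P(t_1{+}t_2)$, and the ergodic limit
$P(t)\to\mathbf{1}\pi^\top$.

Rate variation across sites uses the discrete-gamma approximation with $K$
equiprobable categories (default $K=5$); each category rate is the
conditional mean of a mean-one gamma within its quantile band (the median
variant is available by argument). The mean category rate is exactly 1 for
any shape. Two shape values appear as stage defaults because the original
protocol used both: shape 5 for between-subgroup divergences and an
estimated shape (its published point estimate, 2.6845, is the tree-stage
default) for the phylogeny. The two are deliberately *not* reconciled.

# Pairwise distances and between-subgroup divergence

`pairwise_ml_distance()` maximizes
$\ell(d) = \sum_{\text{sites}} \log \sum_k \tfrac1K\,
\pi_{x}\,[P(d\,r_k)]_{xy}$ over $d\in[10^{-8}, 50]$ by scalar optimization,
after collapsing each pair of rows into a $20\times20$ count matrix of
residue pairs (columns where either row has a gap or an ambiguity letter
are skipped pairwise). The gamma mixture collapses into the eigenbasis, so
an evaluation costs one matrix reconstruction. Boundary candidates are
checked explicitly, so identical sequences return exactly 0.

`between_group_divergence()` reproduces the divergence-table statistic:
distances for all $|A|\times|B|$ between-group pairs on the
coverage-filtered columns (strictly more than 70% site coverage, where
coverage counts unambiguous residues), averaged. The standard error is a
site bootstrap: filtered columns are resampled with replacement (default
500 replicates; smaller sizes are used in the test suite and acceptance
script, stated there), all pair distances re-estimated, and the standard
deviation of replicate means reported. The original tables used MEGA's
analytic SE; the bootstrap is this package's choice and agreement is
approximate by construction.

# Tree likelihood and search

`tree_log_likelihood()` is Felsenstein pruning over site patterns
(compressed once per alignment/column set), with gamma-category averaging
by log-sum-exp and per-column rescaling against underflow. Gaps and
ambiguity codes are missing data — never a 21st state. The implementation
is checked three ways: against brute-force marginalization over internal
states on four-taxon trees (agreement to $10^{-8}$), against re-rooting
invariance, and against an independent implementation (`phangorn::pml`),
which agrees to $10^{-6}$ log units on simulated data.

`optimize_tree()` follows the classic heuristic: NJ and BioNJ starting
topologies built from the ML distance matrix (the better start is kept),
coordinate-wise branch-length optimization (golden-section per edge,
iterated until a pass gains < $10^{-4}$ log units), then NNI hill-climbing.
Each round scores all NNI neighbours at current branch lengths and
re-optimizes only the most promising candidates — a deliberate trade of
thoroughness for speed that keeps the search deterministic; hill-climb
monotonicity (`logL(final) >= logL(start)`) is asserted in the tests.
`bootstrap_support()` resamples columns, reruns the full search per
replicate, and annotates each internal bipartition of the point-estimate
tree with its replicate percentage. `estimate_gamma_shape()` maximizes the
likelihood over the shape on a fixed tree; rate-homogeneous data push the
estimate to the search bound by design.

# Subfamily assignment and subgroup-specific residues

BLAST is not re-implemented. The reciprocal-best-hit scheme only needs a
consistent similarity ranking, so scores are Smith–Waterman local
alignments under BLOSUM62 with gap open 11 / extend 1 (protein-BLAST
defaults). A query inherits its best reference's subgroup only when it is
also that reference's best query (ties broken lexicographically, with a
warning); otherwise it is reported `unassigned`. Note a structural
consequence: with $r$ references at most $r$ queries can be mutual, so on a
many-queries-few-references design the meaningful correctness property —
asserted in the acceptance suite — is that no best hit ever crosses
subfamilies and every mutual assignment is correct.

Subgroup-specific residues operationalize the subfamily-logo contrast as
two frequency thresholds: the in-group's modal residue is called specific
when it reaches `in_threshold` (default 0.7) inside the group and stays at
or below `out_threshold` (default 0.2) outside. Calls can be reported in
the residue numbering of a reference (e.g. the group's human member). The
number of calls is monotone in both thresholds, which the tests assert.

# Phosphorylatable-site conservation

A column position is "phosphorylatable" in a sequence when it carries S, T
or Y, regardless of which residue the upstream predictor named. Predictor
sites are validated against their sequences and projected to alignment
columns; equivalent positions from different proteins collapse.

Global conservation at a column is tested with a one-sided binomial upper
tail $P(X \ge k)$, $X \sim \mathrm{Bin}(N, p)$, where $k$ counts S/T/Y in
the column, $N$ is the number of sequences, and $p$ is the alignment-wide
S/T/Y background over all non-gap, unambiguous residues. Group-specific
conservation uses a two-sided Fisher test on the group-vs-rest,
phosphorylatable-vs-not 2×2 table, for the five subfamilies and for the
nested taxonomic groups (mammals within vertebrates within deuterostomes,
plus early metazoans as outgroup), each group against all remaining
sequences. Both test families are Bonferroni-corrected with family size =
number of tested columns, applied separately per grouping scheme (the
partition of tests into families is configurable, since protocols differ
here). Flags follow the published relevance rules: corrected $p < 0.01$
plus conservation ≥ 60% (≥ 90% for the stronger global flag).

One denominator decision deserves emphasis. The binomial $N$ is the total
number of sequences — a gappy column keeps the full denominator. The
per-group conservation *percentages* and Fisher tables, however, default to
non-gap denominators (`denominator = "nongap"`): that is the convention the
family's published per-subgroup percentages follow (values such as 35/37 in
a 40-member subgroup are only explicable with gapped rows excluded), and
the gap-inclusive variant remains available as `denominator = "all"`.
Power and error control are verified by simulation: a column planted at
in-group frequency 0.95 vs out-group 0.02 (group 15 of 83) is flagged in
well over 95% of replicates, and on null columns drawn at the background
rate the Bonferroni-corrected family produces no false flag in ≥ 95% of
replicates of an 84-column family.

# Sequence features

Motifs are scanned on ungapped sequences with fixed patterns —
`S-x-D-x-G-x-x-[W/F]` for the Asp-box, `[T/F]-Y-R-[I/V]-P` for the
N-terminal motif — reporting every start, including overlapping ones.
Aligned motif locations are clustered by span overlap (≥ 1 shared column)
and summarized as the fraction of subgroup members with an intact motif.
Catalytic-residue checks demand identity with the reference residue in the
aligned column (the family reports *complete* conservation of R21, D46,
E218, R237, R304, Y334 in human NEU2 numbering, shipped as the default
table). Loop lengths count a sequence's residues strictly between the
aligned flanks of a reference-defined window, so insertions are measured
and a deleted loop scores 0; loops touching the reference terminus fall
back to the unflanked window with a warning. The default loop table is the
ten-loop set in NEU2 numbering, including the overlapping Loop 0/Loop 1
pair as published. Exon junctions are residue indices per sequence, mapped
to alignment columns through the same coordinate maps.

# The synthetic scenario

`generate_family_scenario()` produces the dataset every stage is tested
on. Its defaults are fixed once and mirror the real study's analyzed data:
83 sequences in five clades of 37/8/19/11/8 (the post-filtering partition —
the 40/8/20/11 counts describe the initial assignment before four poorly
aligning sequences were dropped), taxon labels echoing the real nested
totals (21 mammals / 52 vertebrates / 74 deuterostomes / 9 early
metazoans), a backbone with NEU1 most distant, NEU3–NEU4 closest and NEU5
intermediate (stem lengths chosen once so mean between-clade divergences
land in the 1–3 substitutions/site range of the published table), 900 core
columns simulated under WAG+Γ (shape 2.6845), and within-clade coalescent
subtrees of height 0.15.

Planted features, overwritten after simulation (a deliberate,
non-biological simplification — detectors do not care how the signal
arose): frozen catalytic columns in all sequences; five Asp-box locations
with boxes 2–3 family-wide, 1 and 5 concentrated in the NEU1-like clade and
partially in NEU5; a near-universal N-terminal motif; global and
subgroup/taxon-specific phosphorylatable columns at stated frequencies
(0.95/0.02 for specific ones) plus unplanted columns; clade-private
loop insertions (the only source of gaps — there is no indel process, which
is the generator's main departure from real alignments, where gap patterns
are far richer); and per-clade exon structures with 6/2/2/3/4 exons.
Everything is reproducible bit for bit from the configuration and seed, and
truth tables for each planted feature ship with the bundle.

What passing tests on this scenario show — and what they do not: they
validate the statistics and algorithms against known ground truth under the
model's own assumptions; they cannot certify behaviour under alignment
error, compositional heterogeneity, or realistic indel structure, none of
which the generator emulates.

One property of the scenario is worth understanding before reading its
outputs. The binomial and Fisher tests treat sequences as independent
draws, but sequences on a tree are correlated: a slowly evolving column
whose root happened to be a serine can come out almost fully conserved with
no planting at all. The scenario's *unplanted* columns therefore are not
"null" in the iid sense — some of them are legitimately flagged, exactly as
naturally conserved columns are in real data. Error control of the
Bonferroni machinery is therefore checked on genuinely iid columns drawn at
the background rate (where the familywise error is controlled as designed),
while the scenario's unplanted columns illustrate the test's known
blindness to phylogenetic correlation — a caveat that applies verbatim to
the original protocol.

# Numerical choices and degenerate inputs

* Scalar optimizations use `stats::optimize` (distance tolerance
  $10^{-6}$, branch edges $10^{-4}$, gamma shape $10^{-4}$), always with
  explicit boundary checks so optima at 0 or at the bound are returned
  exactly.
* Transition-matrix entries are clamped at 0 against eigendecomposition
  round-off; pruning rescales columns only when a partial likelihood drops
  below $10^{-120}$.
* Negative NJ/BioNJ branch estimates are clamped to 0.
* Site-pattern compression makes likelihoods independent of column order;
  identical configurations and seeds give byte-identical outputs
  throughout.
* Empty groups, unknown ids, ragged alignments, `.`-gap dialects, malformed
  newick and out-of-range coordinates all fail fast with named errors
  rather than propagating silently.

Problem sizes in the shipped tests and acceptance script are chosen at
desk scale: simulated checks use hundreds to a few thousand columns,
bootstrap sizes of 50–100 replicates for divergence SEs, 50 replicates for
topology recovery and 200 for detection power; these sizes are stated where
used and keep the whole suite runnable on a laptop while leaving the
statistical conclusions unambiguous.

# Known limitations

* The RBH stage ranks by local-alignment score, not E-value; profile
  methods (PSI-BLAST) and the original study's manual confirmation steps
  (similarity-matrix inspection, tree position) are out of scope — the
  reports give an analyst what those steps need.
* Divergence SEs are bootstrap, not analytic, estimates.
* The tree search is NNI-only (matching the scale of the original
  heuristic); SPR/TBR are not implemented.
* The generator plants features by overwriting simulated columns, so
  planted columns do not follow the site rate distribution of their
  neighbours.
* Model selection (the 48-candidate scan of the original protocol) is not
  reproduced; the winning model is the hard-coded default with overrides.
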