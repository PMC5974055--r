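test_that("affine-gap alignment scores equal the independent Gotoh oracle", {
  set.seed(21)
  mat <- circplasmid:::.nuc_matrix(1, -1)
  for (r in 1:60) {
    a <- random_dna_str(sample(3:12, 1)); b <- random_dna_str(sample(3:12, 1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 1,
      type = "global")
    expect_equal(Biostrings::score(pa), gotoh_global(a, b, nuc_score, 5, 1),
                 info = paste(a, b))
  }
  # the Gotoh oracle itself equals exhaustive path enumeration on tiny inputs
  for (r in 1:25) {
    a <- random_dna_str(sample(2:6, 1)); b <- random_dna_str(sample(2:6, 1))
    expect_equal(gotoh_global(a, b, nuc_score, 5, 1),
                 exhaustive_global(a, b, nuc_score, 5, 1), info = paste(a, b))
  }
})

test_that("circularAlign is exact on self and recovers random rotations", {
  fx <- family_fixture()
  a <- fx$fam$seqs[["A"]]
  self <- circularAlign(a, a)
  expect_equal(alnIdentity(self), 100)
  expect_equal(abs(self@rotation), 1L)
  set.seed(22)
  for (k in sample(2:seqLength(a), 5)) {
    al <- circularAlign(a, rotate(a, k))
    expect_equal(alnIdentity(al), 100)
    # rotating the rotated copy by the recovered offset restores the original
    expect_equal(residues(rotate(rotate(a, k), abs(al@rotation))), residues(a))
  }
  short <- circularSeq("s", "ACGTACGT")
  expect_error(circularAlign(a, short), "100 nt")
})

test_that("circularAlign auto-orients a reverse-complemented replicon", {
  fx <- family_fixture()
  a <- fx$fam$seqs[["A"]]
  rc <- circularSeq("rc", paste(rev(strsplit(chartr("ACGT", "TGCA",
        residues(a)), "")[[1]]), collapse = ""))
  al <- circularAlign(a, rc)
  expect_equal(alnIdentity(al), 100)
  expect_lt(al@rotation, 0)
})

test_that("progressive MSA handles duplicates, pairs, and beats star alignment", {
  fx <- family_fixture()
  a <- fx$fam$seqs[["A"]]
  # n copies of one sequence align gap-free
  copies <- list(a, circularSeq("A2", residues(a)), circularSeq("A3", residues(a)))
  msa <- progressiveMsa(copies)
  expect_false(any(grepl("-", msa@aligned, fixed = TRUE)))
  # two sequences: identical to the pairwise circular alignment
  b <- fx$fam$seqs[["B"]]
  msa2 <- progressiveMsa(list(a, b))
  al <- circularAlign(a, b)
  expect_equal(unname(msa2@aligned), alnStrings(al))
  # family MSA columns >= longest input
  msa5 <- progressiveMsa(fx$fam$seqs)
  expect_gte(nchar(msa5@aligned[[1]]),
             max(vapply(fx$fam$seqs, seqLength, integer(1))))
})

test_that("MSA distances are symmetric with zero diagonal and NJ is order-invariant", {
  fx <- family_fixture()
  msa <- progressiveMsa(fx$fam$seqs)
  d <- distFromMsa(msa)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  tree <- njTree(msa, bootstrap_n = 0)
  perm <- rev(fx$fam$seqs)
  tree2 <- njTree(progressiveMsa(perm), bootstrap_n = 0)
  expect_equal(ape::dist.topo(tree, tree2)[1], 0)
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- njTree(d, bootstrap_n = 0)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["x"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["y"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["z"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(23)
  for (r in 1:25) {
    tr <- ape::rtree(sample(5:8, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- stats::cophenetic(tr)
    rec <- njTree(D[tr$tip.label, tr$tip.label], bootstrap_n = 0)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec)[1], 0)
  }
})

test_that("bootstrap supports are deterministic given the seed", {
  fx <- family_fixture()
  msa <- progressiveMsa(fx$fam$seqs)
  t1 <- njTree(msa, bootstrap_n = 25, seed = 9)
  t2 <- njTree(msa, bootstrap_n = 25, seed = 9)
  expect_equal(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
})

test_that("region similarity reproduces the two divergence tiers of the family", {
  fx <- family_fixture()
  msa <- progressiveMsa(fx$fam$seqs)
  reg <- fx$anc$truth$regions
  f_end <- reg$end[reg$name == "F_block"]
  sim_f <- regionSimilarity(msa, 1, f_end)
  sim_rest <- regionSimilarity(msa, f_end + 1, seqLength(fx$fam$seqs[[1]]))
  expect_gt(sim_f, sim_rest + 15)       # clearly two-tiered
  expect_gt(sim_f, 75); expect_lt(sim_f, 95)
  expect_gt(sim_rest, 40); expect_lt(sim_rest, 65)
  # identical sequences give 100 anywhere
  a <- fx$fam$seqs[["A"]]
  msa_id <- progressiveMsa(list(a, circularSeq("A2", residues(a))))
  expect_equal(regionSimilarity(msa_id, 100, 500), 100)
  expect_error(regionSimilarity(msa, 0, 0), "no alignment columns")
})
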