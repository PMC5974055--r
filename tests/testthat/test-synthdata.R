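test_that("the generator is deterministic and seed-sensitive", {
  a1 <- generateAncestor(seed = 5)
  a2 <- generateAncestor(seed = 5)
  expect_identical(residues(a1$seq), residues(a2$seq))
  expect_identical(a1$truth$genes, a2$truth$genes)
  a3 <- generateAncestor(seed = 6)
  expect_false(identical(residues(a1$seq), residues(a3$seq)))
  f1 <- evolveFamily(a1, seed = 9)
  f2 <- evolveFamily(a2, seed = 9)
  expect_identical(lapply(f1$seqs, residues), lapply(f2$seqs, residues))
})

test_that("the ancestor meets the family architecture and GC plan", {
  fx <- family_fixture()
  anc <- fx$anc
  expect_true(abs(seqLength(anc$seq) - 6200) <= 60)
  reg <- anc$truth$regions
  for (nm in c("F_block", "central", "R_block")) {
    r <- reg[reg$name == nm, ]
    gc <- regionGC(anc$seq, r$start, r$end) / 100
    expect_lt(abs(gc - r$gc_target), 0.021, )
  }
  # seven core ORFs recovered by the annotation module at the truth coordinates
  orfs <- findOrfs(anc$seq)
  tr <- anc$truth$genes
  for (i in seq_len(nrow(tr))) {
    expect_true(any(orfs$start == tr$start[i] & orfs$end == tr$end[i] &
                      orfs$strand == tr$strand[i]), info = tr$name[i])
  }
  # planted literal elements are present verbatim
  el <- anc$truth$elements
  rbs <- el[el$name == "RBS_F3", ]
  expect_equal(subseqCirc(anc$seq, rbs$start, rbs$end), "GGAGGCGA")
  slip <- el[el$name == "SLIPPERY", ]
  expect_equal(subseqCirc(anc$seq, slip$start, slip$end, "-"), "GGGAAAC")
})

test_that("planted elements are switched off cleanly", {
  par <- familyParams()
  par$plant_elements <- FALSE
  anc <- generateAncestor(par, seed = 5)
  expect_null(anc$truth$elements)
  # without the planted instance, intergenic-positioned promoter hits are
  # at background level (usually none in the short head)
  hits <- scanIupac(anc$seq, "SRNNRNNNTTWW", strands = "both")
  head_hits <- hits[hits$start <= 44, ]
  expect_lte(nrow(head_hits), 1L)
})

test_that("zero-length branches give identical leaves; defaults give two tiers", {
  fx <- family_fixture()
  par <- familyParams()
  par$tree <- "((A:0,B:0):0,(C:0,D:0):0,E:0);"
  par$indel_rate <- 0; par$insertion <- FALSE; par$pseudogene <- FALSE
  fam0 <- evolveFamily(fx$anc, par, seed = 3)
  for (id in names(fam0$seqs))
    expect_identical(residues(fam0$seqs[[id]]), residues(fx$anc$seq))
  # default conditions: F-block diverges less than the rest in every leaf
  real <- do.call(rbind, fx$fam$realized)
  expect_true(all(real[, "F_block"] < real[, "central"]))
  expect_true(all(real[, "F_block"] < real[, "R_block"]))
})

test_that("truth tables stay coordinate-consistent through indels and edits", {
  fx <- family_fixture()
  for (id in names(fx$fam$seqs)) {
    s <- fx$fam$seqs[[id]]
    tr <- fx$fam$truth[[id]]
    # protected literals are intact at their remapped coordinates
    el <- tr$elements
    rbs <- el[el$name == "RBS_F3", ]
    expect_equal(subseqCirc(s, rbs$start, rbs$end), "GGAGGCGA", info = id)
    slip <- el[el$name == "SLIPPERY", ]
    expect_equal(subseqCirc(s, slip$start, slip$end, "-"), "GGGAAAC", info = id)
    pirl <- el[el$name == "PIR_left", ]
    expect_equal(subseqCirc(s, pirl$start, pirl$end), "GCATTAGT", info = id)
    # gene boundaries carry start codons (except the interrupted R6)
    g <- tr$genes
    for (i in seq_len(nrow(g))) {
      mrna <- subseqCirc(s, g$start[i], g$end[i], g$strand[i])
      expect_true(substr(mrna, 1, 3) %in% c("ATG", "GTG"),
                  info = paste(id, g$name[i]))
    }
  }
})

test_that("read simulation is deterministic with the expected base yield", {
  fx <- family_fixture()
  p <- fx$fam$seqs[["A"]]
  r1 <- simulateReads(p, coverage = 10, read_len = 100, seed = 2)
  r2 <- simulateReads(p, coverage = 10, read_len = 100, seed = 2)
  expect_identical(r1, r2)
  total <- sum(nchar(r1$seq))
  expect_lt(abs(total - 10 * seqLength(p)) / (10 * seqLength(p)), 0.05)
  r3 <- simulateReads(p, coverage = 10, read_len = 100, seed = 3)
  expect_false(identical(r1$seq, r3$seq))
  expect_error(simulateReads(p, coverage = 10, read_len = 10000), "read_len")
  # error rate perturbs roughly error_rate of the bases
  r5 <- simulateReads(p, coverage = 5, read_len = 100, error_rate = 0, seed = 2)
  r4 <- simulateReads(p, coverage = 5, read_len = 100, error_rate = 0.05,
                      seed = 2)
  diffs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  r4$seq, r5$seq)
  expect_lt(abs(mean(diffs) / 100 - 0.05), 0.02)
})

test_that("spacer sets honor mutation settings and ship DR metadata", {
  fx <- family_fixture()
  ss <- makeSpacerSet(fx$fam$seqs, n_true = 4, n_decoy = 3, mutation_rate = 0,
                      seed = 8, genes = lapply(fx$fam$truth, function(t) t$genes))
  expect_equal(nrow(ss$spacers), 7L)
  expect_true(all(nchar(ss$spacers$spacer) >= 30 &
                    nchar(ss$spacers$spacer) <= 40))
  expect_true(all(!is.na(ss$spacers$DR)))
  # truth intervals reproduce the spacer strings exactly at mutation 0
  for (i in which(ss$truth$is_true)) {
    t <- ss$truth[i, ]
    expect_equal(ss$spacers$spacer[i],
                 subseqCirc(fx$fam$seqs[[t$plasmid_id]], t$start, t$end,
                            t$strand))
  }
  # FASTA round trip preserves sequence and DR tag
  tmp <- tempfile(fileext = ".fa")
  writeSpacers(ss$spacers, tmp)
  back <- readSpacers(tmp)
  expect_equal(back$spacer, ss$spacers$spacer)
  expect_equal(back$DR, ss$spacers$DR)
})
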