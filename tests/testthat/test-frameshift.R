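test_that("hairpin DP equals exhaustive stem enumeration on short sequences", {
  set.seed(41)
  for (r in 1:40) {
    x <- random_dna_str(sample(10:20, 1))
    expect_equal(hairpinDG(hairpinEnergy(x)), min(0, brute_hairpin(x)),
                 info = x)
  }
})

test_that("hairpin energetics behave physically", {
  forced <- hairpinEnergy("GGGGAAAACCCC")
  expect_equal(nrow(forced@stem_pairs), 4L)
  expect_lt(hairpinDG(forced), 0)
  # no self-complementarity, no hairpin
  none <- hairpinEnergy("AAAAAAAAAA")
  expect_equal(hairpinDG(none), 0)
  expect_equal(nrow(none@stem_pairs), 0L)
  # disrupting a stem base never stabilizes the best hairpin
  x <- "GGCGAGGCGACTTCAGTCGCCTCGCC"
  base <- hairpinDG(hairpinEnergy(x))
  mut <- x
  substr(mut, 3, 3) <- "A"   # inside the 5' stem arm
  expect_gte(hairpinDG(hairpinEnergy(mut)), base)
  expect_error(hairpinEnergy("ACGTACG"), "length")
})

test_that("slippery-site scan matches the X XXY YYZ pattern in frame", {
  # A AAA AAC planted so the heptamer starts at the last base of codon 2
  cds_seq <- paste0("ATG", "CCA", "AAA", "AAC", "CCC", "TAA")
  s <- circularSeq("fs", paste0(cds_seq, strrep("G", 100)), topology = "circular")
  cds <- data.frame(start = 1L, end = nchar(cds_seq), strand = "+")
  sites <- findSlipperySites(s, cds, max_deviation = 0)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$heptamer, "AAAAAAC")
  expect_equal(sites$mrna_pos, 6L)
  expect_equal(sites$start, 6L)
})

test_that("strict slippery heptamers occur at the closed-form background rate", {
  # P(strict site at an in-frame position) for uniform bases:
  # b2=b1, b3=b1 (1/16), b4 in {A,T} (1/2), b5=b4, b6=b4 (1/16), b7 != G (3/4)
  p <- (1 / 16) * (1 / 2) * (1 / 16) * (3 / 4)
  set.seed(42)
  reps <- 60L; n_cod <- 300L
  counts <- integer(reps)
  sense <- names(circplasmid:::.CODON_TABLE)[circplasmid:::.CODON_TABLE != "*"]
  for (r in seq_len(reps)) {
    cdsq <- paste0("ATG", paste(sample(sense, n_cod, TRUE), collapse = ""), "TAA")
    s <- circularSeq("b", paste0(cdsq, strrep("C", 60)))
    cds <- data.frame(start = 1L, end = nchar(cdsq), strand = "+")
    counts[r] <- nrow(findSlipperySites(s, cds, max_deviation = 0))
  }
  positions <- n_cod        # one in-frame heptamer anchor per codon, roughly
  expected <- positions * p
  sigma <- sqrt(positions * p / reps)   # Poisson-scale error of the mean
  expect_lt(abs(mean(counts) - expected), 4 * sigma + 0.05)
})

test_that("the planted R6 slippery site and stem-loop are detected in every leaf", {
  fx <- family_fixture()
  for (id in names(fx$fam$seqs)) {
    tr <- fx$fam$truth[[id]]
    r6 <- tr$genes[tr$genes$name == "R6", ]
    slip <- tr$elements[tr$elements$name == "SLIPPERY", ]
    sites <- findSlipperySites(fx$fam$seqs[[id]],
                               data.frame(start = r6$start, end = r6$end,
                                          strand = "-"), max_deviation = 0)
    hit <- sites[sites$start == slip$start & sites$end == slip$end, ]
    expect_equal(nrow(hit), 1L, info = id)
    if (nrow(hit) == 1L) {
      expect_lt(hit$dG, -12)               # stable planted stem-loop
      expect_lte(hit$hairpin_distance, 12L)
    }
  }
})

test_that("internal stops are located exactly on both strands", {
  # plus strand: stop TGA at codon 3 of a 6-codon CDS
  s <- circularSeq("st", paste0("ATGAAATGACCCAAATAA", strrep("C", 50)),
                   topology = "circular")
  st <- internalStops(s, data.frame(start = 1L, end = 18L, strand = "+"))
  expect_equal(st$codon, 3L)
  expect_equal(c(st$start, st$end), c(7L, 9L))
  # reverse strand: same CDS on the minus strand
  rc <- circplasmid:::.revcomp(paste0("ATGAAATGACCCAAATAA"))
  s2 <- circularSeq("st2", paste0(strrep("C", 50), rc))
  st2 <- internalStops(s2, data.frame(start = 51L, end = 68L, strand = "-"))
  expect_equal(st2$codon, 3L)
  expect_equal(st2$end - st2$start, 2L)
})

test_that("a single deleted base is recovered by insertion rescue at its site", {
  set.seed(43)
  sense <- names(circplasmid:::.CODON_TABLE)[circplasmid:::.CODON_TABLE != "*"]
  for (r in 1:10) {
    n_cod <- 150L
    clean <- paste0("ATG", paste(sample(sense, n_cod, TRUE), collapse = ""), "TAA")
    del_at <- sample(10:(nchar(clean) - 60L), 1)
    broken <- paste0(substr(clean, 1, del_at - 1),
                     substr(clean, del_at + 1, nchar(clean)))
    s <- circularSeq("br", paste0(broken, strrep("C", 60)))
    cds <- data.frame(start = 1L, end = nchar(broken), strand = "+")
    if (!nrow(internalStops(s, cds))) next  # rare: frameshift hits no stop
    res <- rescueOrfByInsertion(s, cds, consensus_len = n_cod + 1L)
    expect_true(nrow(res) > 0L, info = r)
    expect_true(min(abs(res$after_mrna_pos - del_at)) <= 4L, info = r)
    expect_true(all(abs(res$restored_len - (n_cod + 1L)) <= (n_cod + 1L) * 0.1))
  }
  # a clean gene yields an empty result with a note
  clean <- paste0("ATG", paste(sample(sense, 60, TRUE), collapse = ""), "TAA")
  s <- circularSeq("cl", paste0(clean, strrep("C", 60)))
  out <- rescueOrfByInsertion(s, data.frame(start = 1L, end = nchar(clean),
                                            strand = "+"))
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "note"), "no internal stop")
})

test_that("the planted R6 pseudogene rescues near the planted deletion", {
  fx <- family_fixture()
  id <- "D"   # pseudogene leaf under default conditions
  tr <- fx$fam$truth[[id]]
  ev <- tr$events
  del <- ev[ev$type == "pseudogene_del", ]
  expect_equal(nrow(del), 1L)
  r6 <- tr$genes[tr$genes$name == "R6", ]
  cds <- data.frame(start = r6$start, end = r6$end, strand = "-")
  expect_gt(nrow(internalStops(fx$fam$seqs[[id]], cds)), 0L)
  res <- rescueOrfByInsertion(fx$fam$seqs[[id]], cds, consensus_len = 278L)
  expect_gt(nrow(res), 0L)
  expect_lte(min(abs(res$plus_pos - del$pos)), 8L)
  expect_true(278L %in% res$restored_len)
})
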