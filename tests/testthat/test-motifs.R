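test_that("scanIupac equals brute-force degenerate matching on random sequences", {
  set.seed(31)
  for (r in 1:20) {
    x <- circularSeq("t", random_dna_str(sample(60:200, 1)))
    for (pat in c("SRNNRNNNTTWW", "GGAGGTGA", "WWYR")) {
      got <- scanIupac(x, pat, strands = "+")$start
      expect_equal(sort(as.integer(got)), sort(brute_iupac_scan(residues(x), pat)),
                   info = paste(seqId(x), pat, r))
    }
  }
  x <- circularSeq("n", "ACGTACGT")
  expect_equal(nrow(scanIupac(x, "NN", strands = "+")), 8L)  # every position
  expect_error(scanIupac(x, "AXG"), "invalid IUPAC")
})

test_that("reverse-strand hits are the plus-strand hits of the reverse complement", {
  set.seed(32)
  x <- circularSeq("t", random_dna_str(300))
  pat <- "SRNNRNNNTTWW"
  minus <- scanIupac(x, pat, strands = "-")
  rc <- circularSeq("rc", circplasmid:::.revcomp(residues(x)))
  plus_rc <- scanIupac(rc, pat, strands = "+")
  # a minus-strand footprint [s, e] corresponds to [n-e+1, n-s+1] on the rc
  n <- seqLength(x)
  got <- sort(((n - minus$end + 1L) - 1L) %% n + 1L)
  expect_equal(got, sort(plus_rc$start))
})

test_that("background promoter-motif counts match the closed-form expectation", {
  # per-position match probability of SRNNRNNNTTWW at 40% GC:
  # S=0.4, R=0.5, W=0.6, T=0.3 (positions independent)
  p <- 0.4 * 0.5 * 0.5 * 0.3 * 0.3 * 0.6 * 0.6
  set.seed(33)
  n <- 1000L; reps <- 40L
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    x <- circularSeq("b", random_dna_str(n, gc = 0.4))
    counts[r] <- nrow(scanIupac(x, "SRNNRNNNTTWW", strands = "+"))
  }
  expected <- n * p
  sigma <- sqrt(n * p * (1 - p) / reps)
  expect_lt(abs(mean(counts) - expected), 3 * sigma + 1e-9)
  # a planted instance is always recovered
  inst <- "CGTAGACCTTAT"   # matches the consensus
  x <- circularSeq("pl", paste0(random_dna_str(500, gc = 0.4), inst,
                                random_dna_str(488, gc = 0.4)))
  hits <- scanIupac(x, "SRNNRNNNTTWW", strands = "+")
  expect_true(501 %in% hits$start)
})

test_that("findRbs reports the planted motif with the documented offset convention", {
  set.seed(34)
  # exact GGAGGTGA ending 5 nt before the start codon => offset 5
  filler <- strrep("C", 60)
  s <- circularSeq("r", paste0(filler, "GGAGGTGA", "CCCCC", "ATG",
                               random_dna_str(100, 0.5)))
  gene <- data.frame(start = 74L, end = 120L, strand = "+")
  hit <- findRbs(s, gene)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$offset, 5L)
  # no upstream similarity -> NULL
  s2 <- circularSeq("r2", paste0(strrep("C", 80), "ATG", random_dna_str(60)))
  expect_null(findRbs(s2, data.frame(start = 81L, end = 120L, strand = "+")))
  # the planted family RBS: GGAGGCGA (one mismatch to consensus) 4 nt
  # upstream of every F3 start
  fx <- family_fixture()
  for (id in names(fx$fam$seqs)) {
    tr <- fx$fam$truth[[id]]$genes
    f3 <- tr[tr$name == "F3", ]
    hit <- findRbs(fx$fam$seqs[[id]],
                   data.frame(start = f3$start, end = f3$end, strand = "+"))
    expect_false(is.null(hit))
    expect_equal(hit$offset, 4L, info = id)
    expect_equal(hit$mismatches, 1L, info = id)
  }
})

test_that("inverted repeats: planted palindrome found; null rate is 4^-arm scale", {
  s <- circularSeq("ir", paste0(strrep("C", 20), "AAGGCC", "TTTT", "GGCCTT",
                                strrep("G", 20)))
  ir <- findInvertedRepeats(s, region = c(15, 56), min_arm = 4, max_loop = 10)
  expect_gte(nrow(ir), 1L)
  top <- ir[1, ]
  # maximal arms may extend past the planted 6-mers into lucky flanking
  # pairings; the planted repeat must be contained in the top hit
  expect_gte(top$arm, 6L)
  expect_lte(top$loop, 6L)
  expect_equal(top$mismatches, 0L)
  expect_lte(top$left_start, 21L)
  expect_gte(top$right_end, 36L)
  # null: arm-8 exact inverted repeats are rare in random sequence
  set.seed(35)
  hits <- 0L
  for (r in 1:40) {
    x <- circularSeq("n", random_dna_str(300))
    hits <- hits + nrow(findInvertedRepeats(x, min_arm = 8, max_loop = 10,
                                            max_mismatch = 0))
  }
  # ~300 positions x ~10 loops x 4^-8 per arm pair => << 1 expected per seq
  expect_lt(hits / 40, 1)
})

test_that("the planted R4-proximal inverted repeat is recovered at its center", {
  fx <- family_fixture()
  for (id in names(fx$fam$seqs)) {
    s <- fx$fam$seqs[[id]]
    tr <- fx$fam$truth[[id]]$genes
    r4 <- tr[tr$name == "R4", ]
    reg <- c((r4$end %% seqLength(s)) + 1L, 44L)
    ir <- findInvertedRepeats(s, region = reg, min_arm = 4, max_loop = 20)
    expect_true(nrow(ir) >= 1L, info = id)
    center <- (ir$left_start[1] + ir$right_end[1]) / 2
    # center relative to the R4 start (positions past the origin)
    expect_gte(center, 14); expect_lte(center, 27)
    expect_gte(ir$at_motif[1], 4L)
  }
})

test_that("CIS detection finds conserved intergenic islands and nothing else", {
  fx <- family_fixture()
  msa <- progressiveMsa(fx$fam$seqs)
  genes <- lapply(names(fx$fam$seqs), function(id) {
    tr <- fx$fam$truth[[id]]$genes
    data.frame(start = tr$start, end = tr$end, strand = tr$strand,
               family = tr$name, stringsAsFactors = FALSE)
  })
  names(genes) <- names(fx$fam$seqs)
  cis <- detectCis(msa, genes, fx$fam$seqs)
  expect_gte(nrow(cis), 3L)
  expect_true(all(cis$mean_conservation >= 0.9))
  # the planted islands are all represented (reference = plasmid A)
  ref_tr <- fx$fam$truth$A$elements
  for (nm in c("CIS_I", "CIS_III", "CIS_IV", "CIS_V")) {
    el <- ref_tr[ref_tr$name == nm, ]
    cover <- any(!is.na(cis$A_start) & cis$A_start <= el$start + 5 &
                   cis$A_end >= el$end - 5)
    expect_true(cover, info = nm)
  }
  # input order invariance
  cis2 <- detectCis(progressiveMsa(fx$fam$seqs), genes, fx$fam$seqs)
  expect_equal(cis$col_start, cis2$col_start)
})

test_that("positional filtering keeps exactly the promoters upstream of starts", {
  genes <- data.frame(start = c(200L), end = c(400L), strand = "+")
  hits <- data.frame(seq_id = "x", start = c(168L, 95L), end = c(179L, 106L),
                     strand = "+", type = "motif", family = NA,
                     attributes = "", mismatches = 0L)
  out <- promoterPositionalFilter(hits, genes, 1000L, center_range = c(-30, -20))
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 168L)   # center 173 => -27 from start 200
  # the planted overlapping promoter pair survives on the synthetic family
  fx <- family_fixture()
  for (id in c("A", "E")) {
    s <- fx$fam$seqs[[id]]
    tr <- fx$fam$truth[[id]]$genes
    g <- data.frame(start = tr$start, end = tr$end, strand = tr$strand)
    hits <- scanIupac(s, "SRNNRNNNTTWW", strands = "both")
    kept <- promoterPositionalFilter(hits, g, seqLength(s),
                                     center_range = c(-30, -20))
    expect_true(any(kept$start == 13 & kept$strand == "+"), info = id)
    expect_true(any(kept$start == 17 & kept$strand == "-"), info = id)
  }
})
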