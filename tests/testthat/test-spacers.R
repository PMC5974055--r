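test_that("an exact spacer substring matches at full identity and exact interval", {
  set.seed(51)
  p <- circularSeq("p", random_dna_str(2000))
  sp <- data.frame(id = "s1", spacer = subseqCirc(p, 501, 536), DR = NA)
  m <- matchSpacers(sp, list(p))
  expect_gte(nrow(m), 1L)
  expect_equal(m$identity[1], 100)
  expect_equal(c(m$start[1], m$end[1]), c(501L, 536L))
  expect_equal(m$strand[1], "+")
})

test_that("matching is strand-symmetric under reverse complement", {
  set.seed(52)
  p <- circularSeq("p", random_dna_str(2000))
  sp_f <- data.frame(id = "f", spacer = subseqCirc(p, 901, 936), DR = NA)
  sp_r <- data.frame(id = "r",
                     spacer = circplasmid:::.revcomp(sp_f$spacer), DR = NA)
  mf <- matchSpacers(sp_f, list(p)); mr <- matchSpacers(sp_r, list(p))
  expect_equal(c(mf$start[1], mf$end[1]), c(mr$start[1], mr$end[1]))
  expect_false(mf$strand[1] == mr$strand[1])
  expect_equal(mf$identity[1], mr$identity[1])
})

test_that("local alignment scores equal a Smith-Waterman oracle on short inputs", {
  set.seed(53)
  sc <- circplasmid:::.SPACER_SCORING
  nscore <- function(x, y) if (x == y) sc$match else sc$mismatch
  mat <- circplasmid:::.nuc_matrix(sc$match, sc$mismatch)
  for (r in 1:40) {
    a <- random_dna_str(sample(15:40, 1)); b <- random_dna_str(sample(15:40, 1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = sc$gap_open,
      gapExtension = sc$gap_extend, type = "local")
    expect_equal(Biostrings::score(pa),
                 sw_local(a, b, nscore, sc$gap_open, sc$gap_extend),
                 info = paste(a, b))
  }
})

test_that("the printed spacer/protospacer pair aligns to its brute-force optimum", {
  spacer <- "TTTTGGTTGTGTGCCCTTAGGCACACCTCTAACGGG"
  target <- "TTTTGATGTTGTGCCCTTAGGCACACCCCTAACAGC"
  p <- circularSeq("pl", paste0(random_dna_str(120, 0.5), target,
                                random_dna_str(120, 0.5)))
  set.seed(54)
  m <- matchSpacers(data.frame(id = "sp", spacer = spacer, DR = NA), list(p),
                    min_len = 25, min_identity = 65)
  expect_gte(nrow(m), 1L)
  sc <- circplasmid:::.SPACER_SCORING
  nscore <- function(x, y) if (x == y) sc$match else sc$mismatch
  expect_equal(m$score[1],
               sw_local(spacer, residues(p), nscore, sc$gap_open, sc$gap_extend))
  # aligned identical positions match the brute-force optimal local alignment
  qa <- strsplit(m$spacer_aln[1], "")[[1]]
  ta <- strsplit(m$target_aln[1], "")[[1]]
  expect_gte(sum(qa == ta & qa != "-"), 28)
})

test_that("translated comparison reads the gene frame and renders stops", {
  # the published F3 protospacer translations differ at a single residue
  spacer <- "CCACCGCCTCCCCGTGGAGTGTAAGCACTACTACGA"
  target_seg <- "TCATCAACTCCCCGTCGAGTGCAAGCACTACTATGC"
  expect_equal(circplasmid:::.translate(substr(target_seg, 2, 34)),
               "HQLPVECKHYY")
  expect_equal(circplasmid:::.translate(substr(spacer, 2, 34)),
               "HRLPVECKHYY")
  # spacer spanning a stop/start junction shows the stop symbol
  sense <- names(circplasmid:::.CODON_TABLE)[circplasmid:::.CODON_TABLE != "*"]
  set.seed(55)
  g1 <- paste0("ATG", paste(sample(sense, 30, TRUE), collapse = ""), "TAA")
  g2 <- paste0("ATG", paste(sample(sense, 30, TRUE), collapse = ""), "TAA")
  p <- circularSeq("j", paste0(strrep("C", 50), g1, "CC", g2, strrep("C", 50)))
  genes <- data.frame(start = c(51L, 51L + nchar(g1) + 2L),
                      end = c(50L + nchar(g1), 50L + nchar(g1) + 2L + nchar(g2)),
                      strand = "+", family = c("A", "B"))
  # spacer covering the end of g1 and start of g2, in g1's frame
  sp_seq <- subseqCirc(p, 50L + nchar(g1) - 17L, 50L + nchar(g1) + 17L)
  m <- matchSpacers(data.frame(id = "jx", spacer = sp_seq, DR = NA), list(p),
                    min_len = 30, min_identity = 95)
  expect_equal(nrow(m), 1L)
  tc <- translateCompare(m[1, ], list(j = p), genes)
  expect_match(tc$target_aa, "\\*")
  expect_equal(tc$spacer_aa, tc$target_aa)  # identical nucleotide match
})

test_that("decoy spacers stay below the calibrated false-positive level", {
  fx <- family_fixture()
  ss <- makeSpacerSet(fx$fam$seqs, n_true = 0, n_decoy = 120, seed = 56)
  m <- matchSpacers(ss$spacers, fx$fam$seqs)
  # <= 1% of spacer-plasmid comparisons may fire at default thresholds
  expect_lte(nrow(unique(m[, c("spacer_id", "plasmid_id")])),
             ceiling(0.01 * 120 * length(fx$fam$seqs)) + 2)
  # unmutated gene-region spacers are always recovered
  ss2 <- makeSpacerSet(fx$fam$seqs, n_true = 6, n_decoy = 0, seed = 57,
                       genes = lapply(fx$fam$truth, function(t) t$genes))
  m2 <- matchSpacers(ss2$spacers, fx$fam$seqs)
  expect_setequal(unique(m2$spacer_id), ss2$spacers$id)
  perfect <- m2[m2$identity == 100, ]
  expect_setequal(unique(perfect$spacer_id), ss2$spacers$id)
})
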