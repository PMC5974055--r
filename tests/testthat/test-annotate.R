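test_that("findOrfs calls simple ORFs and honors min_aa and start set", {
  lin <- circularSeq("l", "ATGAAATAG", topology = "linear")
  orfs <- findOrfs(lin, min_aa = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, 9L)
  # no start codon -> nothing
  none <- circularSeq("n", "CCCCCCTAGCCCCCC", topology = "linear")
  expect_equal(nrow(findOrfs(none, min_aa = 2)), 0L)
  # GTG start honored only when requested
  g <- circularSeq("g", "GTGAAATAGCCC", topology = "linear")
  expect_equal(nrow(findOrfs(g, min_aa = 2, starts = "ATG")), 0L)
  expect_equal(findOrfs(g, min_aa = 2)$start_codon, "GTG")
})

test_that("ORF calls are rotation-invariant on circular sequences", {
  fx <- family_fixture()
  s <- fx$anc$seq
  base <- sort(findOrfs(s, min_aa = 50)$protein)
  set.seed(11)
  for (k in sample(seqLength(s), 3)) {
    rot <- findOrfs(rotate(s, k), min_aa = 50)
    expect_equal(sort(rot$protein), base)
  }
})

test_that("origin-spanning ORFs are reported with end < start and translate correctly", {
  set.seed(12)
  # a gene of 42 codons placed across the origin; the filler has no A/T so
  # it can contribute neither starts nor stops
  codons <- names(circplasmid:::.CODON_TABLE)
  sense <- codons[circplasmid:::.CODON_TABLE != "*" &
                    !codons %in% c("ATG", "GTG")]
  gene <- paste0("ATG", paste(sample(sense, 40, TRUE), collapse = ""), "TAA")
  filler <- strrep("C", 200)
  s_lin <- paste0(substr(gene, 60, nchar(gene)), filler, substr(gene, 1, 59))
  s <- circularSeq("w", s_lin)
  orfs <- findOrfs(s, min_aa = 30)
  wrap <- orfs[orfs$end < orfs$start, ]
  expect_gte(nrow(wrap), 1L)
  expect_equal(wrap$protein[1], circplasmid:::.translate(
    substr(gene, 1, nchar(gene) - 3)))
})

test_that("operon detection groups overlapping and closely spaced genes", {
  genes <- data.frame(start = c(100L, 397L, 1000L), end = c(400L, 700L, 1300L),
                      strand = "+", stringsAsFactors = FALSE)
  out <- detectOperons(genes, gap_max = 30)
  expect_equal(out$operon[1], out$operon[2])   # 4-nt overlap
  expect_false(out$operon[3] == out$operon[1]) # 299-nt gap
  # the planted forward block forms one 3-gene operon
  fx <- family_fixture()
  tr <- fx$anc$truth$genes
  fwd <- tr[tr$strand == "+", c("start", "end", "strand")]
  grp <- detectOperons(fwd, seq_length = seqLength(fx$anc$seq))
  expect_length(unique(grp$operon), 1L)
})

test_that("filterNestedOrfs keeps the longest call per locus and drops nesting", {
  genes <- data.frame(
    seq_id = "p", start = c(100L, 120L, 397L, 150L, 900L),
    end = c(400L, 250L, 700L, 420L, 980L),
    strand = c("+", "+", "+", "-", "-"), type = "CDS",
    family = NA_character_, attributes = "",
    length_aa = c(100L, 43L, 101L, 90L, 26L), stringsAsFactors = FALSE)
  kept <- filterNestedOrfs(genes, 2000L)
  # nested (120-250) and heavily antisense-overlapping (150-420) calls drop;
  # the 1-nt stop/start overlap of an operon pair is retained
  expect_equal(kept$start, c(100L, 397L, 900L))
  # length-ranked greediness: when two calls overlap, the longer wins
  two <- genes[c(1, 4), ]
  two$length_aa <- c(50L, 90L)
  expect_equal(filterNestedOrfs(two, 2000L)$start, 150L)
  # origin-spanning footprints are handled
  wrap <- data.frame(seq_id = "p", start = c(1900L, 10L), end = c(50L, 60L),
                     strand = "+", type = "CDS", family = NA_character_,
                     attributes = "", length_aa = c(50L, 17L),
                     stringsAsFactors = FALSE)
  expect_equal(filterNestedOrfs(wrap, 2000L)$start, 1900L)
})

test_that("protein statistics: pI bisection finds the unique charge root", {
  polyk <- proteinStats(strrep("K", 20))
  expect_gt(polyk$pI, 9)
  polyd <- proteinStats(strrep("D", 20))
  expect_lt(polyd$pI, 4)
  expect_error(proteinStats("MKXL"), "unknown residue")
  set.seed(13)
  for (r in 1:10) {
    p <- random_protein_str(sample(30:200, 1))
    st <- proteinStats(p)
    counts <- table(factor(strsplit(p, "")[[1]],
                           levels = c("K", "R", "H", "D", "E", "C", "Y")))
    expect_lt(abs(circplasmid:::.net_charge(st$pI, counts)), 1e-4)
    # monotone decreasing charge in pH
    expect_gt(circplasmid:::.net_charge(st$pI - 1, counts),
              circplasmid:::.net_charge(st$pI + 1, counts))
  }
})

test_that("protein identity is 100 for identical inputs and symmetric", {
  set.seed(14)
  for (r in 1:5) {
    a <- random_protein_str(60); b <- random_protein_str(60)
    expect_equal(pairwiseProteinIdentity(a, a), 100)
    expect_equal(pairwiseProteinIdentity(a, b), pairwiseProteinIdentity(b, a))
  }
  a <- random_protein_str(80)
  rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  expect_lt(pairwiseProteinIdentity(a, rev_a), 40)
})

test_that("family assignment recovers the seven core families with synteny labels", {
  fx <- family_fixture()
  genes <- lapply(fx$fam$seqs, findOrfs)
  fam <- assignFamilies(genes)
  ev <- fam$evidence
  core <- ev[ev$family %in% c("F1", "F2", "F3", "R4", "R5", "R6", "R7"), ]
  expect_setequal(core$family, c("F1", "F2", "F3", "R4", "R5", "R6", "R7"))
  # forward families are present in all plasmids; reverse families may lose
  # at most one member (the interrupted R6 fragment of the pseudogene leaf
  # can fall below the clustering length ratio)
  expect_true(all(core$n_plasmids[core$strand == "+"] == 5L))
  expect_true(all(core$n_plasmids[core$strand == "-"] >= 4L))
  # strand blocks respect the family architecture
  expect_true(all(core$strand[core$family %in% c("F1", "F2", "F3")] == "+"))
  expect_true(all(core$strand[core$family %in% c("R4", "R5", "R6", "R7")] == "-"))
  # synteny order along the consensus coordinates
  pos <- core$pos[match(c("F1", "F2", "F3", "R7", "R6", "R5", "R4"), core$family)]
  expect_true(all(diff(pos) > 0))
  # the strain-specific insertion does not join a core family
  kept <- fam$genes[fam$genes$kept & fam$genes$plasmid == "C", ]
  tr <- fx$fam$truth$C$genes
  ins <- tr[tr$name == "inserted_methylase", ]
  hit <- kept[kept$start <= ins$start & kept$end >= ins$end - 3L &
                kept$strand == "+", ]
  if (nrow(hit)) expect_true(all(hit$family %in% c("other", NA)))
})

test_that("family assignment is invariant to plasmid input order", {
  fx <- family_fixture()
  genes <- lapply(fx$fam$seqs, findOrfs)
  f1 <- assignFamilies(genes)
  f2 <- assignFamilies(rev(genes))
  lab1 <- f1$genes[f1$genes$kept, c("plasmid", "start", "family")]
  lab2 <- f2$genes[f2$genes$kept, c("plasmid", "start", "family")]
  lab1 <- lab1[order(lab1$plasmid, lab1$start), ]
  lab2 <- lab2[order(lab2$plasmid, lab2$start), ]
  expect_equal(lab1, lab2, ignore_attr = TRUE)
})
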