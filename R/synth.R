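# Synthetic PL6-like plasmid families with known ground truth.
#
# The ancestor emulates the family's canonical architecture: a short
# intergenic head carrying a conserved island (CIS) with an overlapping,
# oppositely oriented promoter pair and an inverted repeat upstream of the
# R4 start; a high-GC forward block of three genes (F1-F3) with overlapping
# stop/start codons and an internal RBS 4 nt before the F3 start; an
# AT-rich central region with two further conserved islands; and a reverse
# block of four closely spaced genes (R4-R7) with a conserved island
# downstream of R6 and a slippery heptamer + stem-loop inside R6.

# fixed planted literals (verified stop-free in their reading frames)
.PLANT <- list(
  pir_left = "GCATTAGT",                 # AT-motif run of 4 inside the arm
  dual_promoter = "CGTAATAATTATGACG",    # + instance cols 1-12, - cols 5-16
  pir_right = "ACTAATGC",                # revcomp of pir_left
  rbs = "GGAGGCGA",                      # planted 4 nt upstream of F3 ATG
  slippery = "GGGAAAC",                  # G GGA AAC in the R6 zero frame
  hairpin = "GCGAGGCGACTTCAGTCGCCTCGC")  # 10 bp GC stem, 4 nt loop

#' Default parameters of the synthetic plasmid family
#'
#' The defaults emulate the study conditions of a five-member ~6.2-kb
#' family: protein sizes matching the core families (F1 99 aa, F2 297 aa,
#' F3 570 aa, R7 109 aa, R6 278 aa, R5 214 aa, R4 115 aa), a high-GC
#' (0.55) forward block, an AT-rich (0.42) central region, a moderately
#' GC-rich (0.51) reverse block, and a two-tier divergence structure (lower
#' substitution rate over the forward block) sized so that the family's
#' mean pairwise nucleotide identity falls in the observed 61-79% band with
#' forward-block similarity near 84% and the remainder near 54%. One leaf
#' receives an AT-rich methylase-like gene insertion and one leaf a
#' single-base deletion in R6 creating a premature stop.
#'
#' @param n_plasmids number of leaves (default 5; currently the default
#'   guide tree supports 5, a star tree is used otherwise).
#' @return named list of generator parameters.
#' @export
familyParams <- function(n_plasmids = 5L) {
  list(
    n_plasmids = as.integer(n_plasmids),
    aa_len = c(F1 = 99L, F2 = 297L, F3 = 570L,
               R7 = 109L, R6 = 278L, R5 = 214L, R4 = 115L),
    gc_f = 0.55, gc_central = 0.42, gc_r = 0.51,
    central_len = 1000L,
    tree = "((A:0.04,B:0.04):0.07,(C:0.06,D:0.06):0.06,E:0.12);",
    rate_f = 0.8, rate_rest = 3.1,
    third_pos_weight = 2.5,        # synonymous-position mutation bias
    indel_rate = 0.02,             # per free-zone nt per unit branch length
    indel_mean_len = 3,
    plant_elements = TRUE,
    insertion = TRUE, insertion_leaf = "C", insertion_gc = 0.38,
    insertion_aa = 330L,
    pseudogene = TRUE, pseudogene_leaf = "D",
    pseudogene_mrna_pos = 608L     # R6 mRNA position just 3' of the heptamer
  )
}

# sample n sense codons with independent base probabilities targeting gc
.sample_codons <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cod <- paste(sample(names(p), 3L, replace = TRUE, prob = p), collapse = "")
    if (!.is_stop(cod)) { out[i] <- cod; i <- i + 1L }
  }
  out
}

# build a gene: ATG + (aa_len - 1) sense codons + TGA
.make_gene <- function(aa_len, gc) {
  paste0("ATG", paste(.sample_codons(aa_len - 1L, gc), collapse = ""), "TGA")
}

#' Generate the ancestral synthetic plasmid
#'
#' Deterministic given `seed`. Regional GC is achieved by biased codon
#' sampling followed by a codon-resampling correction loop (tolerance
#' 2 GC points); planted regulatory elements are inserted at fixed,
#' recorded coordinates and are never altered by the correction.
#'
#' @param params from [familyParams()].
#' @param seed integer seed.
#' @return list with `seq` (a [CircularSeq-class]) and `truth` (gene,
#'   element and region coordinate tables plus the protection mask).
#' @export
generateAncestor <- function(params = familyParams(), seed = 1L) {
  set.seed(seed)
  aa <- params$aa_len
  P <- .PLANT
  # --- forward gene block with overlapping stop/starts ---------------------
  f1 <- .make_gene(aa[["F1"]], params$gc_f)
  f2 <- .make_gene(aa[["F2"]], params$gc_f)
  f3 <- .make_gene(aa[["F3"]], params$gc_f)
  head_len <- 44L
  f1_start <- head_len + 1L                       # 45
  f1_end <- f1_start + nchar(f1) - 1L
  f2_start <- f1_end                              # ATG shares the stop's A
  f2_end <- f2_start + nchar(f2) - 1L
  f3_start <- f2_end
  f3_end <- f3_start + nchar(f3) - 1L
  # assemble F block: f2 overlaps f1's last base, f3 overlaps f2's last base
  fblock <- paste0(f1, substr(f2, 2L, nchar(f2)), substr(f3, 2L, nchar(f3)))
  # stop/start overlap works because .make_gene ends TGA and begins ATG:
  # ...TGA|TG... reads TGA (stop) and ATG sharing the A
  # --- central AT-rich region ---------------------------------------------
  central <- .random_dna(params$central_len, params$gc_central)
  # --- reverse gene block --------------------------------------------------
  r7 <- .make_gene(aa[["R7"]], params$gc_r)
  r6 <- .make_gene(aa[["R6"]], params$gc_r)
  r5 <- .make_gene(aa[["R5"]], params$gc_r)
  r4 <- .make_gene(aa[["R4"]], params$gc_r)
  # each reverse gene's immediate upstream gap begins "TTA" (read TAA, an
  # in-frame stop, on the gene strand) so annotated starts cannot drift
  # upstream through the gap
  gap1 <- paste0("TTA", .random_dna(31L, params$gc_r))
  gap2 <- paste0("TTA", .random_dna(27L, params$gc_r))
  gap3 <- paste0("TTA", .random_dna(27L, params$gc_r))
  # head positions 1-3 read TAA on the reverse strand (guards the R4 start,
  # whose upstream region wraps into the head) and positions 42-44 carry a
  # plus-strand TAA in the F1 frame (guards the F1 start against the
  # in-frame ATG inside the right PIR arm); without planted elements the
  # regulatory literals are replaced by plain background
  head <- if (params$plant_elements) {
    paste0("TTAC", P$pir_left, P$dual_promoter, P$pir_right, "CGCGGTAA")
  } else {
    paste0("TTAC", .random_dna(32L, 0.5), "CGCGGTAA")
  }
  s <- paste0(head, fblock, central,
              .revcomp(r7), gap1, .revcomp(r6), gap2, .revcomp(r5), gap3,
              .revcomp(r4))
  n <- nchar(s)
  # --- coordinates ---------------------------------------------------------
  central_start <- f3_end + 1L
  central_end <- f3_end + params$central_len
  r7_start <- central_end + 1L; r7_end <- r7_start + nchar(r7) - 1L
  r6_start <- r7_end + 35L; r6_end <- r6_start + nchar(r6) - 1L
  r5_start <- r6_end + 31L; r5_end <- r5_start + nchar(r5) - 1L
  r4_start <- r5_end + 31L; r4_end <- r4_start + nchar(r4) - 1L
  stopifnot(r4_end == n)
  genes <- data.frame(
    name = c("F1", "F2", "F3", "R7", "R6", "R5", "R4"),
    start = c(f1_start, f2_start, f3_start, r7_start, r6_start, r5_start,
              r4_start),
    end = c(f1_end, f2_end, f3_end, r7_end, r6_end, r5_end, r4_end),
    strand = c("+", "+", "+", "-", "-", "-", "-"),
    length_aa = as.integer(aa[c("F1", "F2", "F3", "R7", "R6", "R5", "R4")]),
    stringsAsFactors = FALSE)
  # start guards inside the forward operon: a stop codon in the frame of
  # the DOWNSTREAM gene, placed a few codons upstream of its start within
  # the upstream gene, pins the annotated start (the overwritten upstream
  # codons remain sense codons: they end in T or read GAx)
  s <- .str_assign(s, f2_start - 6L, f2_start - 3L, "TGAC")
  s <- .str_assign(s, f3_start - 15L, f3_start - 13L, "TGA")
  elements <- NULL
  if (params$plant_elements) {
    # RBS: motif 3' end 5 nt before the F3 ATG => 4 intervening nt; the
    # spacer is fixed too (no ATG/GTG in the F3 frame, no stop in the F2
    # frame) so the annotated F3 start cannot drift upstream
    rbs_end <- f3_start - 5L
    rbs_start <- rbs_end - nchar(P$rbs) + 1L
    s <- .str_assign(s, rbs_start, rbs_end, P$rbs)
    # the 4-nt spacer overlaps the F2 stop codon (the F2/F3 stop/start
    # overlap places that stop 2 nt before the F3 ATG): its last two bases
    # must stay "TG" so that ...TG|A(TG) still terminates F2, and the
    # leading "CT" keeps every F3-frame triplet here a non-start
    s <- .str_assign(s, rbs_end + 1L, f3_start - 1L, "CTTG")
    # left junction: if the motif's first G lands on a codon third position,
    # a preceding "TA" would read TAG; force the prefix to "CC" (proline)
    if ((rbs_start - f2_start) %% 3L == 2L &&
        substr(s, rbs_start - 2L, rbs_start - 1L) == "TA")
      s <- .str_assign(s, rbs_start - 2L, rbs_start - 1L, "CC")
    # slippery heptamer + hairpin inside R6 (mRNA coordinates 600 and 613)
    slip_mrna <- 600L
    hp_mrna <- slip_mrna + 13L
    slip_s <- r6_end - (slip_mrna + 6L) + 1L
    slip_e <- r6_end - slip_mrna + 1L
    s <- .str_assign(s, slip_s, slip_e, .revcomp(P$slippery))
    hp_s <- r6_end - (hp_mrna + nchar(P$hairpin) - 1L) + 1L
    hp_e <- r6_end - hp_mrna + 1L
    s <- .str_assign(s, hp_s, hp_e, .revcomp(P$hairpin))
    # guard: the codon whose third base is the heptamer's first G could have
    # become TAG; rewrite its first two bases if so
    cod_lo <- r6_end - slip_mrna + 1L     # plus coord of the codon's 3rd base
    cod <- subseqCirc(circularSeq("tmp", s), cod_lo, cod_lo + 2L, "-")
    if (.is_stop(cod))
      s <- .str_assign(s, cod_lo + 1L, cod_lo + 2L, .revcomp("GC"))
    # conserved islands in the central region and the R7-R6 gap
    cis3 <- c(central_start + 300L, central_start + 339L)
    cis4 <- c(central_start + 650L, central_start + 679L)
    cis5 <- c(r7_end + 5L, r7_end + 30L)
    elements <- data.frame(
      name = c("CIS_I", "PIR_left", "PROM_plus", "PROM_minus", "PIR_right",
               "RBS_F3", "RBS_spacer", "CIS_III", "CIS_IV", "CIS_V",
               "SLIPPERY", "HAIRPIN",
               "start_guard_F2", "start_guard_F3", "start_guard_R7",
               "start_guard_R6", "start_guard_R5"),
      start = c(5L, 5L, 13L, 17L, 29L, rbs_start, rbs_end + 1L, cis3[1L],
                cis4[1L], cis5[1L], slip_s, hp_s,
                f2_start - 6L, f3_start - 15L, r7_end + 1L, r6_end + 1L,
                r5_end + 1L),
      end = c(36L, 12L, 24L, 28L, 36L, rbs_end, f3_start - 1L, cis3[2L],
              cis4[2L], cis5[2L], slip_e, hp_e,
              f2_start - 3L, f3_start - 13L, r7_end + 3L, r6_end + 3L,
              r5_end + 3L),
      strand = c("+", "+", "+", "-", "+", "+", "+", "+", "+", "+", "-", "-",
                 "+", "+", "-", "-", "-"),
      stringsAsFactors = FALSE)
  }
  # --- regions and protection mask ----------------------------------------
  regions <- data.frame(
    name = c("head", "F_block", "central", "R_block"),
    start = c(1L, f1_start, central_start, r7_start),
    end = c(head_len, f3_end, central_end, n),
    gc_target = c(0.5, params$gc_f, params$gc_central, params$gc_r),
    stringsAsFactors = FALSE)
  protected <- logical(n)
  protected[1:head_len] <- TRUE                  # head incl. CIS I / PIR
  if (!is.null(elements)) {
    for (i in seq_len(nrow(elements)))
      protected[elements$start[i]:elements$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(genes))) {              # start + stop codons
    g <- genes[i, ]
    if (g$strand == "+") {
      protected[g$start:(g$start + 2L)] <- TRUE
      protected[(g$end - 2L):g$end] <- TRUE
    } else {
      protected[(g$end - 2L):g$end] <- TRUE
      protected[g$start:(g$start + 2L)] <- TRUE
    }
  }
  # --- GC correction loop (never touches protected positions) -------------
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars <- .tune_region_gc(chars, genes, regions, protected, tol = 0.02)
  s <- paste(chars, collapse = "")
  # sanity: all seven genes must translate without internal stops
  cs <- circularSeq("ancestor", s)
  for (i in seq_len(nrow(genes))) {
    prot <- .translate(subseqCirc(cs, genes$start[i], genes$end[i],
                                  genes$strand[i]))
    if (grepl("*", substr(prot, 1L, nchar(prot) - 1L), fixed = TRUE))
      stop("internal stop created in gene ", genes$name[i],
           " (infeasible GC target for gene constraints?)")
  }
  list(seq = cs,
       truth = list(genes = genes, elements = elements, regions = regions,
                    protected = protected))
}

# resample unprotected codons (genes) / flip bases (intergenic) until every
# region is within tol of its GC target; then homogenize within regions at
# window scale so the compositional boundaries between regions are as crisp
# as the profile transitions observed in real plasmids of this family
.tune_region_gc <- function(chars, genes, regions, protected, tol = 0.02,
                            window = 200L, window_tol = 0.02) {
  in_gene <- integer(length(chars))   # gene index or 0, for stop-avoidance
  for (g in seq_len(nrow(genes)))
    in_gene[genes$start[g]:genes$end[g]] <- g

  flip_span <- function(chars, span, target, tol, max_iter) {
    for (iter in seq_len(max_iter)) {
      gc <- mean(chars[span] %in% c("G", "C"))
      if (abs(gc - target) <= tol) break
      want_gc <- gc < target
      cand <- span[!protected[span]]
      if (want_gc) cand <- cand[chars[cand] %in% c("A", "T")]
      else cand <- cand[chars[cand] %in% c("G", "C")]
      if (!length(cand)) break
      needed <- ceiling(abs(gc - target) * length(span))
      flip <- cand[sample.int(length(cand),
                              min(needed, 25L, length(cand)))]
      for (p in flip) {
        newb <- if (want_gc) sample(c("G", "C"), 1L) else sample(c("A", "T"), 1L)
        old <- chars[p]
        chars[p] <- newb
        g <- in_gene[p]
        if (g > 0L) {
          # reject the flip if it creates a stop codon in the gene frame
          st <- genes$strand[g]
          off <- if (st == "+") (p - genes$start[g]) %% 3L
                 else (genes$end[g] - p) %% 3L
          c1 <- if (st == "+") p - off else p + off
          cod <- if (st == "+")
            paste(chars[c1:(c1 + 2L)], collapse = "")
          else .revcomp(paste(chars[(c1 - 2L):c1], collapse = ""))
          if (.is_stop(cod)) chars[p] <- old
        }
      }
    }
    chars
  }

  for (r in seq_len(nrow(regions))) {
    span <- regions$start[r]:regions$end[r]
    chars <- flip_span(chars, span, regions$gc_target[r], tol, 400L)
    # window-scale homogenization within the region
    if (length(span) < window) next
    starts <- unique(c(seq(regions$start[r], regions$end[r] - window + 1L,
                           by = window),
                       regions$end[r] - window + 1L))
    for (ws in starts) {
      wspan <- ws:min(ws + window - 1L, regions$end[r])
      chars <- flip_span(chars, wspan, regions$gc_target[r], window_tol, 40L)
    }
  }
  chars
}

# shift coordinate vector through an indel: insertion of `delta` nt after
# `pos` (delta > 0) or deletion of positions pos..pos-delta-1 (delta < 0)
.remap_coords <- function(coords, pos, delta) {
  if (delta > 0) ifelse(coords > pos, coords + delta, coords)
  else {
    del_end <- pos - delta - 1L
    ifelse(coords > del_end, coords + delta,
           ifelse(coords >= pos, NA_integer_, coords))
  }
}

.remap_truth <- function(truth, pos, delta) {
  for (tab in c("genes", "elements", "regions")) {
    t <- truth[[tab]]
    if (is.null(t)) next
    t$start <- .remap_coords(t$start, pos, delta)
    t$end <- .remap_coords(t$end, pos, delta)
    truth[[tab]] <- t
  }
  truth
}

#' Evolve a plasmid family from the ancestor along a guide tree
#'
#' Substitutions are applied per branch as independent per-site events
#' (Jukes-Cantor style: a hit site takes one of the other three bases) with
#' region-specific rates: the forward block evolves slowly (with extra
#' weight on synonymous third codon positions) and the central + reverse
#' regions quickly, reproducing the family's two-tier similarity structure.
#' Planted elements, start/stop codons and the intergenic head are
#' protected; substitutions that would create an in-frame stop are
#' redrawn. Indels (geometric lengths) are applied per leaf within free
#' intergenic zones only, so gene frames stay intact and all truth
#' coordinates are remapped exactly. One leaf optionally gains an AT-rich
#' methylase-like gene inside the central region, and one leaf a
#' single-base deletion in R6 that creates a premature stop (the
#' pseudogene / -1 frameshift scenario).
#'
#' @param ancestor result of [generateAncestor()].
#' @param params from [familyParams()].
#' @param seed integer seed.
#' @return list with `seqs` (named list of [CircularSeq-class]),
#'   `truth` (per-leaf coordinate tables incl. `events`), and
#'   `realized` (per-leaf, per-region substitution fractions).
#' @export
evolveFamily <- function(ancestor, params = familyParams(), seed = 1L) {
  set.seed(seed + 1L)
  tree <- ape::read.tree(text = params$tree)
  if (length(tree$tip.label) != params$n_plasmids) {
    tips <- LETTERS[seq_len(params$n_plasmids)]
    tree <- ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:0.12", tips), collapse = ","), ");"))
  }
  anc_chars <- strsplit(residues(ancestor$seq), "", fixed = TRUE)[[1L]]
  n <- length(anc_chars)
  truth0 <- ancestor$truth
  protected <- truth0$protected
  # per-site substitution weight
  fb <- truth0$regions[truth0$regions$name == "F_block", ]
  rate <- rep(params$rate_rest, n)
  rate[fb$start:fb$end] <- params$rate_f
  # third-codon-position (synonymous) weighting inside all genes; the mean
  # per-gene rate is preserved, so nucleotide-level divergence is unchanged
  w <- params$third_pos_weight %||% 2.5
  for (g in seq_len(nrow(truth0$genes))) {
    gn <- truth0$genes[g, ]
    third <- if (gn$strand == "+") seq(gn$start + 2L, gn$end, by = 3L)
             else seq(gn$end - 2L, gn$start, by = -3L)
    rate[gn$start:gn$end] <- rate[gn$start:gn$end] * 3 / (2 + w)
    rate[third] <- rate[third] * w
  }
  gene_frame <- .gene_frame_index(truth0$genes, n)

  mutate_branch <- function(chars, len) {
    p <- pmin(0.95, rate * len)
    hit <- which(stats::runif(n) < p & !protected)
    for (pos in hit) {
      for (try in 1:4) {
        newb <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
        old <- chars[pos]; chars[pos] <- newb
        if (!.creates_stop(chars, pos, gene_frame, truth0$genes)) break
        chars[pos] <- old
      }
    }
    chars
  }
  # evolve down the tree (node sequences in ancestor coordinates)
  ntip <- length(tree$tip.label)
  node_seq <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  node_seq[[root]] <- anc_chars
  po <- tree$edge
  done <- c(rep(FALSE, ntip), TRUE, rep(FALSE, tree$Nnode - 1L))
  repeat {
    progress <- FALSE
    for (e in seq_len(nrow(po))) {
      parent <- po[e, 1L]; child <- po[e, 2L]
      if (done[parent] && !done[child]) {
        node_seq[[child]] <- mutate_branch(node_seq[[parent]],
                                           tree$edge.length[e])
        done[child] <- TRUE; progress <- TRUE
      }
    }
    if (all(done)) break
    if (!progress) stop("guide tree traversal failed")
  }
  # leaf post-processing: realized divergence, indels, insertion, pseudogene
  seqs <- list(); truths <- list(); realized <- list()
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  free_zones <- .free_zones(truth0, n)
  for (i in seq_len(ntip)) {
    id <- tree$tip.label[i]
    chars <- node_seq[[i]]
    realized[[id]] <- vapply(seq_len(nrow(truth0$regions)), function(r) {
      span <- truth0$regions$start[r]:truth0$regions$end[r]
      mean(chars[span] != anc_chars[span])
    }, numeric(1L))
    names(realized[[id]]) <- truth0$regions$name
    truth <- truth0[c("genes", "elements", "regions")]
    truth$events <- data.frame(type = character(0), pos = integer(0),
                               length = integer(0))
    sstr <- paste(chars, collapse = "")
    # --- indels in free intergenic zones ---------------------------------
    fz <- free_zones
    n_indel <- stats::rpois(1L, params$indel_rate * sum(fz$end - fz$start + 1L) *
                              depths[i])
    for (k in seq_len(n_indel)) {
      z <- fz[sample.int(nrow(fz), 1L), ]
      len <- stats::rgeom(1L, 1 / params$indel_mean_len) + 1L
      if (stats::runif(1L) < 0.5) {             # insertion
        zr <- z$start:z$end
        pos <- zr[sample.int(length(zr), 1L)]
        ins <- .random_dna(len, 0.45)
        sstr <- paste0(substr(sstr, 1L, pos), ins,
                       substr(sstr, pos + 1L, nchar(sstr)))
        truth <- .remap_truth(truth, pos, len)
        fz$start <- .remap_coords(fz$start, pos, len)
        fz$end <- .remap_coords(fz$end, pos, len)
        truth$events <- rbind(truth$events,
                              data.frame(type = "ins", pos = pos, length = len))
      } else {                                  # deletion, kept inside zone
        len <- min(len, z$end - z$start)
        if (len < 1L) next
        zr <- z$start:(z$end - len + 1L)
        pos <- zr[sample.int(length(zr), 1L)]
        sstr <- paste0(substr(sstr, 1L, pos - 1L),
                       substr(sstr, pos + len, nchar(sstr)))
        truth <- .remap_truth(truth, pos, -len)
        fz$start <- .remap_coords(fz$start, pos, -len)
        fz$end <- .remap_coords(fz$end, pos, -len)
        fz <- fz[!is.na(fz$start) & !is.na(fz$end) & fz$start <= fz$end, ,
                 drop = FALSE]
        truth$events <- rbind(truth$events,
                              data.frame(type = "del", pos = pos, length = len))
      }
      if (!nrow(fz)) break
    }
    # --- strain-specific AT-rich gene insertion --------------------------
    if (isTRUE(params$insertion) && id == params$insertion_leaf) {
      gene <- .make_gene(params$insertion_aa, params$insertion_gc)
      # the 5' flank ends with an in-frame stop + non-start triplet so the
      # inserted gene's annotated start cannot drift into the flank
      flank5 <- paste0(.random_dna(34L, params$insertion_gc), "TAACTC")
      flank3 <- .random_dna(40L, params$insertion_gc)
      cassette <- paste0(flank5, gene, flank3)
      centr <- truth$regions[truth$regions$name == "central", ]
      pos <- centr$start + (centr$end - centr$start) %/% 2L
      # keep clear of the central conserved islands
      if (!is.null(truth$elements)) {
        cis <- truth$elements[truth$elements$name %in% c("CIS_III", "CIS_IV"), ]
        pos <- max(cis$end[1L] + 20L, min(pos, cis$start[2L] - 20L))
      }
      sstr <- paste0(substr(sstr, 1L, pos), cassette,
                     substr(sstr, pos + 1L, nchar(sstr)))
      truth <- .remap_truth(truth, pos, nchar(cassette))
      truth$genes <- rbind(truth$genes, data.frame(
        name = "inserted_methylase", start = pos + 41L,
        end = pos + 40L + nchar(gene), strand = "+",
        length_aa = params$insertion_aa, stringsAsFactors = FALSE))
      truth$events <- rbind(truth$events, data.frame(
        type = "gene_insertion", pos = pos, length = nchar(cassette)))
    }
    # --- premature stop in R6 by single-base deletion --------------------
    # the base is removed just downstream of the slippery heptamer (as at a
    # real -1 frameshift locus, where the heptamer stays in the zero frame
    # and the lesion interrupts the frame after it); if the frameshifted
    # tail happens to be stop-free, the next unprotected position is tried
    if (isTRUE(params$pseudogene) && id == params$pseudogene_leaf) {
      r6 <- truth$genes[truth$genes$name == "R6", ]
      cand <- c(params$pseudogene_mrna_pos + 0:4,     # heptamer..hairpin spacer
                params$pseudogene_mrna_pos + 29L + 0:40)  # past the hairpin
      for (off in cand) {
        del_pos <- r6$end - off + 1L
        trial <- paste0(substr(sstr, 1L, del_pos - 1L),
                        substr(sstr, del_pos + 1L, nchar(sstr)))
        mrna <- .revcomp(substr(trial, r6$start, r6$end - 1L))
        prot <- .translate(mrna)
        stop_at <- regexpr("*", prot, fixed = TRUE)
        if (stop_at > 0L && stop_at < nchar(prot)) {
          sstr <- trial
          truth <- .remap_truth(truth, del_pos, -1L)
          truth$events <- rbind(truth$events, data.frame(
            type = "pseudogene_del", pos = del_pos, length = 1L))
          break
        }
      }
    }
    seqs[[id]] <- circularSeq(id, sstr, "circular")
    truths[[id]] <- truth
  }
  list(seqs = seqs, truth = truths, realized = realized)
}

# free (unprotected, intergenic) zones usable for indels
.free_zones <- function(truth, n) {
  occupied <- truth$protected
  for (g in seq_len(nrow(truth$genes)))
    occupied[truth$genes$start[g]:truth$genes$end[g]] <- TRUE
  runs <- rle(!occupied)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  z <- data.frame(start = starts[runs$values], end = ends[runs$values])
  z[z$end - z$start + 1L >= 10L, , drop = FALSE]
}

.gene_frame_index <- function(genes, n) {
  idx <- integer(n)
  for (g in seq_len(nrow(genes)))
    idx[genes$start[g]:genes$end[g]] <- g
  idx
}

# does chars[pos] sit in a gene whose covering codon is now a stop?
.creates_stop <- function(chars, pos, gene_frame, genes) {
  g <- gene_frame[pos]
  if (g == 0L) return(FALSE)
  st <- genes$strand[g]
  off <- if (st == "+") (pos - genes$start[g]) %% 3L
         else (genes$end[g] - pos) %% 3L
  cod <- if (st == "+") {
    c1 <- pos - off
    paste(chars[c1:(c1 + 2L)], collapse = "")
  } else {
    c3 <- pos + off
    .revcomp(paste(chars[(c3 - 2L):c3], collapse = ""))
  }
  .is_stop(cod)
}

#' Simulate shotgun reads from a circular plasmid
#'
#' Uniform circular start positions on both strands; per-base substitution
#' errors at `error_rate`. Deterministic given `seed`.
#'
#' @param plasmid a [CircularSeq-class].
#' @param coverage mean fold coverage.
#' @param read_len read length (must not exceed the plasmid length).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return data.frame with `id`, `seq`, `start`, `strand`.
#' @export
simulateReads <- function(plasmid, coverage, read_len = 100L,
                          error_rate = 0, seed = 1L) {
  n <- seqLength(plasmid)
  if (read_len > n) stop("read_len exceeds plasmid length")
  if (coverage <= 0) stop("coverage must be > 0")
  set.seed(seed)
  n_reads <- round(coverage * n / read_len)
  starts <- sample.int(n, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- vapply(seq_len(n_reads), function(i) {
    e <- ((starts[i] + read_len - 2L) %% n) + 1L
    subseqCirc(plasmid, starts[i], e, strands[i])
  }, character(1L))
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(q) {
      hit <- which(stats::runif(read_len) < error_rate)
      if (!length(hit)) return(q)
      ch <- strsplit(q, "", fixed = TRUE)[[1L]]
      for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
      paste(ch, collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  data.frame(id = sprintf("%s_read%05d", seqId(plasmid), seq_len(n_reads)),
             seq = seqs, start = starts, strand = strands,
             stringsAsFactors = FALSE)
}

#' Generate a CRISPR spacer test set with ground truth
#'
#' True spacers are 30-40-nt substrings of gene regions, mutated per base
#' at `mutation_rate`; decoys are random sequences with the plasmids' mean
#' base composition. Direct-repeat strings are attached as metadata, as a
#' spacer-extraction tool would report them.
#'
#' @param plasmids named list of [CircularSeq-class].
#' @param n_true,n_decoy counts of genuine and decoy spacers.
#' @param mutation_rate per-base substitution probability on true spacers.
#' @param seed integer seed.
#' @param genes optional named list of gene tables (truth or [findOrfs()]);
#'   when given, true spacers are drawn from within gene footprints.
#' @return list: `spacers` (data.frame id, spacer, DR) and `truth`
#'   (data.frame spacer_id, plasmid_id, start, end, strand, is_true).
#' @export
makeSpacerSet <- function(plasmids, n_true = 5L, n_decoy = 20L,
                          mutation_rate = 0, seed = 1L, genes = NULL) {
  set.seed(seed)
  dr <- "GTTTCAGACGAACCCTTGTGGGGTTGAAGC"
  spacers <- NULL; truth <- NULL
  gc_mean <- mean(vapply(plasmids, function(p) regionGC(p) / 100, numeric(1L)))
  for (k in seq_len(n_true)) {
    p <- plasmids[[sample.int(length(plasmids), 1L)]]
    len <- sample(30:40, 1L)
    if (!is.null(genes) && !is.null(genes[[seqId(p)]]) &&
        nrow(genes[[seqId(p)]])) {
      g <- genes[[seqId(p)]][sample.int(nrow(genes[[seqId(p)]]), 1L), ]
      glen <- featureSpanLength(g$start, g$end, seqLength(p))
      if (glen > len + 2L) {
        rel <- sample.int(glen - len, 1L)
        start <- ((g$start + rel - 2L) %% seqLength(p)) + 1L
      } else start <- sample.int(seqLength(p), 1L)
    } else start <- sample.int(seqLength(p), 1L)
    end <- ((start + len - 2L) %% seqLength(p)) + 1L
    strand <- sample(c("+", "-"), 1L)
    sp <- subseqCirc(p, start, end, strand)
    if (mutation_rate > 0) {
      ch <- strsplit(sp, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(len) < mutation_rate)
      for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
      sp <- paste(ch, collapse = "")
    }
    id <- sprintf("true_sp%03d", k)
    spacers <- rbind(spacers, data.frame(id = id, spacer = sp, DR = dr,
                                         stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(spacer_id = id, plasmid_id = seqId(p),
                                     start = start, end = end, strand = strand,
                                     is_true = TRUE, stringsAsFactors = FALSE))
  }
  for (k in seq_len(n_decoy)) {
    len <- sample(30:40, 1L)
    id <- sprintf("decoy_sp%03d", k)
    spacers <- rbind(spacers, data.frame(
      id = id, spacer = .random_dna(len, gc_mean), DR = dr,
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(spacer_id = id, plasmid_id = NA_character_,
                                     start = NA_integer_, end = NA_integer_,
                                     strand = NA_character_, is_true = FALSE,
                                     stringsAsFactors = FALSE))
  }
  list(spacers = spacers, truth = truth)
}

#' Write a spacer set as FASTA with DR metadata
#'
#' @param spacers data.frame with `id`, `spacer`, `DR`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpacers <- function(spacers, path) {
  lines <- unlist(lapply(seq_len(nrow(spacers)), function(i) {
    hdr <- paste0(">", spacers$id[i])
    if (!is.na(spacers$DR[i])) hdr <- paste0(hdr, " DR=", spacers$DR[i])
    c(hdr, spacers$spacer[i])
  }))
  writeLines(lines, path)
  invisible(path)
}
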