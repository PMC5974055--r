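#' Find open reading frames on a circular replicon
#'
#' Calls complete CDS (start codon to stop codon) on both strands in all
#' three frames, including ORFs spanning the origin of a circular sequence.
#' Within one stop-bounded frame segment the longest ORF is reported and the
#' number of alternative (nested, downstream) start codons is recorded.
#' Coordinates are the plus-strand footprint of the CDS including the stop
#' codon; for a minus-strand gene the start codon therefore sits at the
#' footprint `end`. `end < start` marks an origin-spanning gene.
#'
#' Start codons default to ATG and GTG: in haloarchaea the vast majority of
#' (often leaderless) transcripts initiate at ATG, with GTG used by poorly
#' expressed genes; TTG is excluded by default but can be supplied.
#'
#' @param x a [CircularSeq-class].
#' @param min_aa minimum protein length in aa (default 30).
#' @param starts allowed start codons.
#' @param prefer_atg if `TRUE` (default), the longest ATG-initiated ORF of a
#'   stop-bounded frame segment is reported even when a GTG start would give
#'   a slightly longer one, reflecting the strong ATG-initiator preference
#'   of (largely leaderless) haloarchaeal transcripts; set `FALSE` to always
#'   report the longest ORF regardless of start codon.
#' @return data.frame with columns `seq_id, start, end, strand, type,
#'   family, attributes, protein, start_codon, n_alt_starts, length_aa`.
#' @export
findOrfs <- function(x, min_aa = 30L, starts = c("ATG", "GTG"),
                     prefer_atg = TRUE) {
  if (min_aa < 2L) stop("'min_aa' must be >= 2")
  n <- seqLength(x)
  circ <- topology(x) == "circular"
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues(x) else .revcomp(residues(x))
    s2 <- if (circ) paste0(s, s) else s
    m <- nchar(s2)
    # collect start/stop candidate pairs across all three frames; on a
    # circular sequence whose length is not a multiple of 3, the same
    # genomic stop appears in two frames of the doubled string, so
    # deduplication must use genomic stop coordinates, not frames
    cand_p1 <- integer(0L); cand_pstop <- integer(0L)
    cand_codon <- character(0L)
    for (f in 0:2) {
      pos <- seq(1L + f, m - 2L, by = 3L)
      cods <- substring(s2, pos, pos + 2L)
      stop_idx <- which(.is_stop(cods))
      start_idx <- which(cods %in% starts)
      if (!length(stop_idx) || !length(start_idx)) next
      nxt <- findInterval(start_idx, stop_idx) + 1L
      ok <- nxt <= length(stop_idx)
      start_idx <- start_idx[ok]; nxt <- nxt[ok]
      if (!length(start_idx)) next
      stop_for <- stop_idx[nxt]
      aa_len <- stop_for - start_idx
      keep <- aa_len >= min_aa &
        (pos[stop_for] + 2L - pos[start_idx] + 1L) <= n &
        pos[start_idx] <= n                     # first copy only
      cand_p1 <- c(cand_p1, pos[start_idx[keep]])
      cand_pstop <- c(cand_pstop, pos[stop_for[keep]])
      cand_codon <- c(cand_codon, cods[start_idx[keep]])
    }
    if (!length(cand_p1)) next
    g_stop <- ((cand_pstop - 1L) %% n) + 1L
    g_start_all <- ((cand_p1 - 1L) %% n) + 1L
    dup_key <- paste(g_stop, g_start_all)       # same genomic ORF seen twice
    first <- !duplicated(dup_key)
    cand_p1 <- cand_p1[first]; cand_pstop <- cand_pstop[first]
    cand_codon <- cand_codon[first]; g_stop <- g_stop[first]
    for (st in unique(g_stop)) {
      sel <- which(g_stop == st)
      pick <- sel
      if (prefer_atg && any(cand_codon[sel] == "ATG"))
        pick <- sel[cand_codon[sel] == "ATG"]
      lens <- cand_pstop[pick] - cand_p1[pick]
      a <- pick[which.max(lens)]
      p1 <- cand_p1[a]; p2 <- cand_pstop[a] + 2L
      prot <- .translate(substr(s2, p1, cand_pstop[a] - 1L))
      if (strand == "+") {
        g_start <- ((p1 - 1L) %% n) + 1L; g_end <- ((p2 - 1L) %% n) + 1L
      } else {
        # map from reverse-strand coordinates back to plus strand
        g_start <- n - (((p2 - 1L) %% n) + 1L) + 1L
        g_end <- n - (((p1 - 1L) %% n) + 1L) + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seqId(x), start = as.integer(g_start),
        end = as.integer(g_end), strand = strand, type = "CDS",
        family = NA_character_, attributes = "",
        protein = prot, start_codon = cand_codon[a],
        n_alt_starts = length(sel) - 1L, length_aa = nchar(prot),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(cbind(featureTable(character(0), integer(0), integer(0),
                              character(0), character(0)),
                 data.frame(protein = character(0), start_codon = character(0),
                            n_alt_starts = integer(0), length_aa = integer(0))))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Resolve nested and antisense ORF calls
#'
#' Six-frame ORF calling over a gene-dense plasmid produces many short ORFs
#' nested within, or antisense to, real genes. This filter keeps ORFs
#' greedily by decreasing protein length, discarding any ORF whose footprint
#' is already covered by kept ORFs over more than `max_overlap_frac` of its
#' length (on either strand). The canonical one-nt stop/start overlaps of an
#' operon are far below the threshold and are retained.
#'
#' @param genes gene table from [findOrfs()].
#' @param seq_length replicon length in nt.
#' @param max_overlap_frac maximum tolerated covered fraction.
#' @return the filtered gene table, ordered by `start`.
#' @export
filterNestedOrfs <- function(genes, seq_length, max_overlap_frac = 0.5) {
  if (!nrow(genes)) return(genes)
  occupied <- logical(seq_length)
  sel <- logical(nrow(genes))
  for (i in order(-genes$length_aa)) {
    span <- if (genes$end[i] >= genes$start[i]) genes$start[i]:genes$end[i]
            else c(genes$start[i]:seq_length, 1L:genes$end[i])
    if (sum(occupied[span]) <= max_overlap_frac * length(span)) {
      sel[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- genes[sel, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group genes into operons by stop/start overlap or short spacing
#'
#' Same-strand consecutive genes whose CDS footprints overlap (typically by a
#' shared stop/start codon nucleotide, as in the F1-F3 forward block of
#' PL6-family plasmids) or whose intergenic gap is at most `gap_max`
#' (default 30 nt, the average intergenic distance in the reverse block)
#' are placed in one operon.
#'
#' @param genes gene table from [findOrfs()].
#' @param gap_max maximum intergenic gap in nt.
#' @param seq_length replicon length; when given, the gap between the last
#'   and first gene of a strand is also evaluated around the origin.
#' @return `genes` with an added `operon` column (`"+1"`, `"-2"`, ...).
#' @export
detectOperons <- function(genes, gap_max = 30L, seq_length = NULL) {
  genes$operon <- NA_character_
  counter <- 0L
  for (strand in c("+", "-")) {
    idx <- which(genes$strand == strand)
    if (!length(idx)) next
    idx <- idx[order(genes$start[idx])]
    grp <- integer(length(idx))
    counter <- counter + 1L
    grp[1L] <- counter
    if (length(idx) > 1L) {
      for (i in 2L:length(idx)) {
        gap <- genes$start[idx[i]] - genes$end[idx[i - 1L]] - 1L
        if (gap > gap_max) counter <- counter + 1L
        grp[i] <- counter
      }
    }
    # circular wrap: first and last gene of the strand may be adjacent
    if (!is.null(seq_length) && length(idx) > 1L) {
      gap <- genes$start[idx[1L]] + seq_length - genes$end[idx[length(idx)]] - 1L
      if (gap <= gap_max) grp[grp == grp[length(idx)]] <- grp[1L]
    }
    genes$operon[idx] <- paste0(strand, grp)
  }
  genes
}

#' Per-protein length, isoelectric point and net charge
#'
#' The pI is found by bisection on the Henderson-Hasselbalch net-charge
#' function with EMBOSS-style pKa values (N-terminus 8.6, C-terminus 3.6,
#' K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1). The charge function
#' is strictly decreasing in pH, so the root is unique.
#'
#' @param protein amino-acid string over the 20-letter alphabet.
#' @return list with `length_aa`, `pI`, and `charge_pH7`.
#' @export
proteinStats <- function(protein) {
  if (!nzchar(protein)) stop("empty protein")
  if (regexpr("[^ACDEFGHIKLMNPQRSTVWY]", protein) > 0L)
    stop("unknown residue in protein")
  counts <- table(factor(strsplit(protein, "", fixed = TRUE)[[1L]],
                         levels = c("K", "R", "H", "D", "E", "C", "Y")))
  chg <- function(pH) .net_charge(pH, counts)
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (chg(mid) > 0) lo <- mid else hi <- mid
  }
  list(length_aa = nchar(protein), pI = (lo + hi) / 2, charge_pH7 = chg(7))
}

.PKA <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
          D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

.net_charge <- function(pH, counts) {
  pos <- 1 / (1 + 10^(pH - .PKA["Nterm"])) +
    counts[["K"]] / (1 + 10^(pH - .PKA[["K"]])) +
    counts[["R"]] / (1 + 10^(pH - .PKA[["R"]])) +
    counts[["H"]] / (1 + 10^(pH - .PKA[["H"]]))
  neg <- 1 / (1 + 10^(.PKA[["Cterm"]] - pH)) +
    counts[["D"]] / (1 + 10^(.PKA[["D"]] - pH)) +
    counts[["E"]] / (1 + 10^(.PKA[["E"]] - pH)) +
    counts[["C"]] / (1 + 10^(.PKA[["C"]] - pH)) +
    counts[["Y"]] / (1 + 10^(.PKA[["Y"]] - pH))
  unname(pos - neg)
}

#' Percent identity between two proteins
#'
#' Global alignment with affine gaps (BLOSUM62, gap opening 11, extension 1;
#' a gap of length L costs 11 + L). Identity is the fraction of identical
#' columns over alignment columns between the first and last column where
#' both sequences have residues (internal gaps count in the denominator,
#' terminal overhangs do not).
#'
#' @param a,b amino-acid strings.
#' @return identity percent in `[0, 100]`.
#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject AAString
#' @export
pairwiseProteinIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  .identity_from_aligned(as.character(Biostrings::alignedPattern(pa)),
                         as.character(Biostrings::alignedSubject(pa)))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

# identity over columns between the first/last column where both are residues
.identity_from_aligned <- function(sa, sb) {
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  both <- which(ca != "-" & cb != "-")
  if (!length(both)) return(0)
  span <- both[1L]:both[length(both)]
  100 * sum(ca[span] == cb[span]) / length(span)
}

#' Assign gene-family labels across a plasmid family
#'
#' Clusters proteins across plasmids by reciprocal best pairwise identity
#' (default: global identity of 30% or more between proteins whose length
#' ratio is at least 0.6), then orders clusters by consensus position and
#' assigns labels by
#' strand block: forward clusters left-to-right get F1, F2, F3, F3.1, F3.2;
#' reverse clusters right-to-left get R4, R5, R6, R7. Genes not clustering
#' across >= 2 plasmids are labeled `other` (e.g. a strain-specific methylase
#' insertion). Reciprocal-best ties break deterministically to the lower
#' coordinate and are flagged in the evidence table.
#'
#' @param plasmid_genes named list (plasmid id -> gene table from
#'   [findOrfs()], with a `protein` column).
#' @param min_identity minimum percent identity for a cluster edge.
#' @param min_len_ratio minimum shorter/longer protein length ratio.
#' @return list with `genes` (the input tables row-bound, `family` filled)
#'   and `evidence` (per-cluster mean identity, members, tie flags).
#' @export
assignFamilies <- function(plasmid_genes, min_identity = 30,
                           min_len_ratio = 0.6) {
  if (length(plasmid_genes) < 2L) stop("need >= 2 plasmids")
  pls <- names(plasmid_genes)
  if (is.null(pls)) stop("'plasmid_genes' must be a named list")
  all_genes <- do.call(rbind, lapply(pls, function(p) {
    g <- plasmid_genes[[p]]
    g$plasmid <- p
    g$gkey <- paste0(p, ":", seq_len(nrow(g)))
    g
  }))
  ng <- nrow(all_genes)
  # pairwise identities between genes of different plasmids (length-filtered,
  # batched: one alignment call per subject gene)
  id_mat <- matrix(0, ng, ng, dimnames = list(all_genes$gkey, all_genes$gkey))
  tie_flag <- character(0L)
  for (j in 2:ng) {
    lj <- all_genes$length_aa[j]
    cand <- which(seq_len(ng) < j & all_genes$plasmid != all_genes$plasmid[j] &
                    pmin(all_genes$length_aa, lj) /
                      pmax(all_genes$length_aa, lj) >= min_len_ratio)
    if (!length(cand)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(all_genes$protein[cand]),
      Biostrings::AAString(all_genes$protein[j]),
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    # full-alignment-length identity (C-level; terminal gaps in the
    # denominator, acceptable for clustering against a 30% threshold)
    pids <- Biostrings::pid(pa, type = "PID1")
    hit <- which(pids >= min_identity)
    for (k in hit) id_mat[cand[k], j] <- id_mat[j, cand[k]] <- pids[k]
  }
  # reciprocal best hits between plasmid pairs
  edges <- NULL
  for (i in seq_len(ng)) {
    for (p in setdiff(pls, all_genes$plasmid[i])) {
      cand <- which(all_genes$plasmid == p & id_mat[i, ] > 0)
      if (!length(cand)) next
      best <- cand[id_mat[i, cand] == max(id_mat[i, cand])]
      if (length(best) > 1L) {
        tie_flag <- c(tie_flag, all_genes$gkey[i])
        best <- best[which.min(all_genes$start[best])]
      }
      # reciprocity
      back <- which(all_genes$plasmid == all_genes$plasmid[i] &
                      id_mat[best, ] > 0)
      if (length(back) && i %in% back[id_mat[best, back] == max(id_mat[best, back])])
        edges <- rbind(edges, c(i, best))
    }
  }
  # connected components over RBH edges
  comp <- seq_len(ng)
  if (!is.null(edges)) {
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(edges))) {
        a <- comp[edges[r, 1L]]; b <- comp[edges[r, 2L]]
        if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
      }
      if (!changed) break
    }
  }
  all_genes$cluster <- comp
  # conservation-aware overlap resolution: six-frame calling produces nested
  # and antisense ORFs; per plasmid, keep genes greedily preferring clusters
  # shared by more plasmids, then longer proteins (consistent presence across
  # the family is the annotation evidence)
  nplas_of <- vapply(comp, function(k)
    length(unique(all_genes$plasmid[comp == k])), integer(1L))
  # rank by the cluster's consensus (median) protein length, not the
  # individual call: a conserved antisense ORF that happens to run long in
  # one plasmid must not displace a real gene there
  medlen_of <- vapply(comp, function(k)
    stats::median(all_genes$length_aa[comp == k]), numeric(1L))
  all_genes$kept <- FALSE
  for (p in pls) {
    rows <- which(all_genes$plasmid == p)
    g <- plasmid_genes[[p]]
    L <- max(all_genes$end[rows], all_genes$start[rows])
    occupied <- logical(L)
    for (i in rows[order(-nplas_of[rows], -medlen_of[rows],
                         -all_genes$length_aa[rows])]) {
      span <- if (all_genes$end[i] >= all_genes$start[i])
        all_genes$start[i]:all_genes$end[i]
      else c(all_genes$start[i]:L, 1L:all_genes$end[i])
      if (sum(occupied[span]) <= 0.5 * length(span)) {
        all_genes$kept[i] <- TRUE
        occupied[span] <- TRUE
      }
    }
  }
  # clusters spanning >= 2 plasmids among kept genes, by consensus position
  info <- do.call(rbind, lapply(unique(comp), function(k) {
    rows <- all_genes[comp == k & all_genes$kept, , drop = FALSE]
    if (!nrow(rows))
      return(data.frame(cluster = k, n_plasmids = 0L, strand = "+", pos = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(cluster = k, n_plasmids = length(unique(rows$plasmid)),
               strand = names(which.max(table(rows$strand))),
               pos = mean(rows$start), stringsAsFactors = FALSE)
  }))
  fam_of <- rep("other", nrow(info))
  fwd <- which(info$n_plasmids >= 2L & info$strand == "+")
  fwd <- fwd[order(info$pos[fwd])]
  f_labels <- c("F1", "F2", "F3", "F3.1", "F3.2")
  fam_of[fwd] <- c(f_labels, rep("other", max(0L, length(fwd) - length(f_labels))))[
    seq_along(fwd)]
  rev_cl <- which(info$n_plasmids >= 2L & info$strand == "-")
  rev_cl <- rev_cl[order(info$pos[rev_cl], decreasing = TRUE)]
  r_labels <- c("R4", "R5", "R6", "R7")
  fam_of[rev_cl] <- c(r_labels, rep("other", max(0L, length(rev_cl) - length(r_labels))))[
    seq_along(rev_cl)]
  info$family <- fam_of
  all_genes$family <- info$family[match(all_genes$cluster, info$cluster)]
  # evidence: mean within-cluster identity
  info$mean_identity <- vapply(info$cluster, function(k) {
    rows <- which(comp == k)
    if (length(rows) < 2L) return(NA_real_)
    vals <- id_mat[rows, rows]; vals <- vals[upper.tri(vals)]
    mean(vals[vals > 0])
  }, numeric(1L))
  info$tied <- vapply(info$cluster, function(k)
    any(all_genes$gkey[comp == k] %in% tie_flag), logical(1L))
  list(genes = all_genes, evidence = info)
}
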