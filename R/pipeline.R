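#' Run the full comparative pipeline over a plasmid set
#'
#' Orchestrates every analysis stage over a family of circular plasmids and
#' writes a report bundle to `out_dir`:
#' \itemize{
#'   \item `summary.tsv`: per-plasmid id, length, GC percent;
#'   \item `identity_matrix.tsv` and `tree.nwk`: all-pairs circular-alignment
#'     identities and the NJ tree with bootstrap support (from the family
#'     MSA);
#'   \item `annotation.gff3`: CDS calls with gene-family labels, plus motif,
#'     inverted-repeat and slippery-site features;
#'   \item `proteins.tsv`: per-family protein length / identity / pI table;
#'   \item `cis.tsv`, `promoters.tsv`, `rbs.tsv`: regulatory-element reports;
#'   \item `spacer_matches.tsv` when spacers are given;
#'   \item `recruitment.tsv` when reads and a seed reference are given.
#' }
#' Rerunning with the same inputs and seed reproduces identical outputs.
#'
#' @param seqs named list of [CircularSeq-class] (>= 1; comparative stages
#'   need >= 2, tree and CIS stages >= 3).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for bootstrap resampling.
#' @param spacers optional data.frame from [readSpacers()].
#' @param reads optional data.frame of reads (`id`, `seq`).
#' @param recruit_seed_id id of the plasmid used as recruitment seed
#'   reference (default: first).
#' @param bootstrap_n bootstrap replicates for the NJ tree.
#' @param min_aa minimum ORF length (aa) for annotation.
#' @param promoter_pattern degenerate promoter consensus to scan.
#' @param comparative run comparative stages (alignment, tree, CIS).
#' @return invisible list with the main in-memory results.
#' @export
runAll <- function(seqs, out_dir, seed = 1L, spacers = NULL, reads = NULL,
                   recruit_seed_id = NULL, bootstrap_n = 100L, min_aa = 30L,
                   promoter_pattern = "SRNNRNNNTTWW", comparative = TRUE) {
  if (is(seqs, "CircularSeq")) seqs <- list(seqs)
  names(seqs) <- vapply(seqs, seqId, character(1L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  # (a) summary table
  res$summary <- data.frame(
    id = names(seqs),
    length_nt = vapply(seqs, seqLength, integer(1L)),
    gc_percent = round(vapply(seqs, function(s) regionGC(s), numeric(1L)), 1),
    stringsAsFactors = FALSE)
  writeTsv(res$summary, file.path(out_dir, "summary.tsv"))

  # (b) annotation: ORF calling, overlap resolution, operon grouping.
  # With >= 2 plasmids, overlap resolution is conservation-aware (inside
  # assignFamilies); alone, it falls back to length-based filtering.
  raw_orfs <- lapply(seqs, findOrfs, min_aa = min_aa)

  if (comparative && length(seqs) >= 2L) {
    fam <- assignFamilies(raw_orfs)
    res$families <- fam
    res$genes <- lapply(names(seqs), function(id) {
      rows <- fam$genes[fam$genes$plasmid == id & fam$genes$kept, ]
      rows <- rows[order(rows$start, rows$end),
                   c("seq_id", "start", "end", "strand", "type", "family",
                     "attributes", "protein", "start_codon", "n_alt_starts",
                     "length_aa")]
      rownames(rows) <- NULL
      detectOperons(rows, seq_length = seqLength(seqs[[id]]))
    })
    names(res$genes) <- names(seqs)
    # (d) protein table by family
    res$proteins <- .protein_family_table(fam$genes[fam$genes$kept, ])
    writeTsv(res$proteins, file.path(out_dir, "proteins.tsv"))
    # (b) identities and tree
    pim <- pairwiseIdentityMatrix(seqs)
    res$identity <- pim$identity
    writeTsv(data.frame(id = rownames(pim$identity),
                        round(pim$identity, 2), check.names = FALSE),
             file.path(out_dir, "identity_matrix.tsv"))
    if (length(seqs) >= 3L) {
      res$msa <- progressiveMsa(seqs)
      res$tree <- njTree(res$msa, bootstrap_n = bootstrap_n, seed = seed)
      writeNewick(res$tree, file.path(out_dir, "tree.nwk"))
      # the intergenic mask uses the conserved (family-labeled) gene set:
      # CIS regions are defined relative to the annotated core genes, not to
      # every six-frame ORF call
      fam_genes <- lapply(res$genes, function(g)
        g[!is.na(g$family) & g$family != "other", , drop = FALSE])
      res$cis <- detectCis(res$msa, fam_genes, seqs)
      writeTsv(res$cis, file.path(out_dir, "cis.tsv"))
    }
  } else {
    res$genes <- lapply(names(seqs), function(id) {
      g <- filterNestedOrfs(raw_orfs[[id]], seqLength(seqs[[id]]))
      detectOperons(g, seq_length = seqLength(seqs[[id]]))
    })
    names(res$genes) <- names(seqs)
  }

  # (e) regulatory elements per plasmid
  promoters <- NULL; rbs_hits <- NULL; irs <- NULL; slips <- NULL
  all_feats <- NULL
  for (id in names(seqs)) {
    s <- seqs[[id]]
    genes <- res$genes[[id]]
    hits <- scanIupac(s, promoter_pattern, strands = "both")
    kept <- promoterPositionalFilter(hits, genes, seqLength(s),
                                     center_range = c(-30L, -20L))
    if (nrow(kept)) {
      kept$n_total_hits <- nrow(hits)
      promoters <- rbind(promoters, kept)
    }
    for (g in seq_len(nrow(genes))) {
      rb <- findRbs(s, genes[g, ])
      if (!is.null(rb)) {
        rb$gene <- g
        rb$gene_family <- genes$family[g]
        rbs_hits <- rbind(rbs_hits, rb)
      }
    }
    # inverted repeats upstream of reverse-strand gene starts
    for (g in which(genes$strand == "-")) {
      gstart <- genes$end[g]
      reg <- c(((gstart) %% seqLength(s)) + 1L,
               ((gstart + 59L) %% seqLength(s)) + 1L)
      ir <- findInvertedRepeats(s, region = reg, min_arm = 4L,
                                max_loop = 20L)
      if (nrow(ir)) {
        ir$seq_id <- id; ir$gene <- g
        irs <- rbind(irs, ir)
      }
    }
    # frameshift signals in substantial genes (short spurious ORFs skipped)
    for (g in which(genes$length_aa >= 100L)) {
      sl <- findSlipperySites(s, genes[g, ])
      if (nrow(sl)) { sl$gene <- g; slips <- rbind(slips, sl) }
    }
    feats <- genes[, c("seq_id", "start", "end", "strand", "type", "family",
                       "attributes")]
    if (nrow(kept))
      feats <- rbind(feats, kept[, c("seq_id", "start", "end", "strand",
                                     "type", "family", "attributes")])
    all_feats <- rbind(all_feats, feats)
  }
  res$promoters <- promoters; res$rbs <- rbs_hits
  res$inverted_repeats <- irs; res$slippery <- slips
  if (!is.null(promoters))
    writeTsv(promoters, file.path(out_dir, "promoters.tsv"))
  if (!is.null(rbs_hits)) writeTsv(rbs_hits, file.path(out_dir, "rbs.tsv"))
  if (!is.null(irs))
    writeTsv(irs, file.path(out_dir, "inverted_repeats.tsv"))
  if (!is.null(slips))
    writeTsv(slips, file.path(out_dir, "slippery_sites.tsv"))
  writeGff3(all_feats, seqs, file.path(out_dir, "annotation.gff3"))

  # (f) spacer matching
  if (!is.null(spacers)) {
    res$spacer_matches <- matchSpacers(spacers, seqs)
    writeTsv(res$spacer_matches, file.path(out_dir, "spacer_matches.tsv"))
  }

  # (g) recruitment / assembly
  if (!is.null(reads)) {
    seed_ref <- seqs[[recruit_seed_id %||% names(seqs)[1L]]]
    res$assembly <- iterativeClosure(reads, seed_ref)
    writeTsv(res$assembly@log, file.path(out_dir, "recruitment.tsv"))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Table-3-style per-family protein summary
.protein_family_table <- function(genes_with_families) {
  fams <- setdiff(unique(genes_with_families$family), NA)
  fams <- fams[order(match(fams, c("F1", "F2", "F3", "F3.1", "F3.2",
                                   "R7", "R6", "R5", "R4", "other")))]
  out <- NULL
  for (f in fams) {
    rows <- genes_with_families[genes_with_families$family %in% f, ]
    lens <- rows$length_aa
    pis <- vapply(rows$protein, function(p) proteinStats(p)$pI, numeric(1L))
    idts <- c()
    if (nrow(rows) >= 2L) {
      for (i in seq_len(nrow(rows) - 1L)) for (j in (i + 1L):nrow(rows)) {
        if (rows$plasmid[i] == rows$plasmid[j]) next
        idts <- c(idts, pairwiseProteinIdentity(rows$protein[i],
                                                rows$protein[j]))
      }
    }
    out <- rbind(out, data.frame(
      family = f, n = nrow(rows),
      length_range = sprintf("%d-%d", min(lens), max(lens)),
      length_mean = round(mean(lens), 1),
      identity_range = if (length(idts))
        sprintf("%.0f-%.0f", min(idts), max(idts)) else NA_character_,
      identity_mean = if (length(idts)) round(mean(idts), 1) else NA_real_,
      pI_range = sprintf("%.2f-%.2f", min(pis), max(pis)),
      pI_mean = round(mean(pis), 2), stringsAsFactors = FALSE))
  }
  out
}
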