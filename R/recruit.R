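#' AssemblyState: the state of an iterative recruitment-assembly run
#'
#' @slot iteration rounds completed.
#' @slot recruited_ids read ids recruited so far (monotone non-decreasing
#'   across rounds).
#' @slot contigs data.frame (contig, length, coverage) from the last round.
#' @slot closed whether circular closure was detected.
#' @slot final_seq the closed circular sequence (`CircularSeq`) or `NULL`.
#' @slot log data.frame per-round report (round, n_recruited,
#'   longest_contig, closed).
#' @export
setClass("AssemblyState",
  representation(iteration = "integer", recruited_ids = "character",
                 contigs = "data.frame", closed = "logical",
                 final_seq = "ANY", log = "data.frame"))

setValidity("AssemblyState", function(object) {
  if (object@closed && is.null(object@final_seq))
    return("closed assembly must carry a final sequence")
  TRUE
})

setMethod("show", "AssemblyState", function(object) {
  cat(sprintf("AssemblyState: %d round(s), %d reads recruited, closed=%s\n",
              object@iteration, length(object@recruited_ids), object@closed))
  if (object@closed) cat(sprintf("  final circle: %d nt\n",
                                 seqLength(object@final_seq)))
})

#' @describeIn iterativeClosure was circular closure reached?
#' @param x an `AssemblyState`.
#' @export
isClosed <- function(x) x@closed

#' @describeIn iterativeClosure the closed circular sequence (or `NULL`).
#' @export
finalSeq <- function(x) x@final_seq

# k-mer seed index of a reference (both strands handled by the caller)
.seed_index <- function(refseq, k) {
  kms <- .kmers(refseq, k)
  split(seq_along(kms), kms)
}

#' Recruit reads to a reference by seeded alignment
#'
#' A read is recruited when an exact seed k-mer (default 15 nt) shared with
#' the reference (either strand) extends to an alignment covering at least
#' `min_cov_frac` of the read at `min_identity` percent identity or better.
#' The reference is treated as circular by origin-doubling, so reads
#' spanning the origin recruit normally.
#'
#' @param reads data.frame with `id` and `seq` columns (e.g. from
#'   [simulateReads()]).
#' @param reference a [CircularSeq-class] or a plain contig string.
#' @param min_identity minimum percent identity of the read alignment.
#' @param min_cov_frac minimum fraction of the read that must align.
#' @param k seed length.
#' @return the recruited subset of `reads` (same columns), with a
#'   `recruited_strand` column.
#' @export
recruitReads <- function(reads, reference, min_identity = 90,
                         min_cov_frac = 0.8, k = 15L) {
  refseq <- if (is(reference, "CircularSeq")) {
    if (topology(reference) == "circular")
      paste0(residues(reference), residues(reference))
    else residues(reference)
  } else reference                      # linear contig: ends are real ends
  idx <- .seed_index(refseq, k)
  keep <- logical(nrow(reads))
  strand_hit <- rep(NA_character_, nrow(reads))
  for (r in seq_len(nrow(reads))) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") reads$seq[r] else .revcomp(reads$seq[r])
      qlen <- nchar(q)
      if (qlen < k) next
      # probe seeds along the read until one anchors
      probe_at <- unique(c(seq(1L, qlen - k + 1L, by = k), qlen - k + 1L))
      anchored <- FALSE
      for (s in probe_at) {
        hits <- idx[[substr(q, s, s + k - 1L)]]
        if (is.null(hits)) next
        for (h in hits[seq_len(min(3L, length(hits)))]) {
          w_start <- max(1L, h - s + 1L - 10L)
          w_end <- min(nchar(refseq), h - s + qlen + 10L)
          win <- substr(refseq, w_start, w_end)
          if (w_end - w_start + 1L >= qlen + 10L) {
            # read fully inside the reference: end-to-end read alignment
            pa <- Biostrings::pairwiseAlignment(
              Biostrings::DNAString(q), Biostrings::DNAString(win),
              substitutionMatrix = .nuc_matrix(1, -1),
              gapOpening = 5, gapExtension = 1, type = "global-local")
            aligned_q <- qlen - Biostrings::nindel(pa)@insertion[, "WidthSum"]
            ident <- Biostrings::pid(pa, type = "PID1")
            if (aligned_q >= min_cov_frac * qlen && ident >= min_identity) {
              anchored <- TRUE; break
            }
          } else {
            # read overhangs a contig end: overlap alignment; accept on the
            # overlapping segment (>= 25 nt) so contigs can be extended
            pa <- Biostrings::pairwiseAlignment(
              Biostrings::DNAString(q), Biostrings::DNAString(win),
              substitutionMatrix = .nuc_matrix(1, -1),
              gapOpening = 5, gapExtension = 1, type = "overlap")
            ov <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa)
            ident <- Biostrings::pid(pa, type = "PID1")
            if (ov >= min(25L, min_cov_frac * qlen) && ident >= min_identity) {
              anchored <- TRUE; break
            }
          }
        }
        if (anchored) break
      }
      if (anchored) { keep[r] <- TRUE; strand_hit[r] <- strand; break }
    }
  }
  out <- reads[keep, , drop = FALSE]
  out$recruited_strand <- strand_hit[keep]
  rownames(out) <- NULL
  out
}

#' Assemble reads with a de Bruijn graph
#'
#' Builds the k-mer de Bruijn graph over both read strands, prunes
#' singleton-coverage k-mers when deeper ones exist (tip/error removal),
#' and emits unitigs (maximal non-branching paths) with mean k-mer
#' coverage. Canonical ordering of k-mers makes the output independent of
#' read input order. A contig assembled from a circular template carries a
#' terminal `k-1` self-overlap.
#'
#' @param reads data.frame with a `seq` column.
#' @param k odd k-mer size, 11-63.
#' @return data.frame (contig, length, coverage), longest first.
#' @export
assembleReads <- function(reads, k = 31L) {
  if (!nrow(reads)) stop("no reads to assemble")
  if (k %% 2L == 0L || k < 11L || k > 63L) stop("k must be odd and in [11, 63]")
  seqs <- reads$seq[nchar(reads$seq) >= k + 1L]
  if (!length(seqs)) stop("all reads shorter than k + 1")
  kmers <- unlist(lapply(c(seqs, vapply(seqs, .revcomp, character(1L))),
                         .kmers, k = k), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  counts <- table(kmers)
  # drop likely-error k-mers: coverage 1 when the graph has deeper k-mers
  if (max(counts) >= 4L) counts <- counts[counts >= 2L]
  kset <- sort(names(counts))
  cov <- as.integer(counts[kset])
  names(cov) <- kset
  pre <- substr(kset, 1L, k - 1L)          # prefix (k-1)-mer
  suf <- substr(kset, 2L, k)               # suffix (k-1)-mer
  out_of <- split(seq_along(kset), pre)    # node -> outgoing kmers
  in_of <- split(seq_along(kset), suf)     # node -> incoming kmers
  used <- logical(length(kset))
  contigs <- NULL
  for (i in seq_along(kset)) {
    if (used[i]) next
    used[i] <- TRUE
    path <- i
    # extend right through non-branching nodes
    cur <- i
    repeat {
      node <- suf[cur]
      cand <- out_of[[node]]
      if (is.null(cand) || length(cand) != 1L ||
          length(in_of[[node]]) != 1L || used[cand]) break
      used[cand] <- TRUE; path <- c(path, cand); cur <- cand
    }
    # extend left
    cur <- i
    repeat {
      node <- pre[cur]
      cand <- in_of[[node]]
      if (is.null(cand) || length(cand) != 1L ||
          length(out_of[[node]]) != 1L || used[cand]) break
      used[cand] <- TRUE; path <- c(cand, path); cur <- cand
    }
    contig <- paste0(kset[path[1L]],
                     paste(substr(kset[path[-1L]], k, k), collapse = ""))
    contigs <- rbind(contigs, data.frame(
      contig = contig, length = nchar(contig),
      coverage = mean(cov[path]), stringsAsFactors = FALSE))
  }
  # each contig also exists as its reverse complement; keep the
  # lexicographically smaller representative once
  canon <- pmin(contigs$contig, vapply(contigs$contig, .revcomp, character(1L)))
  contigs <- contigs[!duplicated(canon), , drop = FALSE]
  contigs <- contigs[order(-contigs$length, contigs$contig), , drop = FALSE]
  rownames(contigs) <- NULL
  contigs
}

# detect a terminal (>= k-1) exact self-overlap and trim it
.detect_closure <- function(contig, k) {
  ov <- k - 1L
  n <- nchar(contig)
  if (n <= 2L * ov) return(NULL)
  if (substr(contig, 1L, ov) == substr(contig, n - ov + 1L, n))
    return(substr(contig, 1L, n - ov))
  NULL
}

#' Iterative read recruitment and reassembly to circular closure
#'
#' Reproduces, at desk scale, the strategy used to reconstruct a plasmid
#' from metavirome reads: recruit reads to a (possibly diverged) seed
#' reference, de novo assemble the recruited reads, take the longest contig
#' as the new reference, and repeat until the contig's ends share an exact
#' `k-1` overlap (circular closure, which is then trimmed) or progress
#' stalls for two consecutive rounds.
#'
#' @param reads data.frame with `id` and `seq` columns.
#' @param seed_reference a [CircularSeq-class] or contig string.
#' @param max_rounds maximum recruitment/assembly rounds.
#' @param k assembly k-mer size.
#' @param min_identity,min_cov_frac recruitment thresholds; the first round
#'   uses a relaxed identity (`seed_identity`) to admit reads of a true
#'   target diverged from the seed.
#' @param seed_identity identity threshold for round 1.
#' @return an [AssemblyState-class].
#' @export
iterativeClosure <- function(reads, seed_reference, max_rounds = 40L, k = 31L,
                             min_identity = 90, min_cov_frac = 0.8,
                             seed_identity = 70) {
  reference <- seed_reference
  recruited_ids <- character(0L)
  log <- NULL
  contigs <- data.frame()
  closed <- FALSE
  final_seq <- NULL
  stall <- 0L
  round <- 0L
  while (round < max_rounds) {
    round <- round + 1L
    idthr <- if (round == 1L) seed_identity else min_identity
    todo <- reads[!reads$id %in% recruited_ids, , drop = FALSE]
    rec <- recruitReads(todo, reference, min_identity = idthr,
                        min_cov_frac = min_cov_frac)
    recruited_ids <- union(recruited_ids, rec$id)
    rec_all <- reads[reads$id %in% recruited_ids, , drop = FALSE]
    if (!nrow(rec_all)) {
      log <- rbind(log, data.frame(round = round, n_recruited = 0L,
                                   longest_contig = 0L, closed = FALSE))
      break
    }
    contigs <- assembleReads(rec_all, k = k)
    longest <- contigs$contig[1L]
    circ <- .detect_closure(longest, k)
    log <- rbind(log, data.frame(round = round,
                                 n_recruited = length(recruited_ids),
                                 longest_contig = nchar(longest),
                                 closed = !is.null(circ)))
    if (!is.null(circ)) {
      closed <- TRUE
      final_seq <- circularSeq("assembled_circle", circ, "circular")
      break
    }
    if (round > 1L &&
        log$longest_contig[round] <= log$longest_contig[round - 1L] &&
        log$n_recruited[round] <= log$n_recruited[round - 1L]) {
      stall <- stall + 1L
      if (stall >= 2L) break
    } else stall <- 0L
    reference <- longest
  }
  new("AssemblyState", iteration = round, recruited_ids = recruited_ids,
      contigs = contigs, closed = closed, final_seq = final_seq,
      log = if (is.null(log)) data.frame() else log)
}
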