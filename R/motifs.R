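.IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

.revcomp_iupac <- function(p) {
  paste(rev(.IUPAC_COMP[strsplit(toupper(p), "", fixed = TRUE)[[1L]]]),
        collapse = "")
}

# mismatch count of a concrete window vs an IUPAC pattern; N in the pattern
# never counts as a mismatch
.iupac_mismatches <- function(window, pattern_chars) {
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  sum(!mapply(function(ch, p) ch %in% .IUPAC_SET[[p]], w, pattern_chars))
}

#' Scan a replicon for a degenerate IUPAC motif
#'
#' Reports every position (wrapping through the origin of a circular
#' sequence) where the window matches the pattern with at most
#' `max_mismatch` mismatches. Degenerate positions (R, S, W, ...) must match
#' their base set; pattern `N` matches anything and never counts as a
#' mismatch. Overlapping hits are all reported. With `strands = "both"` the
#' reverse strand is scanned with the reverse-complemented pattern and hits
#' are reported by their plus-strand footprint with `strand = "-"`.
#'
#' @param x a [CircularSeq-class].
#' @param pattern IUPAC string, e.g. the haloarchaeal promoter consensus
#'   `"SRNNRNNNTTWW"`.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @param max_mismatch maximum mismatches at non-N positions (default 0).
#' @param pattern_id label stored with each hit.
#' @return feature table of motif hits with a `mismatches` column.
#' @importFrom Biostrings matchPattern
#' @export
scanIupac <- function(x, pattern, strands = c("both", "+", "-"),
                      max_mismatch = 0L, pattern_id = pattern) {
  strands <- match.arg(strands)
  pattern <- toupper(pattern)
  pchars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(pchars %in% names(.IUPAC_SET)))
    stop("invalid IUPAC letter(s): ",
         paste(setdiff(pchars, names(.IUPAC_SET)), collapse = ", "))
  L <- nchar(pattern)
  n <- seqLength(x)
  if (L > n) stop("pattern longer than sequence")
  subject <- if (topology(x) == "circular")
    paste0(residues(x), substr(residues(x), 1L, L - 1L)) else residues(x)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(
      pat, Biostrings::DNAString(subject), max.mismatch = max_mismatch,
      fixed = c(pattern = FALSE, subject = TRUE))
    st <- BiocGenerics::start(hits)
    st <- st[st <= n]
    if (!length(st)) return(NULL)
    pc <- strsplit(pat, "", fixed = TRUE)[[1L]]
    mm <- vapply(st, function(s)
      .iupac_mismatches(substr(subject, s, s + L - 1L), pc), numeric(1L))
    data.frame(seq_id = seqId(x), start = as.integer(st),
               end = as.integer(((st + L - 2L) %% n) + 1L), strand = strand,
               type = "motif", family = NA_character_,
               attributes = paste0("pattern=", pattern_id),
               mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }
  out <- NULL
  if (strands %in% c("both", "+")) out <- rbind(out, scan_one(pattern, "+"))
  if (strands %in% c("both", "-"))
    out <- rbind(out, scan_one(.revcomp_iupac(pattern), "-"))
  if (is.null(out))
    out <- cbind(featureTable(character(0), integer(0), integer(0),
                              character(0), character(0)),
                 data.frame(mismatches = integer(0)))
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Search for a ribosome-binding site upstream of a gene
#'
#' Scans the window `search_window[1]`..`search_window[2]` nt upstream of the
#' start codon (on the gene strand) for the best match to the RBS consensus
#' (default `GGAGGTGA`). The offset is the number of nt strictly between the
#' motif's 3' end and the first nt of the start codon, so the PL6-family
#' `GGAGGCGA` consistently 4 nt before the F3 start codon reports offset 4.
#' Ranking is fewest mismatches, then smallest offset. Absence is a valid
#' result (`NULL`): most haloarchaeal transcripts are leaderless.
#'
#' @param x a [CircularSeq-class].
#' @param gene one-row gene table (from [findOrfs()]): `start,end,strand`.
#' @param consensus RBS consensus.
#' @param max_mismatch maximum accepted mismatches (default 1).
#' @param search_window integer c(min, max) offset range in nt.
#' @return one-row motif hit with an `offset=` attribute, or `NULL`.
#' @export
findRbs <- function(x, gene, consensus = "GGAGGTGA", max_mismatch = 1L,
                    search_window = c(3L, 12L)) {
  L <- nchar(consensus)
  n <- seqLength(x)
  pchars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  # 5' start-codon position on the gene strand
  gstart <- if (gene$strand == "+") gene$start else gene$end
  best <- NULL
  for (off in seq(search_window[1L], search_window[2L])) {
    # motif occupies [gstart - off - L, gstart - off - 1] on the gene strand
    if (gene$strand == "+") {
      s <- ((gstart - off - L - 1L) %% n) + 1L
      e <- ((gstart - off - 2L) %% n) + 1L
      win <- subseqCirc(x, s, e, "+")
    } else {
      s <- ((gstart + off) %% n) + 1L
      e <- ((gstart + off + L - 1L) %% n) + 1L
      win <- subseqCirc(x, s, e, "-")
    }
    mm <- .iupac_mismatches(win, pchars)
    if (mm <= max_mismatch && (is.null(best) || mm < best$mismatches))
      best <- data.frame(seq_id = seqId(x), start = as.integer(s),
                         end = as.integer(e), strand = gene$strand,
                         type = "motif", family = NA_character_,
                         attributes = sprintf("pattern=RBS;offset=%d;motif=%s",
                                              off, win),
                         mismatches = as.integer(mm), offset = as.integer(off),
                         stringsAsFactors = FALSE)
    if (!is.null(best) && best$mismatches == 0L) break
  }
  best
}

#' Find inverted repeats within a region
#'
#' Detects arm pairs (left arm, loop, right arm = reverse complement of the
#' left arm up to `max_mismatch`) using maximal palindromic regions. The
#' AT-motif length is the longest run of A/T within the left arm, a feature
#' of the regulatory inverted repeats found just upstream of the R4 start in
#' PL6-family plasmids. Results are sorted by arm length (descending), then
#' position.
#'
#' @param x a [CircularSeq-class].
#' @param region c(start, end) region to scan (may wrap the origin).
#' @param min_arm minimum arm length in nt (>= 4).
#' @param max_loop maximum loop length in nt.
#' @param max_mismatch maximum mismatches between the arms.
#' @return data.frame with absolute arm coordinates, loop/arm lengths,
#'   mismatch count and AT-motif length.
#' @importFrom Biostrings findPalindromes palindromeArmLength
#' @importFrom BiocGenerics start end width
#' @export
findInvertedRepeats <- function(x, region = c(1L, seqLength(x)), min_arm = 4L,
                                max_loop = 15L, max_mismatch = 0L) {
  if (min_arm < 4L) stop("'min_arm' must be >= 4")
  win <- subseqCirc(x, region[1L], region[2L], "+")
  n <- seqLength(x)
  pal <- Biostrings::findPalindromes(
    Biostrings::DNAString(win), min.armlength = min_arm,
    max.looplength = max_loop, max.mismatch = max_mismatch)
  if (!length(pal)) {
    return(data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      arm = integer(0), loop = integer(0),
                      mismatches = integer(0), at_motif = integer(0)))
  }
  arm <- Biostrings::palindromeArmLength(pal, max.mismatch = max_mismatch)
  s <- BiocGenerics::start(pal); w <- BiocGenerics::width(pal)
  abs_pos <- function(p) ((region[1L] + p - 2L) %% n) + 1L
  out <- data.frame(
    left_start = abs_pos(s), left_end = abs_pos(s + arm - 1L),
    right_start = abs_pos(s + w - arm), right_end = abs_pos(s + w - 1L),
    arm = as.integer(arm), loop = as.integer(w - 2L * arm))
  out$mismatches <- vapply(seq_len(nrow(out)), function(i) {
    left <- substr(win, s[i], s[i] + arm[i] - 1L)
    right <- substr(win, s[i] + w[i] - arm[i], s[i] + w[i] - 1L)
    sum(strsplit(left, "")[[1L]] != strsplit(.revcomp(right), "")[[1L]])
  }, integer(1L))
  out$at_motif <- vapply(seq_len(nrow(out)), function(i) {
    left <- substr(win, s[i], s[i] + arm[i] - 1L)
    runs <- rle(strsplit(left, "")[[1L]] %in% c("A", "T"))
    if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  }, integer(1L))
  out <- out[order(-out$arm, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# project original coordinates of one sequence to MSA columns:
# returns integer vector col_of[original position]
.msa_column_map <- function(msa, id, seq_length) {
  aligned <- msa@aligned[[id]]
  rot <- msa@rotations[[id]]
  chars <- strsplit(aligned, "", fixed = TRUE)[[1L]]
  rotpos_of_col <- cumsum(chars != "-")      # rotated position per column
  col_of_rot <- integer(seq_length)
  col_of_rot[rotpos_of_col[chars != "-"]] <- which(chars != "-")
  # original position p maps to rotated position ((p - rot) mod n) + 1
  p <- seq_len(seq_length)
  col_of_rot[((p - rot) %% seq_length) + 1L]
}

#' Detect conserved intergenic sequences (CIS) from a family alignment
#'
#' Finds maximal runs of at least `min_len` alignment columns that are
#' intergenic in every plasmid and whose mean column conservation (fraction
#' of sequences agreeing with the column consensus; gaps never agree) is at
#' least `min_conservation`. Regions are labeled `CIS I`, `CIS II`, ... in
#' column order, which with an F1-anchored linearization reproduces the
#' family's canonical CIS numbering; flanking gene families on the reference
#' are recorded as context.
#'
#' @param msa a [PlasmidMSA-class] over >= 3 plasmids.
#' @param gene_annotations named list (plasmid id -> gene table in original
#'   plasmid coordinates, e.g. from [findOrfs()]).
#' @param seqs named list of [CircularSeq-class] (for lengths).
#' @param min_len minimum region length in columns (default 12).
#' @param min_conservation minimum mean column conservation (default 0.9).
#' @return data.frame: label, col_start, col_end, mean_conservation, context,
#'   plus `<id>_start`/`<id>_end` coordinates per plasmid.
#' @export
detectCis <- function(msa, gene_annotations, seqs, min_len = 12L,
                      min_conservation = 0.9) {
  m <- as.matrix(msa)
  ids <- rownames(m) <- names(msa@aligned)
  if (length(ids) < 3L) stop("need an alignment of >= 3 plasmids")
  nc <- ncol(m)
  # per-column conservation
  cons <- vapply(seq_len(nc), function(j) {
    col <- m[, j]
    tab <- table(col[col != "-"])
    if (!length(tab)) 0 else max(tab) / length(col)
  }, numeric(1L))
  # genic mask per plasmid projected to columns
  genic <- matrix(FALSE, length(ids), nc, dimnames = list(ids, NULL))
  for (id in ids) {
    n <- seqLength(seqs[[id]])
    colmap <- .msa_column_map(msa, id, n)
    genes <- gene_annotations[[id]]
    for (i in seq_len(NROW(genes))) {
      span <- if (genes$end[i] >= genes$start[i])
        genes$start[i]:genes$end[i]
      else c(genes$start[i]:n, 1L:genes$end[i])
      cols <- colmap[span]
      genic[id, cols[cols > 0L]] <- TRUE
    }
  }
  intergenic <- colSums(genic) == 0L
  ok <- intergenic & cons >= min_conservation
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_len)
  if (!length(keep)) {
    return(data.frame(label = character(0), col_start = integer(0),
                      col_end = integer(0), mean_conservation = numeric(0),
                      context = character(0)))
  }
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  out <- data.frame(
    label = paste("CIS", roman[pmin(seq_along(keep), length(roman))]),
    col_start = starts[keep], col_end = ends[keep],
    mean_conservation = vapply(seq_along(keep), function(i)
      mean(cons[starts[keep[i]]:ends[keep[i]]]), numeric(1L)),
    stringsAsFactors = FALSE)
  # context: nearest genes on the reference plasmid
  ref <- ids[1L]
  nref <- seqLength(seqs[[ref]])
  colmap_ref <- .msa_column_map(msa, ref, nref)
  out$context <- vapply(seq_len(nrow(out)), function(i) {
    g <- gene_annotations[[ref]]
    if (!NROW(g)) return("")
    gcols_start <- colmap_ref[pmax(1L, g$start)]
    before <- which(gcols_start < out$col_start[i])
    after <- which(gcols_start > out$col_end[i])
    fam <- function(k) {
      f <- g$family[k]
      if (length(k) && !is.na(f) && nzchar(f)) f else as.character(k)
    }
    sprintf("%s..%s",
            if (length(before)) fam(before[which.max(gcols_start[before])]) else "origin",
            if (length(after)) fam(after[which.min(gcols_start[after])]) else "origin")
  }, character(1L))
  # per-plasmid coordinates (original, 1-based; NA when fully gapped)
  for (id in ids) {
    n <- seqLength(seqs[[id]])
    colmap <- .msa_column_map(msa, id, n)
    cs <- ce <- rep(NA_integer_, nrow(out))
    for (i in seq_len(nrow(out))) {
      inside <- which(colmap >= out$col_start[i] & colmap <= out$col_end[i] &
                        colmap > 0L)
      if (length(inside)) { cs[i] <- min(inside); ce[i] <- max(inside) }
    }
    out[[paste0(id, "_start")]] <- cs
    out[[paste0(id, "_end")]] <- ce
  }
  out
}

#' Keep promoter-motif hits positioned upstream of a gene start
#'
#' A hit survives when its motif center lies within `center_range`
#' (negative = upstream, in nt, on the gene strand) of the first nt of some
#' gene's start codon, and the hit is on that gene's strand. Haloarchaeal
#' promoter motifs center around -27 to -28 relative to the initiator A of
#' leaderless transcripts.
#'
#' @param hits motif-hit table from [scanIupac()].
#' @param genes gene table from [findOrfs()].
#' @param seq_length replicon length (for circular distances).
#' @param center_range c(min, max) signed center offsets, e.g. `c(-30, -20)`.
#' @return filtered hits with an added `gene` column (matched gene row index).
#' @export
promoterPositionalFilter <- function(hits, genes, seq_length,
                                     center_range = c(-30L, -20L)) {
  if (!nrow(hits)) { hits$gene <- integer(0); return(hits) }
  keep <- logical(nrow(hits))
  gene_idx <- rep(NA_integer_, nrow(hits))
  half <- seq_length %/% 2L
  for (i in seq_len(nrow(hits))) {
    span <- featureSpanLength(hits$start[i], hits$end[i], seq_length)
    center <- ((hits$start[i] - 1L + (span - 1L) %/% 2L) %% seq_length) + 1L
    for (g in seq_len(nrow(genes))) {
      if (genes$strand[g] != hits$strand[i]) next
      gstart <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      delta <- ((center - gstart + half) %% seq_length) - half
      if (genes$strand[g] == "-") delta <- -delta
      if (delta >= center_range[1L] && delta <= center_range[2L]) {
        keep[i] <- TRUE; gene_idx[i] <- g; break
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$gene <- gene_idx[keep]
  rownames(out) <- NULL
  out
}
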