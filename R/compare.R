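#' CircularAlignment: rotation-normalized pairwise alignment of two replicons
#'
#' @slot ids the two sequence ids.
#' @slot aligned two gapped strings of equal length.
#' @slot identity percent identity over alignment columns.
#' @slot rotation the origin offset applied to the second sequence (nt; the
#'   second sequence was rotated to start at this position before alignment).
#' @slot window_identity data.frame (column, identity) of windowed identity.
#' @export
setClass("CircularAlignment",
  representation(ids = "character", aligned = "character",
                 identity = "numeric", rotation = "integer",
                 window_identity = "data.frame"))

setValidity("CircularAlignment", function(object) {
  if (length(object@aligned) != 2L) return("need exactly two aligned strings")
  if (nchar(object@aligned[1L]) != nchar(object@aligned[2L]))
    return("aligned strings must have equal length")
  TRUE
})

setMethod("show", "CircularAlignment", function(object) {
  cat(sprintf("CircularAlignment %s vs %s: %d columns, %.1f%% identity, rotation %d\n",
              object@ids[1L], object@ids[2L], nchar(object@aligned[1L]),
              object@identity, object@rotation))
})

#' @describeIn circularAlign percent identity accessor.
#' @param x a `CircularAlignment`.
#' @export
alnIdentity <- function(x) x@identity

#' @describeIn circularAlign aligned gapped strings accessor.
#' @export
alnStrings <- function(x) x@aligned

#' PlasmidMSA: a multiple alignment of rotation-normalized replicons
#'
#' @slot aligned named character vector of gapped sequences (equal length).
#' @slot rotations named integer vector: origin offset applied per sequence.
#' @export
setClass("PlasmidMSA",
  representation(aligned = "character", rotations = "integer"))

setValidity("PlasmidMSA", function(object) {
  if (length(unique(nchar(object@aligned))) > 1L)
    return("aligned sequences must have equal length")
  if (is.null(names(object@aligned))) return("aligned sequences must be named")
  TRUE
})

setMethod("show", "PlasmidMSA", function(object) {
  cat(sprintf("PlasmidMSA: %d sequences x %d columns\n",
              length(object@aligned), nchar(object@aligned[1L])))
})

#' @export
setMethod("as.matrix", "PlasmidMSA", function(x, ...) {
  do.call(rbind, strsplit(x@aligned, "", fixed = TRUE))
})

# substitution matrix over ACGTN with N scored as mismatch
.nuc_matrix <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

# best rotation of b against a by k-mer offset voting; returns the position
# of b that should become its new origin (1-based), with the winning vote
# count as attribute "votes"
.rotation_vote <- function(a, b, k = 12L, step = 4L) {
  nb <- nchar(b)
  b_ext <- paste0(b, substr(b, 1L, k - 1L))
  bk <- .kmers(b_ext, k)[seq_len(nb)]
  pos_of <- split(seq_len(nb), bk)
  starts <- seq(1L, nchar(a) - k + 1L, by = step)
  ak <- substring(a, starts, starts + k - 1L)
  votes <- integer(nb)
  for (i in seq_along(ak)) {
    hits <- pos_of[[ak[i]]]
    if (is.null(hits)) next
    off <- ((hits - starts[i]) %% nb) + 1L
    votes[off] <- votes[off] + 1L
  }
  out <- if (all(votes == 0L)) 1L else which.max(votes)
  attr(out, "votes") <- max(votes)
  out
}

#' Rotation-aware global alignment of two circular replicons
#'
#' Finds the rotation of `b` that best matches `a` by k-mer offset voting,
#' then computes a global affine-gap alignment (default match +1, mismatch
#' -1, gap opening 5, extension 1; a gap of length L costs `5 + L`).
#' Identity is reported over alignment columns between the first and last
#' column where both sequences have residues.
#'
#' @param a,b [CircularSeq-class] objects (each >= 100 nt).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param allow_n if `FALSE` (default) sequences containing N are rejected;
#'   if `TRUE`, N is scored as a mismatch.
#' @param window window (alignment columns) for the identity series.
#' @param orient `"auto"` (default) also tries the reverse complement of `b`
#'   and keeps the orientation with the stronger k-mer offset vote (useful
#'   when comparing a de novo assembly of unknown strand); `"as-is"` keeps
#'   `b` as given.
#' @return a [CircularAlignment-class] object (slot `rotation` is negative
#'   when `b` was reverse-complemented).
#' @importFrom Biostrings DNAString
#' @export
circularAlign <- function(a, b, match = 1, mismatch = -1, gap_open = 5,
                          gap_extend = 1, allow_n = FALSE, window = 100L,
                          orient = c("auto", "as-is")) {
  orient <- match.arg(orient)
  if (topology(a) != "circular" || topology(b) != "circular")
    stop("both sequences must be circular")
  if (seqLength(a) < 100L || seqLength(b) < 100L)
    stop("sequences below 100 nt: rotation search unreliable")
  if (!allow_n && (grepl("N", residues(a), fixed = TRUE) ||
                   grepl("N", residues(b), fixed = TRUE)))
    stop("sequence contains N (set allow_n = TRUE to score N as mismatch)")
  rot <- .rotation_vote(residues(a), residues(b))
  flipped <- FALSE
  if (orient == "auto") {
    b_rc <- circularSeq(seqId(b), .revcomp(residues(b)), topology(b))
    rot_rc <- .rotation_vote(residues(a), residues(b_rc))
    if (attr(rot_rc, "votes") > attr(rot, "votes")) {
      b <- b_rc; rot <- rot_rc; flipped <- TRUE
    }
  }
  b_rot <- if (rot == 1L) b else rotate(b, as.integer(rot))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(residues(a)), Biostrings::DNAString(residues(b_rot)),
    substitutionMatrix = .nuc_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  sa <- as.character(Biostrings::alignedPattern(pa))
  sb <- as.character(Biostrings::alignedSubject(pa))
  idt <- .identity_from_aligned(sa, sb)
  new("CircularAlignment", ids = c(seqId(a), seqId(b)), aligned = c(sa, sb),
      identity = idt,
      rotation = as.integer(rot) * (if (flipped) -1L else 1L),
      window_identity = .window_identity(sa, sb, window))
}

.window_identity <- function(sa, sb, window = 100L) {
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  n <- length(ca)
  starts <- seq(1L, n, by = window)
  idt <- vapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    100 * sum(ca[s:e] == cb[s:e] & ca[s:e] != "-") / (e - s + 1L)
  }, numeric(1L))
  data.frame(column = starts, identity = idt)
}

#' Progressive multiple alignment of a circular plasmid family
#'
#' All sequences are rotation-normalized against the first by k-mer offset
#' voting, then aligned. With two sequences the package's own affine-gap
#' aligner is used; with three or more, alignment is delegated to MAFFT,
#' the standard progressive aligner, run deterministically.
#'
#' @param seqs named list of [CircularSeq-class] objects (>= 2).
#' @return a [PlasmidMSA-class] object.
#' @export
progressiveMsa <- function(seqs) {
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  ids <- vapply(seqs, seqId, character(1L))
  names(seqs) <- ids
  rots <- c(1L, vapply(seqs[-1L], function(s)
    .rotation_vote(residues(seqs[[1L]]), residues(s)), integer(1L)))
  names(rots) <- ids
  rotated <- lapply(ids, function(id) {
    s <- seqs[[id]]
    if (rots[[id]] == 1L || topology(s) != "circular") s else rotate(s, rots[[id]])
  })
  names(rotated) <- ids
  if (length(seqs) == 2L) {
    al <- circularAlign(rotated[[1L]], rotated[[2L]], orient = "as-is")
    aligned <- setNames(al@aligned, ids)
    # record total rotation applied to the second sequence
    n2 <- seqLength(seqs[[2L]])
    rots[2L] <- (((rots[2L] - 1L) + (al@rotation - 1L)) %% n2) + 1L
    return(new("PlasmidMSA", aligned = aligned, rotations = rots))
  }
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; required for >= 3 sequences")
  infile <- tempfile(fileext = ".fa"); outfile <- tempfile(fileext = ".fa")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(unlist(lapply(rotated, function(s)
    c(paste0(">", seqId(s)), residues(s)))), infile)
  status <- system2("mafft", c("--retree", "2", "--maxiterate", "0",
                               "--quiet", shQuote(infile)),
                    stdout = outfile, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- Biostrings::readDNAStringSet(outfile)
  aligned <- setNames(toupper(as.character(aln)), names(aln))[ids]
  new("PlasmidMSA", aligned = aligned, rotations = rots)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' Distance is `1 - identity` where identity is computed per pair over
#' columns where at least one of the two sequences has a residue, after
#' dropping columns gapped in all sequences.
#'
#' @param msa a [PlasmidMSA-class].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distFromMsa <- function(msa) {
  m <- as.matrix(msa)
  m <- m[, colSums(m != "-") > 0L, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa@aligned), names(msa@aligned)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    valid <- m[i, ] != "-" | m[j, ] != "-"
    idt <- sum(m[i, valid] == m[j, valid] & m[i, valid] != "-") / sum(valid)
    d[i, j] <- d[j, i] <- 1 - idt
  }
  d
}

#' Mean percent identity of a multiple alignment within a region
#'
#' The region is given in the (ungapped, rotation-normalized) coordinates of
#' the reference sequence (the MSA's first row) and mapped to alignment
#' columns; identity is then averaged over all sequence pairs in those
#' columns.
#'
#' @param msa a [PlasmidMSA-class].
#' @param start,end 1-based inclusive region in reference coordinates
#'   (`start <= end`).
#' @return mean percent identity over pairs.
#' @export
regionSimilarity <- function(msa, start, end) {
  m <- as.matrix(msa)
  ref <- m[1L, ]
  refpos <- cumsum(ref != "-")
  cols <- which(refpos >= start & refpos <= end)
  if (!length(cols)) stop("region maps to no alignment columns")
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    xi <- m[i, cols]; xj <- m[j, cols]
    valid <- xi != "-" | xj != "-"
    if (!any(valid)) next
    vals <- c(vals, 100 * sum(xi[valid] == xj[valid] & xi[valid] != "-") / sum(valid))
  }
  mean(vals)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Canonical NJ (Saitou-Nei, as implemented in \pkg{ape}) on the MSA
#' distance matrix, with support values from resampling alignment columns
#' with replacement (default 100 replicates). Negative branch lengths are
#' clamped to zero with a warning. Deterministic given `seed`.
#'
#' @param msa a [PlasmidMSA-class], or a symmetric distance matrix (in which
#'   case no bootstrap is possible and `bootstrap_n` must be 0).
#' @param bootstrap_n number of bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @return an `ape::phylo`; node labels carry bootstrap percentages.
#' @export
njTree <- function(msa, bootstrap_n = 100L, seed = 1L) {
  if (is.matrix(msa) && !is(msa, "PlasmidMSA")) {
    if (bootstrap_n > 0L)
      stop("bootstrap requires the alignment, not just a distance matrix")
    d <- msa
    tree <- ape::nj(stats::as.dist(d))
    return(.clamp_branches(tree))
  }
  d <- distFromMsa(msa)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  tree <- .clamp_branches(ape::nj(stats::as.dist(d)))
  if (bootstrap_n > 0L) {
    m <- as.matrix(msa)
    set.seed(seed)
    boot_trees <- vector("list", bootstrap_n)
    for (b in seq_len(bootstrap_n)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      msab <- new("PlasmidMSA",
                  aligned = setNames(apply(mb, 1L, paste, collapse = ""),
                                     rownames(mb)),
                  rotations = msa@rotations)
      boot_trees[[b]] <- suppressWarnings(
        .clamp_branches(ape::nj(stats::as.dist(distFromMsa(msab)))))
    }
    class(boot_trees) <- "multiPhylo"
    counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- round(100 * counts / bootstrap_n)
  }
  tree
}

.clamp_branches <- function(tree) {
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' All-pairs circular alignment identity matrix
#'
#' @param seqs named list of [CircularSeq-class].
#' @param ... forwarded to [circularAlign()].
#' @return list with `identity` (percent matrix) and `alignments`
#'   (list of [CircularAlignment-class] keyed `"idA|idB"`).
#' @export
pairwiseIdentityMatrix <- function(seqs, ...) {
  ids <- vapply(seqs, seqId, character(1L))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  alns <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- circularAlign(seqs[[i]], seqs[[j]], ...)
    m[i, j] <- m[j, i] <- al@identity
    alns[[paste0(ids[i], "|", ids[j])]] <- al
  }
  list(identity = m, alignments = alns)
}
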