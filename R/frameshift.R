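# Nearest-neighbor RNA stem-loop thermodynamics (37 C, kcal/mol).
# Watson-Crick stack parameters follow the Turner-lab 10-parameter set
# (Xia et al. 1998); stacks involving G:U wobble pairs use a simplified
# two-level approximation (one wobble pair -1.4, two wobble pairs -0.5),
# adequate for ranking candidate stem-loops downstream of frameshift sites.
# Hairpin-loop initiation penalties are the Turner length table, Jacobson-
# Stockmayer extrapolated beyond 9 nt.

.WC_STACK <- local({
  # key: paste0(pair1, pair2) where pair1 = (i,j), pair2 = (i+1, j-1),
  # written 5'->3' on the top strand: "AU" means A:U pair
  v <- c("AU:AU" = -0.93, "AU:UA" = -1.10, "UA:AU" = -1.33,
         "CG:UA" = -2.08, "CG:AU" = -2.11, "GC:UA" = -2.24,
         "GC:AU" = -2.35, "CG:GC" = -2.36, "GC:CG" = -3.42,
         "CG:CG" = -3.26, "GC:GC" = -3.26, "UA:UA" = -0.93,
         "UA:GC" = -2.11, "UA:CG" = -2.35, "AU:GC" = -2.08,
         "AU:CG" = -2.24, "UA:UA" = -0.93)
  # symmetry: stack((i,j),(i+1,j-1)) == stack read from the other strand
  v
})

.PAIRABLE <- c("AU" = TRUE, "UA" = TRUE, "CG" = TRUE, "GC" = TRUE,
               "GU" = TRUE, "UG" = TRUE)

.pairable <- function(a, b) isTRUE(.PAIRABLE[paste0(a, b)] == TRUE)

.stack_energy <- function(a1, b1, a2, b2) {
  # pair1 = a1:b1 (outer), pair2 = a2:b2 (inner, stacked on top)
  p1 <- paste0(a1, b1); p2 <- paste0(a2, b2)
  gu1 <- p1 %in% c("GU", "UG"); gu2 <- p2 %in% c("GU", "UG")
  if (gu1 && gu2) return(-0.5)
  if (gu1 || gu2) return(-1.4)
  e <- .WC_STACK[paste0(p1, ":", p2)]
  if (!is.na(e)) return(unname(e))
  # read the stack from the other strand: (b2,a2) outer, (b1,a1) inner
  e <- .WC_STACK[paste0(b2, a2, ":", b1, a1)]
  if (!is.na(e)) return(unname(e))
  stop("missing stack parameter for ", p1, ":", p2)
}

.HAIRPIN_LOOP <- c(NA, NA, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)

.hairpin_loop_penalty <- function(n) {
  if (n < 3L) return(Inf)
  if (n <= 9L) return(.HAIRPIN_LOOP[n])
  .HAIRPIN_LOOP[9L] + 1.75 * 0.616 * log(n / 9)
}

#' Hairpin: a single stem-loop with its free energy
#'
#' @slot sequence the (RNA-sense) subsequence analyzed.
#' @slot stem_pairs data.frame (pos5, pos3) of paired positions, outermost
#'   first (1-based within `sequence`).
#' @slot loop integer c(start, end) of the unpaired loop.
#' @slot dG free energy in kcal/mol at 37 C (negative = stable).
#' @export
setClass("Hairpin",
  representation(sequence = "character", stem_pairs = "data.frame",
                 loop = "integer", dG = "numeric"))

setValidity("Hairpin", function(object) {
  if (nrow(object@stem_pairs)) {
    if (object@loop[2L] - object@loop[1L] + 1L < 3L)
      return("hairpin loop must be >= 3 nt")
  }
  if (!is.finite(object@dG)) return("dG must be finite")
  TRUE
})

setMethod("show", "Hairpin", function(object) {
  cat(sprintf("Hairpin: %d bp stem, %d nt loop, dG = %.2f kcal/mol\n",
              nrow(object@stem_pairs),
              if (nrow(object@stem_pairs)) object@loop[2L] - object@loop[1L] + 1L else 0L,
              object@dG))
})

#' @describeIn hairpinEnergy free-energy accessor (kcal/mol).
#' @param x a `Hairpin`.
#' @export
hairpinDG <- function(x) x@dG

# lookup tables for the vectorized DP: all 2-mer pairabilities and all
# 4-mer (outer pair + inner pair) stack energies
.PAIR_OK <- local({
  b <- c("A", "C", "G", "U")
  keys <- as.vector(outer(b, b, paste0))
  setNames(keys %in% c("AU", "UA", "CG", "GC", "GU", "UG"), keys)
})

.STACK_TABLE <- local({
  b <- c("A", "C", "G", "U")
  grid <- expand.grid(a1 = b, b1 = b, a2 = b, b2 = b,
                      stringsAsFactors = FALSE)
  keys <- paste0(grid$a1, grid$b1, grid$a2, grid$b2)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    p1 <- paste0(grid$a1[i], grid$b1[i]); p2 <- paste0(grid$a2[i], grid$b2[i])
    if (!.PAIR_OK[[p1]] || !.PAIR_OK[[p2]]) return(Inf)
    .stack_energy(grid$a1[i], grid$b1[i], grid$a2[i], grid$b2[i])
  }, numeric(1L))
  setNames(vals, keys)
})

# DP over all contiguous-stem hairpin decompositions of chars[1..n] (RNA
# letters). E[i,j] = best energy of a hairpin closed by pair (i,j).
.hairpin_dp <- function(chars) {
  n <- length(chars)
  idx_all <- seq_len(n)
  # stack key (i,j) -> outer pair (i,j) with inner pair (i+1, j-1)
  keymat <- outer(idx_all, idx_all, function(i, j)
    paste0(chars[i], chars[j], chars[pmin(i + 1L, n)], chars[pmax(j - 1L, 1L)]))
  STK <- matrix(.STACK_TABLE[keymat], n, n)
  POK <- matrix(.PAIR_OK[outer(idx_all, idx_all, function(i, j)
    paste0(chars[i], chars[j]))], n, n)
  E <- matrix(Inf, n, n)
  for (span in seq(5L, n)) {          # need >= 3 loop nt inside one pair
    i <- seq_len(n - span + 1L)
    j <- i + span - 1L
    ij <- cbind(i, j)
    inner <- E[cbind(i + 1L, j - 1L)]
    val <- pmin(.hairpin_loop_penalty(span - 2L), STK[ij] + inner)
    E[ij] <- ifelse(POK[ij], val, Inf)
  }
  E
}

# traceback of the best hairpin closed at (i,j)
.hairpin_trace <- function(E, chars, i, j) {
  pairs <- NULL
  repeat {
    pairs <- rbind(pairs, c(i, j))
    loop_pen <- .hairpin_loop_penalty(j - i - 1L)
    if (isTRUE(all.equal(E[i, j], loop_pen)) ||
        !is.finite(E[i + 1L, j - 1L])) break
    i <- i + 1L; j <- j - 1L
  }
  list(pairs = pairs, loop = c(pairs[nrow(pairs), 1L] + 1L,
                               pairs[nrow(pairs), 2L] - 1L))
}

#' Minimum-energy single stem-loop of an RNA (or DNA) subsequence
#'
#' Finds the most stable single hairpin (contiguous stem of Watson-Crick or
#' G:U pairs enclosing a terminal loop of >= 3 nt) by dynamic programming
#' over all stem/loop decompositions, using nearest-neighbor stacking
#' energies and hairpin-loop initiation penalties at 37 C. Multiloops and
#' bulges are outside the model: the target application is the short
#' stem-loop expected just downstream of a -1 ribosomal frameshift site.
#'
#' @param x character string (10-200 nt); T is read as U.
#' @param start_max optional latest allowed 5' start of the stem (1-based),
#'   used to demand the hairpin begin close downstream of a slippery site.
#' @return a [Hairpin-class]; when no hairpin has negative energy the object
#'   has an empty stem and `dG = 0`.
#' @export
hairpinEnergy <- function(x, start_max = NULL) {
  x <- toupper(x)
  n <- nchar(x)
  if (n < 10L || n > 200L) stop("sequence length must be in [10, 200] nt")
  chars <- strsplit(chartr("T", "U", x), "", fixed = TRUE)[[1L]]
  E <- .hairpin_dp(chars)
  if (!is.null(start_max)) E[setdiff(seq_len(n), seq_len(start_max)), ] <- Inf
  best <- which(E == min(E), arr.ind = TRUE)
  if (!is.finite(min(E)) || min(E) >= 0) {
    return(new("Hairpin", sequence = x,
               stem_pairs = data.frame(pos5 = integer(0), pos3 = integer(0)),
               loop = c(NA_integer_, NA_integer_), dG = 0))
  }
  i <- best[1L, 1L]; j <- best[1L, 2L]
  tr <- .hairpin_trace(E, chars, i, j)
  new("Hairpin", sequence = x,
      stem_pairs = data.frame(pos5 = tr$pairs[, 1L], pos3 = tr$pairs[, 2L]),
      loop = as.integer(tr$loop), dG = min(E))
}

#' Scan a CDS for -1 ribosomal frameshift slippery sites
#'
#' Searches the mRNA-sense CDS for heptamers of the canonical slippery form
#' `X XXY YYZ` (bases 1-3 identical, bases 4-6 identical and A/U, base 7 not
#' G), aligned so that codons 2-4 and 5-7 are in the zero frame; up to
#' `max_deviation` violations of these constraints are tolerated (the
#' permissive "similar to" reading used for halovirus-like sites). Each site
#' is paired with the best stem-loop whose stem begins 2-12 nt downstream.
#' Coordinates are reported on the plus strand of the deposited sequence,
#' even for reverse-strand genes.
#'
#' @param x a [CircularSeq-class].
#' @param cds one-row gene table: `start,end,strand` of the CDS.
#' @param max_deviation tolerated deviations from the strict pattern.
#' @param hairpin_span nt of downstream context folded for the hairpin.
#' @return data.frame: plus-strand heptamer interval, heptamer, mRNA offset,
#'   deviations, hairpin distance and `dG` (NA when no stable hairpin).
#' @export
findSlipperySites <- function(x, cds, max_deviation = 1L, hairpin_span = 45L) {
  mrna <- subseqCirc(x, cds$start, cds$end, cds$strand)
  L <- nchar(mrna)
  out <- NULL
  for (p in seq(3L, L - 6L, by = 3L)) {
    h <- substr(mrna, p, p + 6L)
    b <- strsplit(h, "", fixed = TRUE)[[1L]]
    dev <- sum(b[2L] != b[1L], b[3L] != b[1L], !(b[4L] %in% c("A", "T")),
               b[5L] != b[4L], b[6L] != b[4L], b[7L] == "G")
    if (dev > max_deviation) next
    # best hairpin starting 2-12 nt downstream of the heptamer
    win_start <- p + 7L + 2L
    win_end <- min(L, p + 7L + 12L + hairpin_span)
    dg <- NA_real_; hp_dist <- NA_integer_
    if (win_end - win_start + 1L >= 10L) {
      hp <- hairpinEnergy(substr(mrna, win_start, win_end), start_max = 11L)
      if (nrow(hp@stem_pairs)) {
        dg <- hp@dG
        hp_dist <- 2L + hp@stem_pairs$pos5[1L] - 1L   # nt after heptamer end
      }
    }
    # map heptamer to plus-strand coordinates
    n <- seqLength(x)
    if (cds$strand == "+") {
      ps <- ((cds$start + p - 2L) %% n) + 1L
      pe <- ((cds$start + p + 4L) %% n) + 1L
    } else {
      pe <- ((cds$end - p) %% n) + 1L
      ps <- ((cds$end - p - 6L) %% n) + 1L
    }
    out <- rbind(out, data.frame(
      seq_id = seqId(x), start = as.integer(ps), end = as.integer(pe),
      strand = cds$strand, type = "slippery_site", family = NA_character_,
      attributes = sprintf("heptamer=%s", h), heptamer = h,
      mrna_pos = as.integer(p), deviations = as.integer(dev),
      hairpin_distance = hp_dist, dG = dg, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), family = character(0),
                      attributes = character(0), heptamer = character(0),
                      mrna_pos = integer(0), deviations = integer(0),
                      hairpin_distance = integer(0), dG = numeric(0))
  rownames(out) <- NULL
  out
}

#' Internal stop codons of an annotated CDS
#'
#' @param x a [CircularSeq-class].
#' @param cds one-row gene table: `start,end,strand`.
#' @return data.frame of internal stops: mRNA codon index and plus-strand
#'   nt interval of each stop codon (excluding the terminal stop).
#' @export
internalStops <- function(x, cds) {
  mrna <- subseqCirc(x, cds$start, cds$end, cds$strand)
  ncod <- nchar(mrna) %/% 3L
  starts <- seq(1L, by = 3L, length.out = ncod)
  cods <- substring(mrna, starts, starts + 2L)
  idx <- which(.is_stop(cods))
  idx <- idx[idx < ncod]
  n <- seqLength(x)
  if (!length(idx))
    return(data.frame(codon = integer(0), start = integer(0), end = integer(0)))
  mpos <- starts[idx]
  if (cds$strand == "+") {
    s <- ((cds$start + mpos - 2L) %% n) + 1L
    e <- ((cds$start + mpos) %% n) + 1L
  } else {
    e <- ((cds$end - mpos) %% n) + 1L
    s <- ((cds$end - mpos - 2L) %% n) + 1L
  }
  data.frame(codon = idx, start = as.integer(s), end = as.integer(e))
}

#' Rescue an interrupted CDS by single-base insertion
#'
#' For a CDS carrying an internal stop (a pseudogene candidate, or the
#' product of a sequencing/replication slip), tests the insertion of each of
#' the four bases between every pair of adjacent positions and reports the
#' insertions that restore an end-to-end reading frame: no internal stop,
#' and a protein length within `len_tol` (default 10%) of
#' `consensus_len` (when given) or of the interrupted CDS's own nominal
#' length. Within a homopolymer run all insertion points are equivalent, so
#' a cluster of adjacent rescue positions is the expected signature.
#'
#' @param x a [CircularSeq-class].
#' @param cds one-row gene table: `start,end,strand`.
#' @param consensus_len expected protein length (aa) from the gene family.
#' @param len_tol relative length tolerance.
#' @return data.frame: `after_mrna_pos` (insertion between this mRNA
#'   position and the next), `plus_pos` (plus-strand coordinate of that
#'   position), `base`, `restored_len` (aa). Empty (with a `note`
#'   attribute) when the CDS has no internal stop.
#' @export
rescueOrfByInsertion <- function(x, cds, consensus_len = NULL, len_tol = 0.1) {
  mrna <- subseqCirc(x, cds$start, cds$end, cds$strand)
  L <- nchar(mrna)
  empty <- data.frame(after_mrna_pos = integer(0), plus_pos = integer(0),
                      base = character(0), restored_len = integer(0))
  istops <- internalStops(x, cds)
  if (!nrow(istops)) {
    attr(empty, "note") <- "CDS has no internal stop; nothing to rescue"
    return(empty)
  }
  if (is.null(consensus_len)) consensus_len <- L %/% 3L - 1L
  lo <- ceiling(consensus_len * (1 - len_tol))
  hi <- floor(consensus_len * (1 + len_tol))
  n <- seqLength(x)
  out <- NULL
  # an insertion downstream of the first internal stop cannot remove it
  first_stop_mrna <- 3L * istops$codon[1L] - 2L
  for (i in seq_len(min(L - 1L, first_stop_mrna + 1L))) {
    head <- substr(mrna, 1L, i)
    tail <- substr(mrna, i + 1L, L)
    for (b in c("A", "C", "G", "T")) {
      prot <- .translate(paste0(head, b, tail))
      stop_at <- regexpr("*", prot, fixed = TRUE)
      plen <- if (stop_at > 0L) stop_at - 1L else nchar(prot)
      # full-length restoration: first stop is the terminal codon
      if (stop_at > 0L && stop_at == nchar(prot) && plen >= lo && plen <= hi) {
        plus_pos <- if (cds$strand == "+") ((cds$start + i - 2L) %% n) + 1L
                    else ((cds$end - i) %% n) + 1L
        out <- rbind(out, data.frame(after_mrna_pos = i,
                                     plus_pos = as.integer(plus_pos),
                                     base = b, restored_len = plen,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  out
}
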