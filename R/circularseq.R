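#' CircularSeq: a circular (or linear) DNA replicon
#'
#' Immutable container for a small replicon sequence with explicit topology.
#' Coordinates throughout the package are 1-based and inclusive, matching the
#' convention used for small haloarchaeal plasmids (e.g. "nt 5745-5747").
#' On a circular sequence a feature may span the origin, in which case its
#' `end` is smaller than its `start` and extraction wraps around position 1.
#'
#' @slot id single sequence identifier.
#' @slot residues uppercase DNA string over A,C,G,T,N.
#' @slot topology `"circular"` (default for plasmids) or `"linear"`.
#'
#' @examples
#' p <- circularSeq("p1", "ACGTACGT")
#' seqLength(p)
#' subseqCirc(p, 7, 2)   # wraps through the origin
#' @aliases CircularSeq
#' @export
setClass("CircularSeq",
  representation(id = "character", residues = "character", topology = "character"),
  prototype(topology = "circular"))

setValidity("CircularSeq", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@residues) != 1L || nchar(object@residues) < 1L)
    return("'residues' must be a single non-empty string")
  if (regexpr("[^ACGTN]", object@residues) > 0L)
    return("residues outside the {A,C,G,T,N} alphabet")
  if (!object@topology %in% c("circular", "linear"))
    return("topology must be 'circular' or 'linear'")
  TRUE
})

#' Construct a CircularSeq
#'
#' @param id sequence identifier.
#' @param residues DNA string (lowercase accepted, uppercased on input).
#' @param topology `"circular"` or `"linear"`.
#' @return a [CircularSeq-class] object.
#' @export
circularSeq <- function(id, residues, topology = "circular") {
  residues <- toupper(as.character(residues))
  .check_alphabet(residues, id)
  new("CircularSeq", id = id, residues = residues, topology = topology)
}

#' @describeIn circularSeq sequence identifier accessor.
#' @param x a `CircularSeq`.
#' @export
seqId <- function(x) x@id

#' @describeIn circularSeq topology accessor.
#' @export
topology <- function(x) x@topology

#' @describeIn circularSeq sequence length in nt.
#' @export
seqLength <- function(x) nchar(x@residues)

#' @export
#' @describeIn circularSeq residues as a plain character string.
residues <- function(x) x@residues

setMethod("show", "CircularSeq", function(object) {
  cat(sprintf("CircularSeq '%s': %d nt, %s, GC %.1f%%\n",
              object@id, nchar(object@residues), object@topology,
              100 * .gc_count(object@residues) / nchar(object@residues)))
})

#' @export
setMethod("as.character", "CircularSeq", function(x) x@residues)

#' Extract a subsequence with circular wrap
#'
#' Inclusive 1-based extraction. On a circular sequence `end < start` wraps
#' through the origin; on a linear sequence this is an error. `strand = "-"`
#' returns the reverse complement of the extracted plus-strand window.
#'
#' @param x a [CircularSeq-class].
#' @param start,end 1-based inclusive coordinates in `[1, seqLength(x)]`.
#' @param strand `"+"` or `"-"`.
#' @return character string of the extracted residues.
#' @export
subseqCirc <- function(x, start, end, strand = "+") {
  n <- seqLength(x)
  start <- .stopifnot_scalar_int(start, "start")
  end <- .stopifnot_scalar_int(end, "end")
  if (start < 1L || start > n || end < 1L || end > n)
    stop("coordinates outside [1, length]")
  if (end >= start) {
    s <- substr(x@residues, start, end)
  } else {
    if (x@topology != "circular")
      stop("origin-spanning extraction requested on a linear sequence")
    s <- paste0(substr(x@residues, start, n), substr(x@residues, 1L, end))
  }
  if (strand == "-") s <- .revcomp(s)
  s
}

#' Rotate a circular sequence to a new origin
#'
#' Returns the same replicon linearized so that position `new_origin` of the
#' input becomes position 1. Rotation preserves length and the multiset of
#' k-mers read around the circle.
#'
#' @param x a circular [CircularSeq-class].
#' @param new_origin 1-based position that becomes the first residue.
#' @return a rotated `CircularSeq` with the same id.
#' @export
rotate <- function(x, new_origin) {
  if (x@topology == "linear") stop("cannot rotate a linear sequence")
  n <- seqLength(x)
  k <- ((.stopifnot_scalar_int(new_origin, "new_origin") - 1L) %% n) + 1L
  if (k == 1L) return(x)
  new("CircularSeq", id = x@id, topology = x@topology,
      residues = paste0(substr(x@residues, k, n), substr(x@residues, 1L, k - 1L)))
}

#' Length of a (possibly origin-spanning) feature interval
#'
#' @param start,end 1-based inclusive coordinates.
#' @param seq_length replicon length.
#' @return interval length in nt (never 0; a full wrap is the whole replicon).
#' @export
featureSpanLength <- function(start, end, seq_length) {
  ((end - start) %% seq_length) + 1L
}
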