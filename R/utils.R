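# Internal string helpers shared across modules. Sequences are handled as
# plain uppercase character strings internally; the S4 layer wraps them.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @importFrom methods new is validObject slot
#' @importFrom stats setNames quantile
NULL

.revcomp <- function(x) {
  # reverse complement of a plain character string (N self-complements)
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.check_alphabet <- function(x, id = "<sequence>") {
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("record '%s' contains illegal residue '%s' at position %d",
                 id, substr(x, bad, bad), bad), call. = FALSE)
  }
  invisible(TRUE)
}

# vector of all substrings of length k (1-based sliding window, step 1)
.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0L))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

.CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- strsplit(paste0(
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLL",
    "EDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF"), "")[[1L]]
  setNames(aa, codons)
})

# standard-code translation of an in-frame character string; trailing partial
# codon dropped; codons containing N translate to "X"
.translate <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n)
  cods <- substring(x, starts, starts + 2L)
  aa <- unname(.CODON_TABLE[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# sample length n character string with a given GC fraction
.random_dna <- function(n, gc = 0.5, rng = NULL) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.gc_count <- function(x) {
  counts <- table(factor(strsplit(x, "", fixed = TRUE)[[1L]], levels = DNA_ALPHABET))
  unname(counts[["G"]] + counts[["C"]])
}

# replace substring in-place (1-based inclusive), returning the new string
.str_assign <- function(x, start, end, value) {
  paste0(substr(x, 1L, start - 1L), value, substr(x, end + 1L, nchar(x)))
}

.stopifnot_scalar_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  as.integer(x)
}
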