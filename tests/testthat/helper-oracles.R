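# Independent alignment oracles (plain-R), kept free of the package's own
# alignment code paths. Gap convention: a gap of length L costs open + L*ext.

random_dna_str <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# Gotoh global alignment score with affine gaps
gotoh_global <- function(a, b, score_fun, open, ext) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in b (A aligned to gap)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in a
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- score_fun(A[i], B[j])
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext, Y[i + 1L, j] - ext)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Smith-Waterman local alignment score with affine gaps
sw_local <- function(a, b, score_fun, open, ext) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- score_fun(A[i], B[j])
    M[i + 1L, j + 1L] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext, Y[i + 1L, j] - ext)
    best <- max(best, M[i + 1L, j + 1L])
  }
  best
}

# exhaustive global alignment score by path enumeration (tiny inputs only);
# validates the Gotoh oracle itself
exhaustive_global <- function(a, b, score_fun, open, ext) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, score_fun(A[i], B[j]) + rec(i + 1L, j + 1L, "M"))
    if (i <= length(A))
      best <- max(best, -(if (state == "X") ext else open + ext) +
                    rec(i + 1L, j, "X"))
    if (j <= length(B))
      best <- max(best, -(if (state == "Y") ext else open + ext) +
                    rec(i, j + 1L, "Y"))
    best
  }
  rec(1L, 1L, "M")
}

nuc_score <- function(x, y) if (x == y) 1 else -1

blosum62_score <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62
  function(x, y) B[x, y]
})

# brute-force minimum free energy over all contiguous-stem hairpins
brute_hairpin <- function(x) {
  ch <- strsplit(chartr("T", "U", toupper(x)), "")[[1L]]
  n <- length(ch)
  pair_ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  stk <- circplasmid:::.STACK_TABLE
  loopp <- circplasmid:::.hairpin_loop_penalty
  best <- 0
  for (i in 1:(n - 4L)) for (j in (i + 4L):n) {
    hmax <- (j - i - 3L) %/% 2L + 1L
    for (h in seq_len(hmax)) {
      ok <- TRUE
      for (t in 0:(h - 1L)) if (!pair_ok(ch[i + t], ch[j - t])) { ok <- FALSE; break }
      if (!ok) break
      loop <- (j - h) - (i + h) + 1L
      if (loop < 3L) break
      e <- loopp(loop)
      if (h > 1L) for (t in 0:(h - 2L))
        e <- e + stk[[paste0(ch[i + t], ch[j - t], ch[i + t + 1L], ch[j - t - 1L])]]
      best <- min(best, e)
    }
  }
  best
}

# brute-force IUPAC scan on the plus strand (circular)
brute_iupac_scan <- function(seqstr, pat) {
  iup <- circplasmid:::.IUPAC_SET
  n <- nchar(seqstr); L <- nchar(pat)
  s2 <- paste0(seqstr, substr(seqstr, 1L, L - 1L))
  pc <- strsplit(pat, "")[[1L]]
  hits <- integer(0L)
  for (p in seq_len(n)) {
    w <- strsplit(substr(s2, p, p + L - 1L), "")[[1L]]
    if (all(mapply(function(a, b) a %in% iup[[b]], w, pc))) hits <- c(hits, p)
  }
  hits
}
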