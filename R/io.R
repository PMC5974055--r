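#' Read replicon sequences from FASTA
#'
#' Reads a (multi-)FASTA file into a list of [CircularSeq-class] objects.
#' Topology is taken from a `topology=circular|linear` keyword in the header
#' description and defaults to circular, since the replicons this package
#' targets are circular plasmids. Lowercase residues are uppercased; residues
#' outside A,C,G,T,N raise an error naming the record and position.
#'
#' @param path FASTA file path.
#' @return named list of `CircularSeq` objects.
#' @importFrom Biostrings readBStringSet
#' @export
readFastaCircular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings so that residues outside the DNA alphabet are
  # reported as errors instead of being silently dropped
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(header, "[[:space:]]+")[[1L]]
    id <- toks[1L]
    topo <- "circular"
    m <- grep("^topology=", toks, value = TRUE)
    if (length(m)) topo <- sub("^topology=", "", m[1L])
    out[[i]] <- circularSeq(id, as.character(set[[i]]), topo)
  }
  names(out) <- vapply(out, seqId, character(1L))
  out
}

#' Write replicon sequences to FASTA
#'
#' The topology is recorded in the header as `topology=...` so that
#' `readFastaCircular(writeFastaCircular(x))` round-trips.
#'
#' @param seqs list of [CircularSeq-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaCircular <- function(seqs, path) {
  if (is(seqs, "CircularSeq")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    c(sprintf(">%s topology=%s", seqId(s), topology(s)),
      substring(residues(s), seq(1L, seqLength(s), 70L),
                pmin(seq(1L, seqLength(s), 70L) + 69L, seqLength(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated feature table
#'
#' Features are plain data frames with 1-based inclusive coordinates; on a
#' circular replicon `end < start` denotes an origin-spanning feature. This
#' representation (rather than `GRanges`) keeps origin-spanning intervals
#' first-class.
#'
#' @param seq_id replicon id (character).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param type one of `CDS`, `motif`, `CIS`, `inverted_repeat`,
#'   `slippery_site`, `region`.
#' @param family optional gene-family label (`F1`..`F3.2`, `R4`..`R7`,
#'   `other`) or `NA`.
#' @param attributes free-form `key=value;...` string (GFF3 column 9 style).
#' @return `data.frame` with one row per feature.
#' @export
featureTable <- function(seq_id, start, end, strand, type,
                         family = NA_character_, attributes = "") {
  n <- length(seq_id)
  family <- rep(as.character(family), length.out = n)
  attributes <- rep(as.character(attributes), length.out = n)
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), type = as.character(type),
                   family = as.character(family),
                   attributes = as.character(attributes),
                   stringsAsFactors = FALSE)
  validateFeatures(df)
  df
}

FEATURE_TYPES <- c("CDS", "motif", "CIS", "inverted_repeat",
                   "slippery_site", "region", "hairpin")

#' Validate a feature table
#'
#' @param features data frame in [featureTable()] layout.
#' @param seqs optional named list of [CircularSeq-class] to check
#'   coordinates against.
#' @return `features`, invisibly; errors on violation.
#' @export
validateFeatures <- function(features, seqs = NULL) {
  req <- c("seq_id", "start", "end", "strand", "type")
  if (!all(req %in% names(features)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  if (nrow(features)) {
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(features$type %in% FEATURE_TYPES))
      stop("unknown feature type(s): ",
           paste(setdiff(features$type, FEATURE_TYPES), collapse = ", "))
    if (any(features$start < 1L) || any(features$end < 1L))
      stop("coordinates must be >= 1")
    if (!is.null(seqs)) {
      for (i in seq_len(nrow(features))) {
        s <- seqs[[features$seq_id[i]]]
        if (is.null(s)) stop("feature references unknown sequence: ",
                             features$seq_id[i])
        n <- seqLength(s)
        if (features$start[i] > n || features$end[i] > n)
          stop(sprintf("feature %d outside sequence '%s' (length %d)",
                       i, features$seq_id[i], n))
        if (features$end[i] < features$start[i] && topology(s) != "circular")
          stop("origin-spanning feature on a linear sequence")
      }
    }
  }
  invisible(features)
}

#' Write features as GFF3
#'
#' Origin-spanning features are emitted as two part-lines sharing one `ID`
#' attribute (the standard GFF3 convention for circular replicons);
#' [readGff3()] reassembles them into single `end < start` rows.
#'
#' @param features feature table ([featureTable()] layout).
#' @param seqs named list of [CircularSeq-class] supplying lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(features, seqs, path) {
  validateFeatures(features, seqs)
  lines <- "##gff-version 3"
  for (s in seqs) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", seqId(s), seqLength(s)))
  }
  gfftype <- function(t) if (t == "CDS") "CDS" else "sequence_feature"
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    id <- sprintf("feat%04d", i)
    attrs <- sprintf("ID=%s", id)
    if (!is.na(f$family) && nzchar(f$family))
      attrs <- paste0(attrs, ";family=", f$family)
    attrs <- paste0(attrs, ";ftype=", f$type)
    if (nzchar(f$attributes)) attrs <- paste0(attrs, ";", f$attributes)
    n <- seqLength(seqs[[f$seq_id]])
    phase <- if (f$type == "CDS") "0" else "."
    if (f$end >= f$start) {
      lines <- c(lines, paste(f$seq_id, "circplasmid", gfftype(f$type),
                              f$start, f$end, ".", f$strand, phase, attrs,
                              sep = "\t"))
    } else {
      lines <- c(lines,
        paste(f$seq_id, "circplasmid", gfftype(f$type), f$start, n, ".",
              f$strand, phase, attrs, sep = "\t"),
        paste(f$seq_id, "circplasmid", gfftype(f$type), 1L, f$end, ".",
              f$strand, phase, attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [writeGff3()]
#'
#' @param path GFF3 path.
#' @return feature table in [featureTable()] layout.
#' @export
readGff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- featureTable(character(0), integer(0), integer(0),
                        character(0), character(0))
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  getattr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1L]]
    if (length(m)) m[3L] else NA_character_
  }
  df <- do.call(rbind, lapply(parts, function(p) {
    a <- p[9L]
    data.frame(seq_id = p[1L], start = as.integer(p[4L]), end = as.integer(p[5L]),
               strand = p[7L], type = getattr(a, "ftype"),
               family = getattr(a, "family"), id = getattr(a, "ID"),
               attributes = a, stringsAsFactors = FALSE)
  }))
  # merge two-part origin-spanning features on shared ID
  out <- NULL
  for (id in unique(df$id)) {
    rows <- df[df$id == id, , drop = FALSE]
    if (nrow(rows) == 2L) {
      first <- rows[which.max(rows$start), ]
      second <- rows[which.min(rows$start), ]
      first$end <- second$end
      rows <- first
    }
    out <- rbind(out, rows)
  }
  out$family[is.na(out$family)] <- NA_character_
  out$attributes <- gsub("(^|;)(ID|ftype|family)=[^;]*", "", out$attributes)
  out$attributes <- gsub("^;+|;+$", "", out$attributes)
  out$id <- NULL
  rownames(out) <- NULL
  validateFeatures(out)
  out
}

#' Write a phylogenetic tree to newick
#'
#' @param tree an `ape::phylo` object (node labels carry bootstrap support).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom utils write.table
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
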