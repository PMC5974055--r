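# The five deposited PL6-family plasmid sequences, when available, live as
# plain FASTA under inst/extdata/accessions/<accession>.fasta. They are tiny
# public records (each < 8 kb) but are not redistributed with the package;
# see the README for how to place them before installing.

ACCESSION_IDS <- c(PL6A = "FR746101", PL6B = "FR746102",
                   `pBAJ9-6` = "LT984491", `pLT53-7` = "LT984489",
                   `pLTMV-6` = "LT991975")

accession_paths <- function() {
  dir <- system.file("extdata", "accessions", package = "circplasmid")
  setNames(file.path(dir, paste0(ACCESSION_IDS, ".fasta")),
           names(ACCESSION_IDS))
}

load_accessions <- function() {
  paths <- accession_paths()
  if (!all(nzchar(dirname(paths))) || !all(file.exists(paths))) return(NULL)
  seqs <- lapply(names(paths), function(nm) {
    s <- readFastaCircular(paths[[nm]])[[1]]
    circularSeq(nm, residues(s), "circular")
  })
  names(seqs) <- names(paths)
  seqs
}

missing_accessions_msg <- paste(
  "deposited accession sequences (FR746101, FR746102, LT984491, LT984489,",
  "LT991975) are not available under inst/extdata/accessions/; these checks",
  "require the public FASTA records to be placed there before installation")
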