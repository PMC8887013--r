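#' Read a protein FASTA into a proteome table
#'
#' Parses a protein FASTA file into a data frame with one row per record.
#' Sequences are upper-cased and a single trailing stop symbol (`*`) is
#' stripped; an internal `*` indicates a broken gene model and is a hard
#' error. Record identifiers are the first whitespace-delimited token of the
#' header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description`, `sequence`, in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "mskl*"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop2("not FASTA content at line 1 of ", path, ": expected '>' header")
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  if (any(ids == ""))
    stop2("empty record id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop2("duplicate protein id(s) in ", path, ": ",
          paste(dup, collapse = ", "))
  seqs <- sub("\\*$", "", seqs)
  if (any(nchar(seqs) == 0L))
    stop2("empty sequence for id(s): ",
          paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("\\*", seqs, fixed = FALSE)
  if (any(bad))
    stop2("internal stop symbol '*' in sequence(s): ",
          paste(ids[bad], collapse = ", "),
          " (internal stops indicate broken gene models)")
  if (any(grepl("\\s", seqs)))
    stop2("whitespace inside sequence(s)")
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a proteome table as FASTA
#'
#' @param proteome Data frame with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteome, path) {
  hdr <- ifelse(nchar(proteome$description) > 0,
                paste(proteome$id, proteome$description),
                proteome$id)
  lines <- as.vector(rbind(paste0(">", hdr), proteome$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA as a named character vector of contig sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that upper-cases and
#' names contigs by the first header token.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}
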