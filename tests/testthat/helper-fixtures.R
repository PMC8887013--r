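# shared fixture builders: everything is generated in code at test time

write_fasta_fixture <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal two-exon gene on its own contig, used by GFF3/intron tests
gff3_fixture <- function(exon1 = c(1, 100), exon2 = c(201, 300),
                         strand = "+", exon_order = c(1, 2),
                         feature = "exon") {
  ex <- list(exon1, exon2)[exon_order]
  lines <- c(
    "##gff-version 3",
    paste("ctg1", "test", "gene", 1, 300, ".", strand, ".", "ID=g1",
          sep = "\t"),
    paste("ctg1", "test", "mRNA", 1, 300, ".", strand, ".",
          "ID=m1;Parent=g1", sep = "\t"),
    vapply(seq_along(ex), function(i)
      paste("ctg1", "test", feature, ex[[i]][1], ex[[i]][2], ".", strand,
            ".", paste0("ID=m1.e", i, ";Parent=m1"), sep = "\t"),
      character(1)))
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

# independent positional-check oracles for the PTS grammars (no regex, no
# shared code with the scanner)
oracle_pts1 <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(NA_character_)
  tri <- substr(seq, n - 2, n)
  p1 <- substr(tri, 1, 1); p2 <- substr(tri, 2, 2); p3 <- substr(tri, 3, 3)
  in_pattern <- p1 %in% c("S", "A", "P") && p2 %in% c("K", "R") &&
    p3 %in% c("L", "M")
  if ((in_pattern && !tri %in% c("AKM", "PKM", "PRM")) || tri == "SRI")
    tri else NA_character_
}

oracle_pts2 <- function(seq, pos2 = c("L", "I"), window = 40) {
  chars <- strsplit(seq, "")[[1]]
  hits <- integer()
  last_start <- min(length(chars), window) - 8
  if (last_start >= 1) for (i in seq_len(last_start)) {
    if (chars[i] == "R" && chars[i + 1] %in% pos2 &&
        chars[i + 7] == "H" && chars[i + 8] == "L")
      hits <- c(hits, i)
  }
  hits
}

random_protein <- function(len, alphabet = strsplit(
  "ACDEFGHIKLMNPQRSTVWYX", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
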