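#' Extract introns from gene models
#'
#' For each mRNA with *n* exons, the *n − 1* introns are the gaps between
#' consecutive exons (exons stored sorted by start). Coordinates are 1-based
#' inclusive on the genomic contig. Donor and acceptor dinucleotides are read
#' in transcription orientation: on the minus strand they come from the
#' reverse complement, so the donor is always the transcription-5' end of the
#' intron.
#'
#' Introns shorter than 4 nt cannot host disjoint donor and acceptor
#' dinucleotides; they are recorded with `boundary_class = "other"` and
#' `too_short = TRUE` rather than dropped (missing boundary letters are
#' padded with `N`). Zero-length gaps (abutting exons) define no interval
#' and are not emitted. An exon extending beyond its contig is a hard error.
#'
#' @param gene_models Exon table from [read_gff3_gene_models()].
#' @param genome Named character vector of contig sequences (see
#'   [read_genome_fasta()]).
#' @return Data frame with one row per intron: `gene_id`, `mrna_id`,
#'   `seq_id`, `start`, `end`, `strand`, `donor`, `acceptor`,
#'   `boundary_class`, `too_short`.
#' @export
extract_introns <- function(gene_models, genome) {
  missing_contig <- setdiff(unique(gene_models$seq_id), names(genome))
  if (length(missing_contig))
    stop2("contig(s) absent from genome: ",
          paste(missing_contig, collapse = ", "))
  clen <- nchar(genome)
  if (any(gene_models$end > clen[gene_models$seq_id]))
    stop2("exon beyond contig end")

  ord <- order(gene_models$mrna_id, gene_models$start)
  gm <- gene_models[ord, , drop = FALSE]
  same <- gm$mrna_id[-1] == gm$mrna_id[-nrow(gm)]
  i <- which(c(same, FALSE))           # row i and i+1 are consecutive exons
  if (length(i) == 0L) return(.empty_introns())

  start <- gm$end[i] + 1L
  end <- gm$start[i + 1L] - 1L
  keep <- end >= start                 # abutting exons leave no intron
  tab <- data.frame(gene_id = gm$gene_id[i], mrna_id = gm$mrna_id[i],
                    seq_id = gm$seq_id[i], start = start, end = end,
                    strand = gm$strand[i],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(tab) == 0L) return(.empty_introns())

  len <- tab$end - tab$start + 1L
  five <- .dinuc(genome, tab$seq_id, tab$start, pmin(tab$start + 1L, tab$end))
  three <- .dinuc(genome, tab$seq_id, pmax(tab$end - 1L, tab$start), tab$end)
  minus <- tab$strand == "-"
  tab$donor <- ifelse(minus, .revcomp2(three), five)
  tab$acceptor <- ifelse(minus, .revcomp2(five), three)
  tab$too_short <- len < 4L
  tab$boundary_class <- ifelse(tab$too_short, "other",
                               classify_intron_boundaries(tab$donor,
                                                          tab$acceptor))
  rownames(tab) <- NULL
  tab
}

.empty_introns <- function() {
  data.frame(gene_id = character(), mrna_id = character(),
             seq_id = character(), start = integer(), end = integer(),
             strand = character(), donor = character(),
             acceptor = character(), boundary_class = character(),
             too_short = logical(), stringsAsFactors = FALSE)
}

.dinuc <- function(genome, seq_id, from, to) {
  out <- substr(genome[seq_id], from, to)
  # pad sub-2nt slices (too-short introns) so boundaries stay in {ACGTN}^2
  formatC(unname(out), width = 2, flag = "-") |>
    gsub(pattern = " ", replacement = "N")
}

.revcomp2 <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste0(substr(x, 2, 2), substr(x, 1, 1)))
}

#' Classify intron boundary dinucleotides
#'
#' `GT`+`AG` is the canonical spliceosomal class; `GC`+`AG` the minor
#' variant; everything else — including any `N` — is `other`.
#'
#' @param donor,acceptor Character vectors of 2-letter dinucleotides in
#'   transcription orientation.
#' @return Character vector: `"GT-AG"`, `"GC-AG"`, or `"other"`.
#' @export
classify_intron_boundaries <- function(donor, acceptor) {
  ifelse(donor == "GT" & acceptor == "AG", "GT-AG",
         ifelse(donor == "GC" & acceptor == "AG", "GC-AG", "other"))
}

#' Summarize intron counts, density and boundary-class fractions
#'
#' Intron density is the total intron count divided by the number of gene
#' units, where the unit depends on `isoform_policy`:
#'
#' * `"all_mrnas"` — every mRNA counts once; all introns counted.
#' * `"longest_isoform"` — only the longest mRNA (by summed exon length) per
#'   gene contributes introns; denominator is the gene count.
#' * `"unique_introns_per_gene"` (default) — distinct intron coordinates per
#'   gene; denominator is the gene count. This avoids double-counting
#'   introns shared between isoforms.
#'
#' @param introns Intron table from [extract_introns()].
#' @param gene_models Exon table from [read_gff3_gene_models()].
#' @param isoform_policy One of the three policies above.
#' @return List of class `intron_summary`: `total_introns`,
#'   `genes_considered`, `density`, `class_fractions` (named numeric, empty
#'   when there are no introns), `isoform_policy`.
#' @export
summarize_intron_stats <- function(introns, gene_models,
                                   isoform_policy = c(
                                     "unique_introns_per_gene",
                                     "all_mrnas", "longest_isoform")) {
  isoform_policy <- match.arg(isoform_policy)
  if (nrow(gene_models) == 0L) stop2("no gene models supplied")

  if (isoform_policy == "all_mrnas") {
    denom <- length(unique(gene_models$mrna_id))
    counted <- introns
  } else if (isoform_policy == "longest_isoform") {
    denom <- length(unique(gene_models$gene_id))
    exlen <- aggregate(gene_models$end - gene_models$start + 1L,
                       by = list(gene_id = gene_models$gene_id,
                                 mrna_id = gene_models$mrna_id), FUN = sum)
    exlen <- exlen[order(exlen$gene_id, -exlen$x, exlen$mrna_id), ]
    keep_mrna <- exlen$mrna_id[!duplicated(exlen$gene_id)]
    counted <- introns[introns$mrna_id %in% keep_mrna, , drop = FALSE]
  } else {
    denom <- length(unique(gene_models$gene_id))
    key <- paste(introns$gene_id, introns$seq_id, introns$start,
                 introns$end, introns$strand)
    counted <- introns[!duplicated(key), , drop = FALSE]
  }
  if (denom == 0L) stop2("zero genes under policy ", isoform_policy)

  total <- nrow(counted)
  fractions <- if (total > 0L)
    table(counted$boundary_class) / total
  else table(character())
  structure(list(total_introns = total, genes_considered = denom,
                 density = total / denom,
                 class_fractions = setNames(as.numeric(fractions),
                                            names(fractions)),
                 isoform_policy = isoform_policy),
            class = "intron_summary")
}

#' @export
print.intron_summary <- function(x, ...) {
  cat("Intron summary (policy:", x$isoform_policy, ")\n")
  cat("  introns:", x$total_introns, " genes:", x$genes_considered,
      " density:", format(x$density, digits = 4), "introns/gene\n")
  if (length(x$class_fractions)) {
    cat("  boundary classes:\n")
    for (cl in names(x$class_fractions))
      cat(sprintf("    %-6s %6.2f%%\n", cl, 100 * x$class_fractions[[cl]]))
  }
  invisible(x)
}

#' Write introns as a BED-like TSV
#'
#' Columns: `seq_id`, 0-based half-open `start`, `end`, `strand`,
#' `boundary_class` (BED interval convention).
#'
#' @param introns Intron table from [extract_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  bed <- data.frame(seq_id = introns$seq_id, start = introns$start - 1L,
                    end = introns$end, strand = introns$strand,
                    boundary_class = introns$boundary_class)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
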