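#' Generate an annotated synthetic genome with known intron truth
#'
#' Simulates `n_genes` single-isoform genes, one per contig, each flanked by
#' intergenic sequence. Per gene the intron count is Poisson with the
#' configured mean; each intron is assigned a boundary class by the
#' configured probabilities and its donor/acceptor dinucleotides are written
#' into the genomic sequence accordingly (`GT..AG`, `GC..AG`, or a
#' non-canonical pair such as `GT..GG` for class `other`). Genes are placed
#' on a uniformly random strand; on the minus strand the contig carries the
#' reverse complement, so extraction must read boundaries in transcription
#' orientation.
#'
#' Exon and intron lengths are uniform draws from the configured ranges.
#' The GFF3 and FASTA outputs are mutually consistent and round-trip through
#' [read_gff3_gene_models()] / [extract_introns()]: the extracted intron set
#' equals the truth table exactly.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector of contigs),
#'   `gff` (character vector of GFF3 lines), `gene_models` (exon table in
#'   [read_gff3_gene_models()] layout), and `truth` (intron table:
#'   `gene_id`, `mrna_id`, `seq_id`, `start`, `end`, `strand`, `donor`,
#'   `acceptor`, `boundary_class`).
#' @export
generate_synthetic_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- c("A", "C", "G", "T")
  noncanon <- list(c("GT", "GG"), c("AT", "AC"), c("CT", "AC"))

  rand_nt <- function(k) paste(sample(nt, k, replace = TRUE), collapse = "")

  genome <- character(config$n_genes)
  names(genome) <- sprintf("ctg%04d", seq_len(config$n_genes))
  gff <- c("##gff-version 3")
  exon_rows <- vector("list", config$n_genes)
  truth_rows <- vector("list", config$n_genes)

  for (g in seq_len(config$n_genes)) {
    ctg <- names(genome)[g]
    gene_id <- sprintf("gene%04d", g)
    mrna_id <- sprintf("mrna%04d", g)
    strand <- sample(c("+", "-"), 1L)
    n_intr <- rpois(1L, config$mean_introns)
    n_ex <- n_intr + 1L
    ex_len <- sample(config$exon_len_range[1]:config$exon_len_range[2],
                     n_ex, replace = TRUE)
    in_len <- if (n_intr > 0)
      sample(config$intron_len_range[1]:config$intron_len_range[2],
             n_intr, replace = TRUE) else integer()
    classes <- if (n_intr > 0)
      sample(names(config$boundary_probs), n_intr, replace = TRUE,
             prob = config$boundary_probs) else character()

    # build the gene in transcription (sense) orientation
    pieces <- character(n_ex + n_intr)
    sense_start <- integer(n_intr); sense_end <- integer(n_intr)
    donor <- character(n_intr); acceptor <- character(n_intr)
    pos <- 0L
    for (k in seq_len(n_ex)) {
      pieces[2L * k - 1L] <- rand_nt(ex_len[k])
      pos <- pos + ex_len[k]
      if (k <= n_intr) {
        da <- switch(classes[k],
                     `GT-AG` = c("GT", "AG"),
                     `GC-AG` = c("GC", "AG"),
                     other = noncanon[[sample.int(length(noncanon), 1L)]])
        donor[k] <- da[1]; acceptor[k] <- da[2]
        pieces[2L * k] <- paste0(da[1], rand_nt(in_len[k] - 4L), da[2])
        sense_start[k] <- pos + 1L
        sense_end[k] <- pos + in_len[k]
        pos <- pos + in_len[k]
      }
    }
    sense <- paste(pieces, collapse = "")
    L <- nchar(sense)
    off <- config$flank_len
    body <- if (strand == "+") sense else .revcomp_seq(sense)
    genome[g] <- paste0(rand_nt(off), body, rand_nt(config$flank_len))

    # sense-coordinate intervals -> contig coordinates
    to_ctg <- function(s, e) {
      if (strand == "+") c(off + s, off + e)
      else c(off + L - e + 1L, off + L - s + 1L)
    }
    ex_sense_start <- integer(n_ex); ex_sense_end <- integer(n_ex)
    p <- 0L
    for (k in seq_len(n_ex)) {
      ex_sense_start[k] <- p + 1L
      ex_sense_end[k] <- p + ex_len[k]
      p <- ex_sense_end[k] + if (k <= n_intr) in_len[k] else 0L
    }

    ex_ctg <- t(vapply(seq_len(n_ex), function(k)
      to_ctg(ex_sense_start[k], ex_sense_end[k]), integer(2)))
    in_ctg <- if (n_intr > 0)
      t(vapply(seq_len(n_intr), function(k)
        to_ctg(sense_start[k], sense_end[k]), integer(2)))
    else matrix(integer(), ncol = 2)

    gene_span <- c(off + 1L, off + L)
    gff <- c(gff,
      paste(ctg, "orgatlas_sim", "gene", gene_span[1], gene_span[2], ".",
            strand, ".", paste0("ID=", gene_id), sep = "\t"),
      paste(ctg, "orgatlas_sim", "mRNA", gene_span[1], gene_span[2], ".",
            strand, ".", paste0("ID=", mrna_id, ";Parent=", gene_id),
            sep = "\t"),
      vapply(order(ex_ctg[, 1]), function(k)
        paste(ctg, "orgatlas_sim", "exon", ex_ctg[k, 1], ex_ctg[k, 2], ".",
              strand, ".",
              paste0("ID=", mrna_id, ".exon", k, ";Parent=", mrna_id),
              sep = "\t"), character(1)))

    exon_rows[[g]] <- data.frame(gene_id = gene_id, mrna_id = mrna_id,
                                 seq_id = ctg, strand = strand,
                                 start = sort(ex_ctg[, 1]),
                                 end = ex_ctg[order(ex_ctg[, 1]), 2],
                                 stringsAsFactors = FALSE)
    if (n_intr > 0)
      truth_rows[[g]] <- data.frame(gene_id = gene_id, mrna_id = mrna_id,
                                    seq_id = ctg,
                                    start = pmin(in_ctg[, 1], in_ctg[, 2]),
                                    end = pmax(in_ctg[, 1], in_ctg[, 2]),
                                    strand = strand, donor = donor,
                                    acceptor = acceptor,
                                    boundary_class = classes,
                                    stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                             logical(1))])
  if (is.null(truth)) truth <- .empty_introns()[, 1:9]
  truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  gm <- do.call(rbind, exon_rows)
  gm <- gm[order(gm$mrna_id, gm$start), , drop = FALSE]
  rownames(gm) <- NULL
  list(genome = genome, gff = gff, gene_models = gm, truth = truth)
}

.revcomp_seq <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

#' Write a synthetic genome bundle to FASTA + GFF3 files
#'
#' @param bundle Output of [generate_synthetic_gene_models()].
#' @param fasta_path,gff_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_synthetic_genome <- function(bundle, fasta_path, gff_path) {
  writeLines(as.vector(rbind(paste0(">", names(bundle$genome)),
                             bundle$genome)), fasta_path)
  writeLines(bundle$gff, gff_path)
  invisible(c(fasta = fasta_path, gff = gff_path))
}
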