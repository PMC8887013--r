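# 300-nt contig with a planted intron at 101..200: GT donor at 101-102 and
# AG acceptor at 199-200 on the plus strand
make_contig <- function(donor = "GT", acceptor = "AG") {
  set.seed(42)
  nt <- c("A", "C", "G", "T")
  s <- paste(sample(nt, 300, replace = TRUE), collapse = "")
  substr(s, 101, 102) <- donor
  substr(s, 199, 200) <- acceptor
  s
}

two_exon_models <- function(strand = "+") {
  data.frame(gene_id = "g1", mrna_id = "m1", seq_id = "ctg1",
             strand = strand, start = c(1, 201), end = c(100, 300),
             stringsAsFactors = FALSE)
}

test_that("plus-strand introns are the gaps between exons", {
  genome <- c(ctg1 = make_contig())
  introns <- extract_introns(two_exon_models("+"), genome)
  expect_equal(nrow(introns), 1)
  expect_equal(introns$start, 101)
  expect_equal(introns$end, 200)
  expect_equal(introns$donor, "GT")
  expect_equal(introns$acceptor, "AG")
  expect_equal(introns$boundary_class, "GT-AG")
})

test_that("minus-strand boundaries are read in transcription orientation", {
  # plant CT..AC on the genomic plus strand; the transcribed intron is the
  # reverse complement, so donor = revcomp(AC) = GT, acceptor = revcomp(CT)
  # = AG
  genome <- c(ctg1 = make_contig(donor = "CT", acceptor = "AC"))
  introns <- extract_introns(two_exon_models("-"), genome)
  expect_equal(introns$donor, "GT")
  expect_equal(introns$acceptor, "AG")
  expect_equal(introns$boundary_class, "GT-AG")

  # independent oracle: reverse-complement the spliced-out sequence and
  # take its first/last two bases
  spliced <- substr(genome[["ctg1"]], 101, 200)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spliced)))
  expect_equal(introns$donor, substr(rc, 1, 2))
  expect_equal(introns$acceptor, substr(rc, 99, 100))
})

test_that("single-exon mRNAs and abutting exons yield no introns", {
  genome <- c(ctg1 = make_contig())
  single <- data.frame(gene_id = "g1", mrna_id = "m1", seq_id = "ctg1",
                       strand = "+", start = 1, end = 300,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(extract_introns(single, genome)), 0)
  abutting <- data.frame(gene_id = "g1", mrna_id = "m1", seq_id = "ctg1",
                         strand = "+", start = c(1, 101), end = c(100, 300),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(extract_introns(abutting, genome)), 0)
})

test_that("introns shorter than 4 nt are flagged, not dropped", {
  genome <- c(ctg1 = make_contig())
  gm <- data.frame(gene_id = "g1", mrna_id = "m1", seq_id = "ctg1",
                   strand = "+", start = c(1, 104), end = c(100, 300),
                   stringsAsFactors = FALSE)
  introns <- extract_introns(gm, genome)  # 3-nt gap 101..103
  expect_equal(nrow(introns), 1)
  expect_true(introns$too_short)
  expect_equal(introns$boundary_class, "other")
  expect_true(grepl("^[ACGTN]{2}$", introns$donor))
})

test_that("exons beyond the contig end are a hard error", {
  genome <- c(ctg1 = substr(make_contig(), 1, 250))
  expect_error(extract_introns(two_exon_models("+"), genome),
               "beyond contig end")
  expect_error(extract_introns(two_exon_models("+"), c(other = "ACGT")),
               "absent from genome")
})

test_that("boundary classification covers the three classes", {
  expect_equal(classify_intron_boundaries("GT", "AG"), "GT-AG")
  expect_equal(classify_intron_boundaries("GC", "AG"), "GC-AG")
  expect_equal(classify_intron_boundaries("GT", "GG"), "other")
  expect_equal(classify_intron_boundaries("GN", "AG"), "other")
  expect_equal(classify_intron_boundaries(c("GT", "GC"), c("AG", "AG")),
               c("GT-AG", "GC-AG"))
})

test_that("exon + intron sequences reconstruct the gene span (both strands)", {
  cfg <- sim_config(seed = 31, n_genes = 20)
  bundle <- generate_synthetic_gene_models(cfg)
  introns <- extract_introns(bundle$gene_models, bundle$genome)
  for (m in unique(bundle$gene_models$mrna_id)) {
    ex <- bundle$gene_models[bundle$gene_models$mrna_id == m, ]
    intr <- introns[introns$mrna_id == m, ]
    ctg <- bundle$genome[[ex$seq_id[1]]]
    pieces <- rbind(
      data.frame(start = ex$start, end = ex$end),
      data.frame(start = intr$start, end = intr$end))
    pieces <- pieces[order(pieces$start), ]
    rebuilt <- paste(substring(ctg, pieces$start, pieces$end),
                     collapse = "")
    span <- substr(ctg, min(ex$start), max(ex$end))
    expect_identical(rebuilt, span)
  }
})

test_that("intron summaries compute density and fractions per policy", {
  introns <- data.frame(
    gene_id = rep(c("g1", "g2"), c(3, 4)),
    mrna_id = rep(c("m1", "m2"), c(3, 4)),
    seq_id = "ctg1", start = (1:7) * 100, end = (1:7) * 100 + 50,
    strand = "+", donor = "GT", acceptor = "AG",
    boundary_class = "GT-AG", too_short = FALSE,
    stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                   mrna_id = rep(c("m1", "m2"), each = 2),
                   seq_id = "ctg1", strand = "+",
                   start = c(1, 60, 1000, 1060),
                   end = c(50, 99, 1050, 1099), stringsAsFactors = FALSE)
  s <- summarize_intron_stats(introns, gm, "all_mrnas")
  expect_equal(s$density, 3.5)
  expect_equal(s$total_introns, 7)
  expect_equal(unname(s$class_fractions["GT-AG"]), 1.0)
  expect_equal(sum(s$class_fractions), 1, tolerance = 1e-9)

  # duplicated intron coordinates collapse under the per-gene policy
  dup <- rbind(introns, introns[1, ])
  dup$mrna_id[8] <- "m1b"
  s2 <- summarize_intron_stats(dup, gm, "unique_introns_per_gene")
  expect_equal(s2$total_introns, 7)
  expect_equal(s2$density, 3.5)

  empty <- summarize_intron_stats(introns[0, ], gm, "all_mrnas")
  expect_equal(empty$density, 0)
  expect_length(empty$class_fractions, 0)
  expect_error(summarize_intron_stats(introns, gm[0, ]), "no gene models")
})
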