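test_that("planted class counts echo the config exactly", {
  cfg <- sim_config(seed = 42, n_proteins = 100,
                    fractions = c(pts1 = 0.2, pts2 = 0.1, decoy = 0.1,
                                  tm = 0.1, mitochondrial = 0.2))
  sim <- generate_synthetic_proteome(cfg)
  expect_equal(nrow(sim$proteome), 100)
  counts <- table(sim$truth$planted_signal)
  expect_equal(unname(counts[["pts1"]]), 20)
  expect_equal(unname(counts[["pts2"]]), 10)
  expect_equal(unname(counts[["decoy"]]), 10)
  expect_equal(unname(counts[["none"]]), 30)
  expect_error(sim_config(seed = 1, fractions = c(pts1 = 0.9, pts2 = 0.3)),
               "sum")
})

test_that("generation is deterministic under the seed", {
  cfg <- sim_config(seed = 9, n_proteins = 50, n_genes = 10)
  a <- generate_synthetic_proteome(cfg)
  b <- generate_synthetic_proteome(cfg)
  expect_identical(a, b)
  g1 <- generate_synthetic_gene_models(cfg)
  g2 <- generate_synthetic_gene_models(cfg)
  expect_identical(g1, g2)
  other <- generate_synthetic_proteome(sim_config(seed = 10,
                                                  n_proteins = 50))
  expect_false(identical(a$proteome$sequence, other$proteome$sequence))
  e1 <- generate_synthetic_evidence(a$truth, seed = 3)
  e2 <- generate_synthetic_evidence(a$truth, seed = 3)
  expect_identical(e1, e2)
})

test_that("every planted signal is findable and every decoy rejected", {
  cfg <- sim_config(seed = 13, n_proteins = 150,
                    fractions = c(pts1 = 0.3, pts2 = 0.2, decoy = 0.3))
  sim <- generate_synthetic_proteome(cfg)
  for (i in seq_len(nrow(sim$proteome))) {
    s <- sim$proteome$sequence[i]
    cl <- sim$truth$planted_signal[i]
    m1 <- scan_pts1(s)
    m2 <- scan_pts2(s)
    if (cl == "pts1") {
      expect_equal(m1$motif, sim$truth$motif[i])
    } else if (cl == "pts2") {
      expect_true(sim$truth$position[i] %in% m2$position)
    } else if (cl %in% c("decoy", "none", "mitochondrial")) {
      expect_null(m1)
      expect_equal(nrow(m2), 0)
    }
  }
})

test_that("perfect-rate evidence equals the planted truth for every tool", {
  cfg <- sim_config(seed = 5, n_proteins = 80)
  sim <- generate_synthetic_proteome(cfg)
  ev <- generate_synthetic_evidence(sim$truth, default_tool_rates(1, 1),
                                    seed = 6)
  truth_mito <- sim$truth$protein_id[
    sim$truth$planted_signal == "mitochondrial"]
  for (tool in c("targetp2", "psortii", "multiloc2", "nommpred")) {
    sub <- ev[ev$tool == tool, ]
    for (setting in unique(sub$setting)) {
      called <- sub$protein_id[sub$setting == setting &
                               sub$label == "mitochondrial"]
      expect_setequal(called, truth_mito)
    }
  }
  tm <- ev[ev$tool == "tmhmm", ]
  expect_equal(tm$score[match(sim$truth$protein_id, tm$protein_id)],
               as.numeric(sim$truth$tm_helices))
  pred <- ev[ev$tool == "pts1predictor", ]
  expect_setequal(pred$protein_id[pred$label == "peroxisomal"],
                  sim$truth$protein_id[sim$truth$planted_signal == "pts1"])
})

test_that("imperfect sensitivity lands inside its binomial interval", {
  # 1,000 planted mitochondrial proteins scored at sensitivity 0.8
  truth <- data.frame(
    protein_id = sprintf("p%04d", 1:1250),
    planted_signal = rep(c("mitochondrial", "none"), c(1000, 250)),
    motif = NA_character_, position = NA_integer_, tm_helices = 0L,
    stringsAsFactors = FALSE)
  rates <- default_tool_rates(sensitivity = 0.8, specificity = 1)
  ev <- generate_synthetic_evidence(truth, rates, seed = 21)
  band <- qbinom(c(0.005, 0.995), 1000, 0.8)
  for (setting in c("animal", "fungal")) {
    sub <- ev[ev$tool == "multiloc2" & ev$setting == setting, ]
    n_pos <- sum(sub$label == "mitochondrial" &
                 sub$protein_id %in% truth$protein_id[1:1000])
    expect_gte(n_pos, band[1])
    expect_lte(n_pos, band[2])
  }
  expect_error(generate_synthetic_evidence(truth,
    data.frame(tool = "wolfpsort", setting = "x", sensitivity = 1,
               specificity = 1), seed = 1), "unknown tool")
})

test_that("synthetic gene models are consistent with their annotation", {
  cfg <- sim_config(seed = 17, n_genes = 40)
  bundle <- generate_synthetic_gene_models(cfg)
  td <- tempfile(); dir.create(td)
  write_synthetic_genome(bundle, file.path(td, "g.fa"),
                         file.path(td, "g.gff3"))
  # the reader accepts the generated GFF3 with zero warnings
  expect_no_warning(gm <- read_gff3_gene_models(file.path(td, "g.gff3")))
  expect_identical(gm, bundle$gene_models)
  genome <- read_genome_fasta(file.path(td, "g.fa"))
  expect_identical(genome, bundle$genome)

  # extraction recovers the planted intron set exactly
  introns <- extract_introns(gm, genome)
  cols <- c("seq_id", "start", "end", "strand", "donor", "acceptor",
            "boundary_class")
  got <- introns[order(introns$seq_id, introns$start), cols]
  want <- bundle$truth[order(bundle$truth$seq_id, bundle$truth$start), cols]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("a near-zero intron mean collapses to single-exon genes", {
  cfg <- sim_config(seed = 23, n_genes = 30, mean_introns = 1e-4)
  bundle <- generate_synthetic_gene_models(cfg)
  expect_equal(nrow(bundle$truth), 0)
  introns <- extract_introns(bundle$gene_models, bundle$genome)
  expect_equal(nrow(introns), 0)
  expect_error(sim_config(seed = 1, mean_introns = 0), "positive")
})
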