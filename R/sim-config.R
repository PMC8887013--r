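#' Simulation configuration for the synthetic-data generators
#'
#' One config object drives the proteome, evidence and gene-model
#' generators. The genome-structure defaults match the archamoebal
#' statistics the pipeline is designed around: a mean of 7.43 introns per
#' gene and boundary-class probabilities 0.9841 (GT-AG), 0.0159 (GC-AG),
#' with the remainder non-canonical.
#'
#' @param seed Integer seed; mandatory — every generator is deterministic
#'   under it.
#' @param n_proteins Number of proteins to simulate.
#' @param fractions Named numeric: fraction of proteins per planted class
#'   (`pts1`, `pts2`, `decoy`, `tm`, `mitochondrial`); the remainder is
#'   background (`none`). Must sum to at most 1.
#' @param len_range Protein length range (uniform integer draw).
#' @param n_genes Number of genes for the genome generator.
#' @param mean_introns Poisson mean introns per gene (default 7.43).
#' @param boundary_probs Named probabilities for `GT-AG`, `GC-AG`, `other`;
#'   must sum to 1.
#' @param intron_len_range Intron length range, nt (uniform; minimum 4).
#' @param exon_len_range Exon length range, nt (uniform).
#' @param flank_len Flanking sequence added on each side of a gene, nt.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_proteins = 200L,
                       fractions = c(pts1 = 0.15, pts2 = 0.10, decoy = 0.10,
                                     tm = 0.10, mitochondrial = 0.20),
                       len_range = c(80L, 400L),
                       n_genes = 200L,
                       mean_introns = 7.43,
                       boundary_probs = c(`GT-AG` = 0.9841,
                                          `GC-AG` = 0.0159,
                                          other = 0),
                       intron_len_range = c(40L, 500L),
                       exon_len_range = c(100L, 300L),
                       flank_len = 50L) {
  if (missing(seed)) stop2("sim_config requires an explicit seed")
  known <- c("pts1", "pts2", "decoy", "tm", "mitochondrial")
  if (!all(names(fractions) %in% known))
    stop2("unknown fraction class(es): ",
          paste(setdiff(names(fractions), known), collapse = ", "))
  if (sum(fractions) > 1 + 1e-12)
    stop2("signal-class fractions sum to more than 1")
  if (abs(sum(boundary_probs) - 1) > 1e-9)
    stop2("boundary_probs must sum to 1")
  if (!all(c("GT-AG", "GC-AG", "other") %in% names(boundary_probs)))
    stop2("boundary_probs must name GT-AG, GC-AG and other")
  if (mean_introns <= 0) stop2("mean_introns must be positive")
  if (intron_len_range[1] < 4L)
    stop2("introns shorter than 4 nt cannot carry disjoint boundary ",
          "dinucleotides")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 fractions = fractions, len_range = as.integer(len_range),
                 n_genes = as.integer(n_genes), mean_introns = mean_introns,
                 boundary_probs = boundary_probs,
                 intron_len_range = as.integer(intron_len_range),
                 exon_len_range = as.integer(exon_len_range),
                 flank_len = as.integer(flank_len)),
            class = "sim_config")
}
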