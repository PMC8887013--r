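#' Validate a pipeline configuration
#'
#' A pipeline config is a named list (typically loaded from YAML) with a
#' `stages` vector choosing among `"scan_pts"`, `"mro_call"`,
#' `"intron_stats"` and `"overlap"`, an `outdir`, and per-stage inputs:
#'
#' * `proteome`: protein FASTA (scan_pts, mro_call);
#' * `tm_table`, `pts1_predictor_table`: predictor TSVs in the `tmhmm` /
#'   `pts1predictor` dialects (scan_pts);
#' * `evidence_tables`: list of lists with `path`, `dialect`, optional
#'   `setting` (mro_call);
#' * `blast_tables`: list of lists with `path`, `reference_set` (mro_call);
#' * `families`: optional TSV `protein_id`, `family` for hallmark matching;
#' * `experimental`: optional curated TSV `protein_id`, `observed`, `note`;
#' * `genome`, `gff`: genome FASTA and GFF3 (intron_stats);
#' * `isoform_policy`: see [summarize_intron_stats()];
#' * `candidates_b`, `ortholog_map`: partner candidate-id list (one id per
#'   line) and ortholog pair TSV `id_a`, `id_b` (overlap);
#' * `pts2_window`, `pts2_variant` (`"LI"` or `"LIV"`): motif options.
#'
#' Every referenced path must exist at validation time.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (with defaults filled), invisibly classed
#'   `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$stages <- config$stages %||%
    c("scan_pts", "mro_call", "intron_stats", "overlap")
  bad <- setdiff(config$stages,
                 c("scan_pts", "mro_call", "intron_stats", "overlap"))
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outdir)) stop2("config requires an outdir")
  config$isoform_policy <- config$isoform_policy %||%
    "unique_introns_per_gene"
  config$pts2_window <- config$pts2_window %||% 40L
  config$pts2_variant <- config$pts2_variant %||% "LI"
  config$evalue_threshold <- config$evalue_threshold %||% 1e-10

  need <- character()
  if ("scan_pts" %in% config$stages || "mro_call" %in% config$stages)
    need <- c(need, proteome = config$proteome)
  if ("intron_stats" %in% config$stages)
    need <- c(need, genome = config$genome, gff = config$gff)
  if ("overlap" %in% config$stages)
    need <- c(need, candidates_b = config$candidates_b,
              ortholog_map = config$ortholog_map)
  opt <- c(config$tm_table, config$pts1_predictor_table,
           config$experimental, config$families,
           vapply(config$evidence_tables %||% list(), `[[`, "", "path"),
           vapply(config$blast_tables %||% list(), `[[`, "", "path"))
  for (p in c(need, opt)) {
    if (is.null(p)) stop2("config is missing a required path for stage(s): ",
                          paste(config$stages, collapse = ", "))
    if (!file.exists(p)) stop2("configured path does not exist: ", p)
  }
  class(config) <- c("pipeline_config", "list")
  invisible(config)
}

#' Run the organelle-proteome pipeline end to end
#'
#' Executes the configured stages in a fixed order (scan_pts, mro_call,
#' intron_stats, overlap), writes one TSV report per stage into
#' `config$outdir`, and finishes with a machine-readable `manifest.json`
#' listing every input and output with its MD5 checksum plus a config echo.
#' Identical config and inputs give byte-identical reports. Any stage
#' failure aborts with the stage name; outputs written so far are listed in
#' an `INCOMPLETE` marker file instead of a manifest.
#'
#' @param config A [validate_pipeline_config()]-accepted list or YAML path.
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  motif_cfg <- pts_motif_config(
    pts2_position2_class = if (config$pts2_variant == "LIV")
      c("L", "I", "V") else c("L", "I"),
    pts2_window = config$pts2_window)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(c(paste("failed stage:", name), outputs),
                 file.path(config$outdir, "INCOMPLETE"))
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  perox_calls <- NULL
  if ("scan_pts" %in% config$stages) run_stage("scan_pts", function() {
    proteome <- read_protein_fasta(config$proteome)
    tm <- if (!is.null(config$tm_table))
      read_evidence_table(config$tm_table, "tmhmm") else NULL
    pred <- if (!is.null(config$pts1_predictor_table))
      read_evidence_table(config$pts1_predictor_table, "pts1predictor")
      else NULL
    perox_calls <<- call_peroxisomal_candidates(proteome, tm, pred,
                                                motif_cfg)
    p <- file.path(config$outdir, "peroxisome_candidates.tsv")
    write_candidate_table(perox_calls, p)
    outputs <<- c(outputs, peroxisome_candidates = p)
  })

  if ("mro_call" %in% config$stages) run_stage("mro_call", function() {
    proteome <- read_protein_fasta(config$proteome)
    ev <- do.call(rbind, lapply(config$evidence_tables %||% list(),
      function(e) read_evidence_table(e$path, e$dialect,
                                      setting = e$setting %||% "default",
                                      proteome = proteome)))
    verdicts <- nts_consensus(ev %||% .empty_evidence(),
                              protein_ids = proteome$id)
    hom <- NULL
    if (length(config$blast_tables %||% list())) {
      hits <- do.call(rbind, lapply(config$blast_tables, function(b)
        read_blast_outfmt6(b$path, b$reference_set)))
      hom <- collect_homology_evidence(hits, config$evalue_threshold)
      if (!is.null(config$families)) {
        fam <- read.delim(config$families, stringsAsFactors = FALSE)
        hom$family <- fam$family[match(hom$protein_id, fam$protein_id)]
      }
    }
    exper <- if (!is.null(config$experimental))
      read.delim(config$experimental, stringsAsFactors = FALSE) else NULL
    calls <- integrate_mro_evidence(verdicts, hom, exper,
                                    pts_calls = perox_calls)
    p <- file.path(config$outdir, "mro_candidates.tsv")
    write_candidate_table(calls, p)
    outputs <<- c(outputs, mro_candidates = p)
  })

  if ("intron_stats" %in% config$stages) run_stage("intron_stats",
                                                   function() {
    gm <- read_gff3_gene_models(config$gff)
    genome <- read_genome_fasta(config$genome)
    introns <- extract_introns(gm, genome)
    p_bed <- file.path(config$outdir, "introns.tsv")
    write_intron_bed(introns, p_bed)
    s <- summarize_intron_stats(introns, gm, config$isoform_policy)
    p_sum <- file.path(config$outdir, "intron_summary.tsv")
    sum_tab <- data.frame(
      metric = c("total_introns", "genes_considered", "density",
                 paste0("fraction_", names(s$class_fractions)),
                 "isoform_policy"),
      value = c(s$total_introns, s$genes_considered, s$density,
                unname(s$class_fractions), s$isoform_policy))
    write.table(sum_tab, p_sum, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <<- c(outputs, introns = p_bed, intron_summary = p_sum)
  })

  if ("overlap" %in% config$stages) run_stage("overlap", function() {
    cand_a <- if (!is.null(perox_calls))
      perox_calls$protein_id[perox_calls$tier != "-"]
    else readLines(config$candidates_a)
    cand_b <- readLines(config$candidates_b)
    omap <- read.delim(config$ortholog_map, stringsAsFactors = FALSE)
    ov <- shared_organelle_candidates(cand_a, cand_b, omap)
    p <- file.path(config$outdir, "overlap.tsv")
    hdr <- sprintf("# n_a=%d\tn_b=%d\tn_shared=%d",
                   ov$n_a, ov$n_b, ov$n_shared)
    writeLines(c(hdr, "id_a\tid_b",
                 if (ov$n_shared) paste(ov$shared$id_a, ov$shared$id_b,
                                        sep = "\t")), p)
    outputs <<- c(outputs, overlap = p)
  })

  inputs <- Filter(Negate(is.null),
                   list(proteome = config$proteome, genome = config$genome,
                        gff = config$gff, tm_table = config$tm_table,
                        pts1_predictor_table = config$pts1_predictor_table,
                        experimental = config$experimental))
  manifest <- list(
    package = "orgatlas",
    version = as.character(utils::packageVersion("orgatlas")),
    stages = config$stages,
    config = config[setdiff(names(config), "stages")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(as.list(outputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  outputs <- c(outputs, manifest = file.path(config$outdir, "manifest.json"))
  invisible(as.list(outputs))
}

.empty_evidence <- function() {
  data.frame(protein_id = character(), tool = character(),
             setting = character(), label = character(),
             raw_label = character(), score = numeric(),
             stringsAsFactors = FALSE)
}
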