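#' Consensus rule configuration for mitochondrial targeting predictions
#'
#' The N-terminal targeting-sequence (NTS) consensus treats a small set of
#' predictors as *deciding*: a protein is NTS-positive iff at least one
#' setting of a deciding tool labels it mitochondrial. The remaining
#' predictors are *supporting*: their calls are recorded in the output but do
#' not flip the verdict. Plant-specific settings are dropped for organisms
#' without a plastid.
#'
#' @param deciding_tools Tools whose positive call (any setting) confers
#'   mitochondrial status. Default `c("multiloc2", "nommpred")`.
#' @param supporting_tools Tools recorded but not deciding. Default
#'   `c("targetp2", "psortii")`.
#' @param omit_plant_settings Drop evidence rows whose `setting` is
#'   `"plant"` before scoring. Default `TRUE`.
#' @return A `consensus_rule_config` list.
#' @export
consensus_rule_config <- function(deciding_tools = c("multiloc2", "nommpred"),
                                  supporting_tools = c("targetp2", "psortii"),
                                  omit_plant_settings = TRUE) {
  if (length(intersect(deciding_tools, supporting_tools)))
    stop2("deciding and supporting tool sets must be disjoint")
  unknown <- setdiff(c(deciding_tools, supporting_tools), .tools)
  if (length(unknown))
    stop2("unknown tool(s): ", paste(unknown, collapse = ", "))
  structure(list(deciding_tools = deciding_tools,
                 supporting_tools = supporting_tools,
                 omit_plant_settings = isTRUE(omit_plant_settings)),
            class = "consensus_rule_config")
}

#' Per-protein NTS consensus verdict
#'
#' Applies the deciding-tool rule to joined evidence rows: a protein is
#' `positive` iff at least one (deciding tool, setting) pair labels it
#' `mitochondrial`. Supporting-tool mitochondrial calls are counted and
#' reported but never flip the verdict. Proteins present in `protein_ids`
#' but with no evidence rows are `negative` with `unscored = TRUE`.
#'
#' @param evidence Evidence data frame (rows from [read_evidence_table()]).
#' @param rule_config A [consensus_rule_config()].
#' @param protein_ids Optional vector of ids to score; defaults to the ids
#'   present in `evidence`.
#' @return Data frame with columns `protein_id`, `verdict`
#'   (`"positive"`/`"negative"`), `n_deciding` (count of deciding
#'   tool-setting positives), `deciding_calls` (comma-separated
#'   `tool:setting`), `n_supporting`, `unscored`.
#' @export
nts_consensus <- function(evidence, rule_config = consensus_rule_config(),
                          protein_ids = NULL) {
  if (is.null(protein_ids)) protein_ids <- unique(evidence$protein_id)
  ev <- evidence
  if (rule_config$omit_plant_settings)
    ev <- ev[tolower(ev$setting) != "plant", , drop = FALSE]
  mito <- ev[ev$label == "mitochondrial", , drop = FALSE]
  dec <- mito[mito$tool %in% rule_config$deciding_tools, , drop = FALSE]
  sup <- mito[mito$tool %in% rule_config$supporting_tools, , drop = FALSE]

  calls <- vapply(protein_ids, function(p) {
    rows <- dec[dec$protein_id == p, , drop = FALSE]
    paste(paste0(rows$tool, ":", rows$setting), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  n_dec <- vapply(protein_ids, function(p) sum(dec$protein_id == p),
                  integer(1), USE.NAMES = FALSE)
  n_sup <- vapply(protein_ids, function(p) sum(sup$protein_id == p),
                  integer(1), USE.NAMES = FALSE)
  scored <- protein_ids %in% ev$protein_id

  data.frame(protein_id = protein_ids,
             verdict = ifelse(n_dec >= 1L, "positive", "negative"),
             n_deciding = n_dec, deciding_calls = calls,
             n_supporting = n_sup, unscored = !scored,
             stringsAsFactors = FALSE)
}

#' Fuse the three evidence lines into tiered MRO candidate calls
#'
#' Combines (i) homology to reference organelle proteomes, (ii) the NTS
#' consensus verdict, and (iii) curated heterologous-localization results
#' into one call per protein. The base rule counts positive channels:
#' at least two give a strong call (`+`), exactly one a weak call (`+?`),
#' none an exclusion (`-`). Three overrides reproduce the documented
#' arbitration behavior:
#'
#' 1. *Experimental exclusion*: a protein whose only support is a
#'    single-tool NTS call and whose heterologous localization shows a
#'    non-mitochondrial compartment is excluded (the ATP-citrate-lyase
#'    pattern).
#' 2. *Hallmark retention*: proteins with homology to an unambiguous
#'    mitochondrial marker family (default Tom40, Sam50, mtHSP70, cpn60,
#'    cpn10) stay at strong tier even when heterologous localization fails
#'    (the cpn10 pattern) — a failed import in yeast is not evidence of
#'    another compartment for a hallmark.
#' 3. *Peroxisomal reassignment*: an excluded protein that carries a PTS
#'    match is flagged `reassign_peroxisome` (the
#'    pyrroline-5-carboxylate-reductase pattern).
#'
#' @param nts_verdicts Output of [nts_consensus()].
#' @param homology_evidence Output of [collect_homology_evidence()]; may
#'   carry a `family` column used for hallmark matching. `NULL` for none.
#' @param experimental_evidence Curated data frame with columns
#'   `protein_id`, `observed` (one of `mitochondrial`, `cytosolic`,
#'   `peroxisomal`, `vesicular`, `other`), `note`. Conflicting duplicate
#'   rows for one protein are a hard error (they require curation).
#' @param hallmark_set Character vector of hallmark family names matched
#'   (case-insensitively) against `homology_evidence$family`.
#' @param pts_calls Optional candidate-call data frame from
#'   [call_peroxisomal_candidates()]; proteins with a PTS motif there are
#'   eligible for the reassignment flag.
#' @param strong_min Channels needed for a strong call (default 2).
#' @return Candidate-call data frame: `protein_id`, `compartment` (`"MRO"`),
#'   `tier`, channel columns `homology`, `nts`, `experimental_mito`,
#'   `hallmark`, and `reassign_peroxisome`.
#' @export
integrate_mro_evidence <- function(nts_verdicts,
                                   homology_evidence = NULL,
                                   experimental_evidence = NULL,
                                   hallmark_set = c("Tom40", "Sam50",
                                                    "mtHSP70", "cpn60",
                                                    "cpn10"),
                                   pts_calls = NULL,
                                   strong_min = 2L) {
  ids <- sort(unique(c(nts_verdicts$protein_id,
                       homology_evidence$protein_id,
                       experimental_evidence$protein_id)))

  exp_obs <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(experimental_evidence) && nrow(experimental_evidence)) {
    ok <- c("mitochondrial", "cytosolic", "peroxisomal", "vesicular", "other")
    if (!all(experimental_evidence$observed %in% ok))
      stop2("experimental 'observed' must be one of: ",
            paste(ok, collapse = ", "))
    dup <- split(experimental_evidence$observed,
                 experimental_evidence$protein_id)
    conflict <- names(dup)[vapply(dup, function(x)
      length(unique(x)) > 1L, logical(1))]
    if (length(conflict))
      stop2("conflicting duplicate experimental rows for: ",
            paste(conflict, collapse = ", "), " (requires curation)")
    exp_obs[names(dup)] <- vapply(dup, `[`, character(1), 1L)
  }

  hom <- ids %in% (homology_evidence$protein_id %||% character())
  hallmark <- rep(FALSE, length(ids))
  if (!is.null(homology_evidence) && "family" %in% names(homology_evidence)) {
    hm_ids <- homology_evidence$protein_id[
      tolower(homology_evidence$family) %in% tolower(hallmark_set)]
    hallmark <- ids %in% hm_ids
  }

  vidx <- match(ids, nts_verdicts$protein_id)
  nts_pos <- !is.na(vidx) & nts_verdicts$verdict[vidx] == "positive"
  nts_single <- !is.na(vidx) & nts_verdicts$n_deciding[vidx] == 1L

  exp_mito <- !is.na(exp_obs) & exp_obs == "mitochondrial"
  exp_nonmito <- !is.na(exp_obs) & exp_obs != "mitochondrial"

  n_channels <- hom + nts_pos + exp_mito
  tier <- ifelse(n_channels >= strong_min, "+",
                 ifelse(n_channels == 1L, "+?", "-"))

  # override 1: curated non-mitochondrial localization excludes proteins
  # whose only other support is a single-tool NTS call
  acl_like <- exp_nonmito & !hom & nts_pos & nts_single
  tier[acl_like] <- "-"
  # override 2: hallmark homologs are retained at strong tier regardless
  tier[hallmark] <- "+"

  has_pts <- rep(FALSE, length(ids))
  if (!is.null(pts_calls) && nrow(pts_calls)) {
    pts_ids <- pts_calls$protein_id[!is.na(pts_calls$pts1_motif) |
                                    !is.na(pts_calls$pts2_motif)]
    has_pts <- ids %in% pts_ids
  }
  reassign <- tier == "-" & has_pts

  data.frame(protein_id = ids, compartment = "MRO", tier = tier,
             homology = hom, nts = nts_pos, experimental_mito = exp_mito,
             experimental_observed = unname(exp_obs), hallmark = hallmark,
             reassign_peroxisome = reassign, stringsAsFactors = FALSE)
}
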