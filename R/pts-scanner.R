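#' Peroxisomal targeting-signal motif configuration
#'
#' The PTS1 signal is a C-terminal tripeptide drawn from a position-class
#' grammar plus literal extras, minus literal exclusions; the PTS2 signal is
#' an N-terminal nonapeptide `R[LI]xxxxxHL` (second-position class
#' switchable to `{L,I,V}`) restricted to a window from the N-terminus.
#'
#' Defaults encode the archamoebal grammar: extras `{SRI}`, pattern
#' `[SAP][KR][LM]`, exclusions `{AKM, PKM, PRM}` (tripeptides that match the
#' pattern but are not functional signals in this lineage), PTS2 class
#' `{L,I}` with a 40-residue search window.
#'
#' @param pts1_extra Literal tripeptides accepted in addition to the pattern.
#' @param pts1_pattern List of three character vectors: the allowed residues
#'   at each position of the C-terminal tripeptide.
#' @param pts1_excluded Literal tripeptides removed from the pattern
#'   expansion.
#' @param pts2_position2_class Allowed residues at position 2 of the PTS2
#'   nonapeptide; `c("L","I")` by default, `c("L","I","V")` as the documented
#'   variant.
#' @param pts2_window Number of N-terminal residues searched for PTS2; the
#'   whole 9-residue match must lie within it. Must be at least 9.
#' @return A `pts_motif_config` list.
#' @examples
#' cfg <- pts_motif_config()
#' enumerate_pts1_set(cfg)
#' @export
pts_motif_config <- function(pts1_extra = "SRI",
                             pts1_pattern = list(c("S", "A", "P"),
                                                 c("K", "R"),
                                                 c("L", "M")),
                             pts1_excluded = c("AKM", "PKM", "PRM"),
                             pts2_position2_class = c("L", "I"),
                             pts2_window = 40L) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  stopifnot(length(pts1_pattern) == 3L)
  if (!all(unlist(pts1_pattern) %in% aa20) ||
      !all(pts2_position2_class %in% aa20))
    stop2("motif position classes must contain standard amino-acid letters")
  if (pts2_window < 9L)
    stop2("pts2_window must be >= 9 (the nonapeptide must fit)")
  expansion <- .expand_tripeptides(pts1_pattern)
  if (!all(pts1_excluded %in% expansion))
    stop2("pts1_excluded must be a subset of the pattern expansion")
  structure(list(pts1_extra = toupper(pts1_extra),
                 pts1_pattern = pts1_pattern,
                 pts1_excluded = toupper(pts1_excluded),
                 pts2_position2_class = toupper(pts2_position2_class),
                 pts2_window = as.integer(pts2_window)),
            class = "pts_motif_config")
}

.expand_tripeptides <- function(pattern) {
  g <- expand.grid(pattern[[1]], pattern[[2]], pattern[[3]],
                   stringsAsFactors = FALSE)
  sort(paste0(g[[1]], g[[2]], g[[3]]))
}

#' Enumerate the accepted PTS1 tripeptides
#'
#' Pure function of the config: the position-class pattern expansion, minus
#' the exclusions, union the literal extras. Under the defaults this yields
#' 10 tripeptides (12 pattern expansions - 3 exclusions + SRI).
#'
#' @param config A [pts_motif_config()].
#' @return Sorted character vector of accepted C-terminal tripeptides.
#' @export
enumerate_pts1_set <- function(config = pts_motif_config()) {
  sort(union(setdiff(.expand_tripeptides(config$pts1_pattern),
                     config$pts1_excluded),
             config$pts1_extra))
}

#' Scan a protein for a C-terminal PTS1
#'
#' A protein matches iff its final three residues are in
#' [enumerate_pts1_set()]; the motif is anchored at the C-terminus, internal
#' occurrences never match. Ambiguous residues (X, B, Z, U) never satisfy a
#' class. Proteins shorter than 3 residues yield no match.
#'
#' @param sequence Amino-acid string (single protein).
#' @param config A [pts_motif_config()].
#' @return `NULL`, or a list with `signal_type = "PTS1"`, `motif`, and the
#'   1-based `position` of the tripeptide start (`nchar(sequence) - 2`).
#' @export
scan_pts1 <- function(sequence, config = pts_motif_config()) {
  n <- nchar(sequence)
  if (n < 3L) return(NULL)
  tri <- toupper(substr(sequence, n - 2L, n))
  if (!tri %in% enumerate_pts1_set(config)) return(NULL)
  list(signal_type = "PTS1", motif = tri, position = n - 2L)
}

#' Scan a protein for N-terminal PTS2 nonapeptides
#'
#' Finds every occurrence of `R`, one residue from the position-2 class, any
#' five residues, then `HL`, whose full 9-residue span lies within the first
#' `pts2_window` residues. Matches may overlap. The five wildcard positions
#' accept any residue letter; the fixed positions accept only their stated
#' standard residues, so ambiguity codes never satisfy them.
#'
#' @param sequence Amino-acid string (single protein).
#' @param config A [pts_motif_config()].
#' @return Data frame with columns `signal_type`, `motif`, `position`
#'   (1-based match start); zero rows when there is no match.
#' @export
scan_pts2 <- function(sequence, config = pts_motif_config()) {
  empty <- data.frame(signal_type = character(), motif = character(),
                      position = integer(), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < 9L) return(empty)
  window <- substr(toupper(sequence), 1L, min(n, config$pts2_window))
  pat <- paste0("(?=R[", paste(config$pts2_position2_class, collapse = ""),
                "][A-Z]{5}HL)")
  m <- gregexpr(pat, window, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  starts <- starts[starts + 8L <= config$pts2_window & starts + 8L <= n]
  if (length(starts) == 0L) return(empty)
  data.frame(signal_type = "PTS2",
             motif = substring(window, starts, starts + 8L),
             position = starts, stringsAsFactors = FALSE)
}

#' Call peroxisomal matrix-protein candidates
#'
#' A protein is a peroxisomal candidate iff it carries a PTS motif (PTS1 or
#' PTS2) or is called positive by the external PTS1 predictor, AND has zero
#' predicted transmembrane helices. The motif channel and the predictor
#' channel set the confidence tier: both agree on a PTS1-bearing protein
#' gives a strong call (`+`), exactly one channel firing gives a weak call
#' (`+?`), and everything else — including TM-filtered proteins — is
#' excluded (`-`).
#'
#' @param proteome Data frame from [read_protein_fasta()].
#' @param tm_evidence Evidence rows with `tool == "tmhmm"` (score = predicted
#'   helix count); proteins without a row are treated as having unknown TM
#'   status and are conservatively kept only when `missing_tm_ok = TRUE`.
#' @param pts1_predictor_evidence Evidence rows with
#'   `tool == "pts1predictor"`; label `"peroxisomal"` is a positive call.
#' @param config A [pts_motif_config()].
#' @param missing_tm_ok Treat proteins with no TM row as non-membrane
#'   (default `TRUE`: absence of a TMHMM row means zero predicted helices in
#'   the common all-proteins run).
#' @return Candidate-call data frame: `protein_id`, `compartment`
#'   (`"peroxisome"`), `tier`, and per-channel evidence columns `pts1_motif`,
#'   `pts2_motif`, `pts1_predictor`, `tm_helices`.
#' @export
call_peroxisomal_candidates <- function(proteome, tm_evidence = NULL,
                                        pts1_predictor_evidence = NULL,
                                        config = pts_motif_config(),
                                        missing_tm_ok = TRUE) {
  ids <- proteome$id
  tm <- rep(if (missing_tm_ok) 0 else NA_real_, length(ids))
  if (!is.null(tm_evidence) && nrow(tm_evidence)) {
    extra <- setdiff(tm_evidence$protein_id, ids)
    if (length(extra))
      warning(length(extra), " TM evidence row(s) for proteins absent from ",
              "the proteome ignored", call. = FALSE)
    idx <- match(tm_evidence$protein_id, ids)
    tm[idx[!is.na(idx)]] <- tm_evidence$score[!is.na(idx)]
  }
  pred_pos <- rep(FALSE, length(ids))
  if (!is.null(pts1_predictor_evidence) && nrow(pts1_predictor_evidence)) {
    pos_ids <- pts1_predictor_evidence$protein_id[
      pts1_predictor_evidence$label == "peroxisomal"]
    pred_pos <- ids %in% pos_ids
  }

  pts1 <- vapply(proteome$sequence, function(s) {
    m <- scan_pts1(s, config); if (is.null(m)) NA_character_ else m$motif
  }, character(1), USE.NAMES = FALSE)
  pts2 <- vapply(proteome$sequence, function(s) {
    m <- scan_pts2(s, config)
    if (nrow(m) == 0L) NA_character_ else m$motif[1]
  }, character(1), USE.NAMES = FALSE)

  motif <- !is.na(pts1) | !is.na(pts2)
  no_tm <- !is.na(tm) & tm == 0
  candidate <- (motif | pred_pos) & no_tm
  tier <- ifelse(!candidate, "-",
                 ifelse(motif & pred_pos, "+", "+?"))

  data.frame(protein_id = ids, compartment = "peroxisome", tier = tier,
             pts1_motif = pts1, pts2_motif = pts2,
             pts1_predictor = pred_pos, tm_helices = tm,
             stringsAsFactors = FALSE)
}
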