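#' Collapse BLAST hits into per-protein homology evidence
#'
#' Hits worse than the e-value threshold are dropped; for every
#' (query, reference set) pair the best remaining hit is kept. Best is
#' decided by bitscore (higher wins), ties by e-value (lower wins), then by
#' subject id (lexicographic) so the result is deterministic.
#'
#' @param blast_hits Data frame from [read_blast_outfmt6()] (rows from
#'   several reference sets may be concatenated).
#' @param evalue_threshold Retain hits with `evalue <= evalue_threshold`.
#'   Default `1e-10`, a common cutoff for organellar homology screens.
#' @return Data frame with one row per (protein, reference set):
#'   `protein_id`, `reference_set`, `best_subject_id`, `best_evalue`,
#'   `best_bitscore`.
#' @export
collect_homology_evidence <- function(blast_hits, evalue_threshold = 1e-10) {
  stopifnot(evalue_threshold > 0)
  hits <- blast_hits[blast_hits$evalue <= evalue_threshold, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(protein_id = character(), reference_set = character(),
                      best_subject_id = character(), best_evalue = numeric(),
                      best_bitscore = numeric(), stringsAsFactors = FALSE))
  ord <- order(hits$query_id, hits$reference_set,
               -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(hits$query_id, hits$reference_set))
  best <- hits[keep, , drop = FALSE]
  data.frame(protein_id = best$query_id,
             reference_set = best$reference_set,
             best_subject_id = best$subject_id,
             best_evalue = best$evalue,
             best_bitscore = best$bitscore,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count shared organelle-proteome candidates across two species
#'
#' Given candidate identifier sets from two species and a curated ortholog
#' map (accepted identifier pairs, e.g. best reciprocal hits supplied as a
#' table), returns the matched pairs and counts. Orthology is an input, not
#' inferred here.
#'
#' @param candidates_a,candidates_b Character vectors of candidate protein
#'   ids for species A and B.
#' @param ortholog_map Data frame with columns `id_a`, `id_b`.
#' @param set_a_name,set_b_name Labels used in the result.
#' @return List of class `overlap_result`: `set_a_name`, `set_b_name`,
#'   `shared` (data frame `id_a`, `id_b`), `n_a`, `n_b`, `n_shared`.
#' @export
shared_organelle_candidates <- function(candidates_a, candidates_b,
                                        ortholog_map,
                                        set_a_name = "A", set_b_name = "B") {
  stopifnot(all(c("id_a", "id_b") %in% names(ortholog_map)))
  candidates_a <- unique(candidates_a)
  candidates_b <- unique(candidates_b)
  stray <- !(ortholog_map$id_a %in% candidates_a) &
           !(ortholog_map$id_b %in% candidates_b)
  if (any(stray))
    warning(sum(stray), " ortholog pair(s) reference ids in neither ",
            "candidate set", call. = FALSE)
  hit <- ortholog_map$id_a %in% candidates_a &
         ortholog_map$id_b %in% candidates_b
  shared <- unique(ortholog_map[hit, c("id_a", "id_b"), drop = FALSE])
  rownames(shared) <- NULL
  structure(list(set_a_name = set_a_name, set_b_name = set_b_name,
                 shared = shared,
                 n_a = length(candidates_a), n_b = length(candidates_b),
                 n_shared = nrow(shared)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Organelle-proteome overlap:", x$set_a_name, "vs", x$set_b_name, "\n")
  cat("  |A| =", x$n_a, " |B| =", x$n_b, " shared =", x$n_shared, "\n")
  if (x$n_shared > 0 && x$n_shared <= 20)
    print(x$shared)
  invisible(x)
}
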