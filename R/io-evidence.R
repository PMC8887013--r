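#' Evidence-table dialects
#'
#' Each supported localization predictor writes a different tabular layout.
#' Dialects are defined here as explicit column maps plus a label map into the
#' pipeline's controlled compartment vocabulary (`mitochondrial`, `cytosolic`,
#' `nuclear`, `secretory`, `peroxisomal`, `extracellular`, `er`,
#' `plasma_membrane`, `vesicular`, `membrane`, `other`) — formats are never
#' sniffed, because predictor output drifts between versions. All dialects are
#' tab-separated with a header row:
#'
#' * `targetp2`: columns `ID`, `Prediction` (`mTP`, `SP`, `noTP`/`OTHER`) and
#'   optionally `mTP` (the mitochondrial presequence likelihood, used as the
#'   score). `mTP` maps to `mitochondrial`, `SP` to `secretory`.
#' * `psortii`: columns `protein_id`, `prediction` (abbreviated k-NN winner:
#'   `mit`, `cyt`, `nuc`, `per`, `ext`, `ER`, `PM`, `ves`), optional `score`.
#' * `multiloc2`: columns `protein_id`, `top_location`, optional `score` and
#'   `setting` (`animal`/`fungal`; the plant setting is omitted for
#'   plastid-less organisms).
#' * `nommpred`: columns `protein_id`, `prediction`, optional `setting`
#'   (`MRO`/`Dictyostelium`). `MRO`, `Mitochondrion`, `Hydrogenosome` and
#'   `Mitosome` all map to `mitochondrial`.
#' * `tmhmm`: either the native short format (whitespace-separated fields with
#'   a `PredHel=<n>` token) or a two-column TSV `protein_id`, `pred_hel`. The
#'   predicted helix count becomes the score; label is `membrane` when the
#'   count is positive.
#' * `pts1predictor`: columns `protein_id`, `prediction` (`Targeted` /
#'   `Twilight zone` / `Not targeted`), optional `score`. Only `Targeted` maps
#'   to `peroxisomal`.
#' * `generic`: already in pipeline vocabulary — columns `protein_id`,
#'   `tool`, `setting`, `label`, optional `score`.
#'
#' Unknown labels are preserved under `label = "other"` with the raw token
#' retained in `raw_label`.
#'
#' @name evidence_dialects
NULL

.label_maps <- list(
  targetp2 = c(mtp = "mitochondrial", sp = "secretory", notp = "other",
               other = "other"),
  psortii = c(mit = "mitochondrial", cyt = "cytosolic", nuc = "nuclear",
              per = "peroxisomal", ext = "extracellular", er = "er",
              pm = "plasma_membrane", ves = "vesicular", sec = "secretory"),
  multiloc2 = c(mitochondrial = "mitochondrial", cytoplasmic = "cytosolic",
                nuclear = "nuclear", secretory = "secretory",
                `sp` = "secretory", peroxisomal = "peroxisomal",
                extracellular = "extracellular"),
  nommpred = c(mro = "mitochondrial", mitochondrion = "mitochondrial",
               hydrogenosome = "mitochondrial", mitosome = "mitochondrial",
               not = "other", others = "other", other = "other")
)

.map_label <- function(raw, map) {
  key <- tolower(trimws(raw))
  out <- unname(map[key])
  ifelse(is.na(out), "other", out)
}

#' Read a predictor output table into evidence rows
#'
#' Parses one external predictor's tabular output under a named dialect (see
#' [evidence_dialects]) and normalizes it into the pipeline's evidence-row
#' layout: `protein_id`, `tool`, `setting`, `label`, `raw_label`, `score`.
#'
#' @param path Path to the predictor's TSV output.
#' @param dialect One of `"targetp2"`, `"psortii"`, `"multiloc2"`,
#'   `"nommpred"`, `"tmhmm"`, `"pts1predictor"`, `"generic"`.
#' @param setting Run setting recorded on every row (e.g. NommPred `"MRO"` vs
#'   `"Dictyostelium"`). Overridden by a `setting` column if the file has one.
#'   Default `"default"`.
#' @param proteome Optional proteome data frame; rows referencing proteins
#'   absent from it trigger a warning but are retained (they are joined
#'   later).
#' @return Evidence data frame; `(protein_id, tool, setting)` is unique.
#' @export
read_evidence_table <- function(path, dialect,
                                setting = "default", proteome = NULL) {
  dialects <- c("targetp2", "psortii", "multiloc2", "nommpred", "tmhmm",
                "pts1predictor", "generic")
  if (!dialect %in% dialects)
    stop2("unknown dialect '", dialect, "'; expected one of: ",
          paste(dialects, collapse = ", "))
  if (!file.exists(path)) stop2("evidence table not found: ", path)

  out <- switch(dialect,
    tmhmm = .read_tmhmm(path),
    generic = .read_generic_evidence(path),
    pts1predictor = .read_pts1predictor(path),
    .read_mapped_evidence(path, dialect))

  if (is.null(out$setting)) out$setting <- setting
  out$setting[is.na(out$setting) | out$setting == ""] <- setting

  key <- paste(out$protein_id, out$tool, out$setting)
  if (anyDuplicated(key))
    stop2("duplicate (protein_id, tool, setting) in ", path, ": ",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(proteome)) {
    missing <- setdiff(out$protein_id, proteome$id)
    if (length(missing))
      warning(length(missing), " evidence row(s) reference proteins absent ",
              "from the proteome (retained): ",
              paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out[, c("protein_id", "tool", "setting", "label", "raw_label", "score")]
}

.read_mapped_evidence <- function(path, dialect) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- intersect(c("protein_id", "ID", "id"), names(tab))[1]
  lab_col <- intersect(c("prediction", "Prediction", "top_location"),
                       names(tab))[1]
  if (is.na(id_col) || is.na(lab_col))
    stop2("dialect '", dialect, "' requires an id and a prediction column in ",
          path)
  score <- if ("score" %in% names(tab)) as.numeric(tab$score)
           else if (dialect == "targetp2" && "mTP" %in% names(tab))
             as.numeric(tab$mTP)
           else NA_real_
  out <- data.frame(
    protein_id = as.character(tab[[id_col]]),
    tool = dialect,
    label = .map_label(tab[[lab_col]], .label_maps[[dialect]]),
    raw_label = as.character(tab[[lab_col]]),
    score = score,
    stringsAsFactors = FALSE)
  if ("setting" %in% names(tab)) out$setting <- as.character(tab$setting)
  out
}

.read_tmhmm <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\bpred_hel\\b", first, ignore.case = TRUE)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    ids <- as.character(tab$protein_id)
    n_hel <- as.integer(tab$pred_hel)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    ids <- sub("\\s.*$", "", lines)
    m <- regmatches(lines, regexpr("PredHel=\\d+", lines))
    hit <- grepl("PredHel=\\d+", lines)
    if (!all(hit))
      stop2("tmhmm dialect: no PredHel=<n> token at data line ",
            which(!hit)[1], " of ", path)
    n_hel <- as.integer(sub("PredHel=", "", m))
  }
  data.frame(protein_id = ids, tool = "tmhmm",
             label = ifelse(n_hel > 0, "membrane", "other"),
             raw_label = paste0("PredHel=", n_hel),
             score = as.numeric(n_hel), stringsAsFactors = FALSE)
}

.read_pts1predictor <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("protein_id", "prediction") %in% names(tab)))
    stop2("pts1predictor dialect requires protein_id and prediction columns")
  raw <- as.character(tab$prediction)
  data.frame(protein_id = as.character(tab$protein_id),
             tool = "pts1predictor",
             label = ifelse(tolower(raw) == "targeted", "peroxisomal",
                            "other"),
             raw_label = raw,
             score = if ("score" %in% names(tab)) as.numeric(tab$score)
                     else NA_real_,
             stringsAsFactors = FALSE)
}

.read_generic_evidence <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tool", "setting", "label")
  if (!all(need %in% names(tab)))
    stop2("generic dialect requires columns: ", paste(need, collapse = ", "))
  bad <- !tab$tool %in% .tools
  if (any(bad))
    stop2("unknown tool(s) in generic evidence: ",
          paste(unique(tab$tool[bad]), collapse = ", "))
  data.frame(protein_id = as.character(tab$protein_id),
             tool = as.character(tab$tool),
             setting = as.character(tab$setting),
             label = as.character(tab$label),
             raw_label = if ("raw_label" %in% names(tab))
               as.character(tab$raw_label) else as.character(tab$label),
             score = if ("score" %in% names(tab)) as.numeric(tab$score)
                     else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column BLAST tabular output: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, no header.
#'
#' @param path Path to the BLAST output.
#' @param reference_set Token naming the reference organelle proteome the
#'   search was run against (e.g. `"Mb_hydrogenosome"`).
#' @return Data frame with columns `query_id`, `subject_id`, `reference_set`,
#'   `pident`, `length`, `evalue`, `bitscore`.
#' @export
read_blast_outfmt6 <- function(path, reference_set) {
  if (!file.exists(path)) stop2("BLAST table not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 12L))
    stop2("malformed BLAST outfmt 6 row at line ",
          which(keep)[which(n != 12L)[1]], " of ", path,
          " (expected 12 tab-separated fields, got ", n[n != 12L][1], ")")
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  bad <- is.na(evalue) | is.na(bitscore) | evalue < 0
  if (any(bad))
    stop2("non-numeric or negative evalue/bitscore at line ",
          which(keep)[which(bad)[1]], " of ", path)
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             reference_set = reference_set,
             pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' Write tiered candidate calls as a TSV
#'
#' One row per protein, sorted by id: `protein_id`, `compartment`, `tier`
#' (`+` / `+?` / `-`), then one column per evidence channel. The layout
#' mirrors a curated localization table with a final-call column.
#'
#' @param calls Candidate-call data frame from
#'   [call_peroxisomal_candidates()] or [integrate_mro_evidence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(calls, path) {
  stopifnot(all(c("protein_id", "compartment", "tier") %in% names(calls)))
  if (!all(calls$tier %in% .tiers))
    stop2("tier values must be one of: ", paste(.tiers, collapse = " "))
  calls <- calls[order(calls$protein_id), , drop = FALSE]
  ok <- tryCatch({
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop2("cannot write candidate table to ", path,
                               ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a candidate-call TSV written by [write_candidate_table()]
#'
#' @param path Path to the TSV.
#' @return Candidate-call data frame.
#' @export
read_candidate_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("protein_id", "compartment", "tier") %in% names(tab)))
    stop2("not a candidate table: ", path)
  tab$tier <- as.character(tab$tier)
  tab
}
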