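#' Generate a synthetic proteome with planted targeting signals
#'
#' Simulates a proteome in which a configured fraction of proteins carries a
#' planted signal, with everything recorded in a ground-truth table:
#'
#' * `pts1` — ends in a tripeptide drawn uniformly from the accepted PTS1
#'   set;
#' * `pts2` — carries one `R[LI]xxxxxHL` nonapeptide at a uniform position
#'   inside the PTS2 search window;
#' * `decoy` — ends in an *excluded* tripeptide (matches the position-class
#'   pattern but is not a functional signal);
#' * `tm` — carries a PTS1 tripeptide *and* two planted transmembrane
#'   helices in the truth table, to exercise the TM filter;
#' * `mitochondrial` — background sequence; the class only drives the
#'   evidence simulator;
#' * `none` — background.
#'
#' Background residues are drawn uniformly from the 20 standard amino
#' acids. Accidental motifs are scrubbed from background before planting
#' (C-terminal tripeptides in the accepted set are resampled; chance PTS2
#' nonapeptides inside the window are broken), so scanner output on the
#' simulated proteome equals the planted truth exactly.
#'
#' @param config A [sim_config()]; `seed` drives all draws.
#' @param motif_config A [pts_motif_config()] defining the grammar the
#'   signals are planted against.
#' @return List with `proteome` (data frame `id`, `description`,
#'   `sequence`) and `truth` (data frame `protein_id`, `planted_signal`,
#'   `motif`, `position`, `tm_helices`).
#' @export
generate_synthetic_proteome <- function(config,
                                        motif_config = pts_motif_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- config$n_proteins
  counts <- round(config$fractions * n)
  if (sum(counts) > n) stop2("rounded class counts exceed n_proteins")
  classes <- c(rep(names(counts), counts), rep("none", n - sum(counts)))
  ids <- sprintf("sp%04d", seq_len(n))

  pts1_set <- enumerate_pts1_set(motif_config)
  lens <- sample(config$len_range[1]:config$len_range[2], n, replace = TRUE)

  rand_seq <- function(k) paste(sample(aa20, k, replace = TRUE),
                                collapse = "")

  scrub <- function(seq) {
    # break accidental C-terminal PTS1 (accepted or excluded tripeptide)
    k <- nchar(seq)
    repeat {
      tri <- substr(seq, k - 2L, k)
      if (!tri %in% c(pts1_set, motif_config$pts1_excluded)) break
      substr(seq, k, k) <- sample(aa20, 1L)
    }
    # break accidental PTS2 nonapeptides inside the window
    for (iter in 1:50) {
      m <- scan_pts2(seq, motif_config)
      if (nrow(m) == 0L) break
      p <- m$position[1]
      substr(seq, p, p) <- sample(setdiff(aa20, "R"), 1L)
    }
    seq
  }

  seqs <- character(n)
  motif <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  tm_helices <- integer(n)
  for (i in seq_len(n)) {
    s <- scrub(rand_seq(lens[i]))
    cl <- classes[i]
    if (cl == "pts1" || cl == "tm") {
      tri <- sample(pts1_set, 1L)
      substr(s, lens[i] - 2L, lens[i]) <- tri
      motif[i] <- tri
      position[i] <- lens[i] - 2L
      if (cl == "tm") tm_helices[i] <- 2L
    } else if (cl == "decoy") {
      tri <- sample(motif_config$pts1_excluded, 1L)
      substr(s, lens[i] - 2L, lens[i]) <- tri
      motif[i] <- tri
      position[i] <- lens[i] - 2L
    } else if (cl == "pts2") {
      pos <- sample.int(min(motif_config$pts2_window, lens[i]) - 8L, 1L)
      nona <- paste0("R", sample(motif_config$pts2_position2_class, 1L),
                     rand_seq(5L), "HL")
      substr(s, pos, pos + 8L) <- nona
      motif[i] <- nona
      position[i] <- pos
      s <- .rescrub_tail(s, pts1_set, motif_config, aa20)
    }
    seqs[i] <- s
  }

  list(proteome = data.frame(id = ids,
                             description = paste("synthetic", classes),
                             sequence = seqs, stringsAsFactors = FALSE),
       truth = data.frame(protein_id = ids, planted_signal = classes,
                          motif = motif, position = position,
                          tm_helices = tm_helices,
                          stringsAsFactors = FALSE))
}

# planting a PTS2 nonapeptide cannot create a C-terminal PTS1 unless the
# protein is barely longer than the window; re-check the tail anyway
.rescrub_tail <- function(seq, pts1_set, motif_config, aa20) {
  k <- nchar(seq)
  repeat {
    tri <- substr(seq, k - 2L, k)
    if (!tri %in% c(pts1_set, motif_config$pts1_excluded)) return(seq)
    substr(seq, k, k) <- sample(aa20, 1L)
  }
}

#' Default per-tool rate table for the evidence simulator
#'
#' The standard predictor battery: TargetP 2 (non-plant), PSORT II,
#' MultiLoc2 (animal and fungal settings), NommPred (MRO and Dictyostelium
#' settings), TMHMM, and the PTS1 predictor — one row per (tool, setting)
#' with a sensitivity and a specificity.
#'
#' @param sensitivity,specificity Rates in \[0, 1\] applied to every row.
#' @return Data frame `tool`, `setting`, `sensitivity`, `specificity`.
#' @export
default_tool_rates <- function(sensitivity = 1, specificity = 1) {
  tab <- data.frame(
    tool = c("targetp2", "psortii", "multiloc2", "multiloc2",
             "nommpred", "nommpred", "tmhmm", "pts1predictor"),
    setting = c("non-plant", "default", "animal", "fungal",
                "MRO", "Dictyostelium", "default", "default"),
    stringsAsFactors = FALSE)
  tab$sensitivity <- sensitivity
  tab$specificity <- specificity
  tab
}

#' Simulate predictor evidence tables from planted truth
#'
#' Each (tool, setting) labels each protein independently: a protein whose
#' truth class matches the tool's target class is called positive with
#' probability `sensitivity`; any other protein is called positive with
#' probability `1 - specificity`. Target classes: the NTS predictors
#' (TargetP 2, PSORT II, MultiLoc2, NommPred) target
#' `planted_signal == "mitochondrial"`; TMHMM targets planted TM proteins
#' (a positive call reports the true helix count, a false positive reports
#' 2); the PTS1 predictor targets planted PTS1 proteins.
#'
#' @param truth Truth table from [generate_synthetic_proteome()].
#' @param per_tool_rates Data frame as returned by [default_tool_rates()].
#' @param seed Integer seed.
#' @return Evidence data frame in [read_evidence_table()] layout.
#' @export
generate_synthetic_evidence <- function(truth,
                                        per_tool_rates = default_tool_rates(),
                                        seed) {
  if (missing(seed)) stop2("generate_synthetic_evidence requires a seed")
  unknown <- setdiff(per_tool_rates$tool, .tools)
  if (length(unknown))
    stop2("unknown tool(s) in rates: ", paste(unknown, collapse = ", "))
  if (any(per_tool_rates$sensitivity < 0 | per_tool_rates$sensitivity > 1 |
          per_tool_rates$specificity < 0 | per_tool_rates$specificity > 1))
    stop2("sensitivity/specificity must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(truth)
  rows <- vector("list", nrow(per_tool_rates))
  for (j in seq_len(nrow(per_tool_rates))) {
    tool <- per_tool_rates$tool[j]
    setting <- per_tool_rates$setting[j]
    sens <- per_tool_rates$sensitivity[j]
    spec <- per_tool_rates$specificity[j]
    is_target <- switch(tool,
      tmhmm = truth$planted_signal == "tm",
      pts1predictor = truth$planted_signal == "pts1",
      truth$planted_signal == "mitochondrial")
    p_pos <- ifelse(is_target, sens, 1 - spec)
    pos <- runif(n) < p_pos
    if (tool == "tmhmm") {
      helices <- ifelse(pos, pmax(truth$tm_helices, 2L) * is_target +
                               2L * (!is_target), 0L)
      # a true positive reports the planted helix count
      helices[pos & is_target] <- truth$tm_helices[pos & is_target]
      rows[[j]] <- data.frame(protein_id = truth$protein_id, tool = tool,
                              setting = setting,
                              label = ifelse(helices > 0, "membrane",
                                             "other"),
                              raw_label = paste0("PredHel=", helices),
                              score = as.numeric(helices),
                              stringsAsFactors = FALSE)
    } else if (tool == "pts1predictor") {
      rows[[j]] <- data.frame(protein_id = truth$protein_id, tool = tool,
                              setting = setting,
                              label = ifelse(pos, "peroxisomal", "other"),
                              raw_label = ifelse(pos, "Targeted",
                                                 "Not targeted"),
                              score = ifelse(pos, runif(n, 0.5, 1),
                                             runif(n, 0, 0.4)),
                              stringsAsFactors = FALSE)
    } else {
      rows[[j]] <- data.frame(protein_id = truth$protein_id, tool = tool,
                              setting = setting,
                              label = ifelse(pos, "mitochondrial", "other"),
                              raw_label = ifelse(pos, "mit", "other"),
                              score = NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
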