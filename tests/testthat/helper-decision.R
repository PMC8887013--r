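ev_row <- function(id, tool, setting = "default", label = "mitochondrial") {
  data.frame(protein_id = id, tool = tool, setting = setting, label = label,
             raw_label = label, score = NA_real_, stringsAsFactors = FALSE)
}

# hand-written decision table over the three evidence channels.
# columns: homology present, NTS verdict (with single/multi deciding calls),
# experimental observation, hallmark homology -> expected tier
decision_table <- rbind(
  #               hom    nts        exp              hall   tier
  data.frame(hom = FALSE, nts = "none",   exp = "none",    hall = FALSE, tier = "-"),
  data.frame(hom = TRUE,  nts = "none",   exp = "none",    hall = FALSE, tier = "+?"),
  data.frame(hom = FALSE, nts = "single", exp = "none",    hall = FALSE, tier = "+?"),
  data.frame(hom = FALSE, nts = "multi",  exp = "none",    hall = FALSE, tier = "+?"),
  data.frame(hom = FALSE, nts = "none",   exp = "mito",    hall = FALSE, tier = "+?"),
  data.frame(hom = TRUE,  nts = "single", exp = "none",    hall = FALSE, tier = "+"),
  data.frame(hom = TRUE,  nts = "multi",  exp = "none",    hall = FALSE, tier = "+"),
  data.frame(hom = TRUE,  nts = "none",   exp = "mito",    hall = FALSE, tier = "+"),
  data.frame(hom = FALSE, nts = "single", exp = "mito",    hall = FALSE, tier = "+"),
  data.frame(hom = TRUE,  nts = "single", exp = "mito",    hall = FALSE, tier = "+"),
  # curated non-mitochondrial localization vs weak NTS-only support: out
  data.frame(hom = FALSE, nts = "single", exp = "nonmito", hall = FALSE, tier = "-"),
  # multi-tool NTS support survives a failed yeast localization
  data.frame(hom = FALSE, nts = "multi",  exp = "nonmito", hall = FALSE, tier = "+?"),
  data.frame(hom = TRUE,  nts = "none",   exp = "nonmito", hall = FALSE, tier = "+?"),
  data.frame(hom = TRUE,  nts = "single", exp = "nonmito", hall = FALSE, tier = "+"),
  # hallmark homologs are always retained at strong tier
  data.frame(hom = TRUE,  nts = "none",   exp = "none",    hall = TRUE,  tier = "+"),
  data.frame(hom = TRUE,  nts = "none",   exp = "nonmito", hall = TRUE,  tier = "+"),
  data.frame(hom = TRUE,  nts = "single", exp = "nonmito", hall = TRUE,  tier = "+"),
  data.frame(hom = TRUE,  nts = "multi",  exp = "mito",    hall = TRUE,  tier = "+"))

build_case <- function(hom, nts, exp, hall, id = "px") {
  nts_ev <- switch(nts,
    none = ev_row(id, "multiloc2", "animal", label = "other"),
    single = ev_row(id, "multiloc2", "animal"),
    multi = rbind(ev_row(id, "multiloc2", "animal"),
                  ev_row(id, "nommpred", "MRO")))
  verdicts <- nts_consensus(nts_ev, protein_ids = id)
  hom_ev <- if (hom)
    data.frame(protein_id = id, reference_set = "Mb_hydrogenosome",
               best_subject_id = "ref1", best_evalue = 1e-40,
               best_bitscore = 200,
               family = if (hall) "cpn10" else "PFO",
               stringsAsFactors = FALSE)
  exp_ev <- switch(exp,
    none = NULL,
    mito = data.frame(protein_id = id, observed = "mitochondrial",
                      note = "", stringsAsFactors = FALSE),
    nonmito = data.frame(protein_id = id, observed = "vesicular",
                         note = "", stringsAsFactors = FALSE))
  integrate_mro_evidence(verdicts, hom_ev, exp_ev)
}
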