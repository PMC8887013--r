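---
title: "Inferring organellar proteomes in anaerobic protists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring organellar proteomes in anaerobic protists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgatlas)
```

## The problem

Free-living anaerobic amoebae carry two reduced organelles whose proteomes
cannot be measured directly at useful depth: a mitochondrion-related
organelle (MRO — a hydrogenosome/mitosome-grade derivative of the
mitochondrion) and an anaerobic peroxisome. Their protein inventories are
instead *inferred* from a predicted proteome, by combining targeting-signal
grammars, the outputs of several subcellular-localization predictors,
homology to organellar proteomes of related species, and (for selected
candidates) heterologous localization in yeast. orgatlas implements this
inference as a deterministic, testable pipeline, together with the
genome-structure statistics (intron density and splice-boundary classes)
that characterize such genomes.

Nothing here re-implements an external predictor. TargetP 2, PSORT II,
MultiLoc2, NommPred, TMHMM and the PTS1 predictor are consumed as tabular
evidence under explicit dialects (`?evidence_dialects`); BLAST hits arrive
as standard tabular output. What the package owns is the *decision layer*:
the motif grammars, the consensus and fusion rules, the intron arithmetic,
and a synthetic-data generator that makes every rule testable against
planted ground truth.

## Peroxisomal targeting signals

Peroxisomal matrix proteins carry one of two signals recognized by the
Pex5/Pex7 import receptors:

* **PTS1** — a C-terminal tripeptide. The grammar used here is the
  position-class pattern `[SAP][KR][LM]` *minus* the tripeptides `AKM`,
  `PKM`, `PRM` (pattern-conforming but non-functional in this lineage),
  *plus* the literal `SRI` (functional despite falling outside the
  pattern). Expansion gives 3 × 2 × 2 = 12 tripeptides; with 3 exclusions
  and 1 extra, the accepted set has exactly 10 members:

```{r}
enumerate_pts1_set(pts_motif_config())
```

* **PTS2** — an N-terminal nonapeptide `R[LI]xxxxxHL`. Only matches whose
  full nine residues lie within the first `pts2_window` residues count.
  The window defaults to 40 residues: PTS2 signals sit near the mature
  N-terminus, and 40 covers known placements with margin while excluding
  internal chance matches; it is a config knob, not a constant. A
  documented variant widens the second position to `[LIV]`
  (`pts2_position2_class = c("L","I","V")`); the narrow `[LI]` class is
  the default and the variant is surfaced as an explicit switch rather
  than silently merged, because the two grammars produce different
  candidate sets.

Ambiguity codes (X, B, Z, U) never satisfy a fixed motif position —
conservative calling; the five wildcard positions accept any residue
letter. The scanners are anchored: PTS1 matches only at the C-terminus
(position `length − 2`), internal occurrences never count.

A protein becomes a peroxisomal candidate iff it carries a PTS motif or a
positive external PTS1-predictor call, **and** has zero predicted
transmembrane helices — membrane proteins reach the peroxisome by a
different route, so a TM prediction vetoes a matrix-protein call. The two
channels set the confidence tier: motif *and* predictor agreement is a
strong call (`+`), a single channel is weak (`+?`). Applying the TM filter
before or after the motif/predictor union gives the same final set; the
order is fixed (union first) only so intermediate logs are reproducible.

## The MRO consensus

N-terminal targeting sequences (NTS) of MRO proteins are short and
divergent, so no single predictor is reliable. The consensus rule treats
MultiLoc2 and NommPred — the two tools with protist-appropriate models
(NommPred is run in both its MRO and its *Dictyostelium* mode) — as
*deciding*: one mitochondrial call from any of their settings makes the
protein NTS-positive. TargetP 2 and PSORT II are recorded as *supporting*
but never flip a verdict. Plant-specific settings are dropped for
plastid-less organisms (`omit_plant_settings = TRUE`).

Final calls fuse three evidence lines — homology to reference organelle
proteomes, the NTS verdict, and curated heterologous-localization results
— by counting positive channels: ≥ 2 is strong (`+`), exactly 1 weak
(`+?`), 0 excluded (`-`). The thresholds formalize a confidence scheme
that the source material expresses only graphically, so they are exposed
(`strong_min`) rather than hardcoded. Three overrides encode the
arbitration patterns that a count alone gets wrong:

1. a curated *non*-mitochondrial localization (e.g. vesicles, cytosol)
   excludes a protein whose only other support is a single-tool NTS call —
   weak in-silico evidence does not survive contradicting wet-lab
   evidence;
2. homologs of hallmark mitochondrial families (default Tom40, Sam50,
   mtHSP70, cpn60, cpn10) stay at strong tier even when heterologous
   import fails. A failed import in yeast is an absence of evidence, not
   evidence of another compartment: archamoebal presequences often lack
   the positive charge yeast import requires. This is why the experimental
   override (1) demands an observed *other* compartment and applies only
   to weakly supported proteins, while hallmark retention (2) wins
   whenever both could fire;
3. a protein excluded from the MRO that carries a PTS motif is flagged
   `reassign_peroxisome` — mutually exclusive targeting interpretations
   are resolved toward the compartment with the concrete signal.

The full rule is pinned by an enumerated decision table in the test suite
(all channel combinations × override states), including the three
published-style fixture cases (a citrate-lyase-like exclusion, a
chaperonin-like retention, a reductase-like reassignment).

## Intron extraction and boundary classes

Gene models arrive as GFF3 (1-based inclusive coordinates, kept as such at
the interface; interval arithmetic internally uses half-open intervals and
converts back, which removes the classic off-by-one in gap derivation).
Introns are the gaps between consecutive exons of an mRNA. On the minus
strand, donor and acceptor dinucleotides are read from the reverse
complement, so the donor is always the transcription-5′ end. Splicing
dialects lacking exon rows fall back to CDS features.

Boundary classes are `GT-AG` (canonical spliceosomal), `GC-AG` (minor),
and `other` (including any `N` — no imputation). Introns shorter than 4 nt
cannot host disjoint boundary dinucleotides; they are kept, flagged
`too_short`, and classified `other`, because silently dropping them would
bias density estimates while trusting their boundaries would fabricate
classes.

Intron density (introns per gene) depends on what counts as a gene; the
`isoform_policy` makes the denominator explicit: `all_mrnas` (every
transcript), `longest_isoform`, or the default `unique_introns_per_gene`
(distinct intron coordinates per gene), which avoids double-counting
introns shared between isoforms. The default reflects that published
per-gene densities rarely state their denominator exactly; the policy is
recorded in every summary so numbers are comparable.

## The synthetic-data generator

Every decision rule above is exercised against generated data with planted
truth rather than against downloads:

* **Proteomes** (`generate_synthetic_proteome()`): background residues are
  uniform over the 20 standard amino acids (composition does not affect
  rule-based calls, so the simplest model is used; an empirical
  composition can be supplied by swapping the alphabet). Planted classes:
  PTS1 proteins end in a uniformly drawn accepted tripeptide; PTS2
  proteins carry one nonapeptide at a uniform position inside the window;
  decoys end in an excluded tripeptide; TM proteins carry a PTS1 motif
  *plus* two planted helices (so the veto is exercised); mitochondrial
  proteins are background sequence whose class only drives the evidence
  simulator. Accidental motifs are scrubbed from the background before
  planting, so scanner output equals planted truth exactly — the
  perfect-recovery tests measure the rules, not the generator's luck.
* **Evidence** (`generate_synthetic_evidence()`): each (tool, setting)
  labels each protein independently — target-class proteins positive with
  probability *sensitivity*, others with *1 − specificity*. At rates
  (1, 1) evidence equals truth; at lower rates recovered counts are tested
  against exact 99% binomial intervals.
* **Genomes** (`generate_synthetic_gene_models()`): per-gene intron counts
  are Poisson with mean 7.43 (the intron density the pipeline is designed
  around); boundary classes are drawn at probabilities 0.9841 / 0.0159 /
  remainder and written into the sequence. Intron lengths are uniform on
  [40, 500] nt and exon lengths uniform on [100, 300] nt — any
  positive-length model suffices for rule testing, so the simplest is
  used. Each gene sits on its own contig with 50 nt flanks, on a random
  strand.

All generators consume a single seeded RNG in documented field order, so
equal seeds give identical outputs.

What the simulator does *not* emulate: realistic NTS or TM sequence
content (predictors are out of scope, so their outputs are simulated
directly), homopolymer/GC structure of real contigs, alternative
isoforms, overlapping genes, and chance PTS motifs in real proteomes
(scrubbed here by construction). Passing the recovery suite therefore
shows the decision layer is faithful to its rules — not that the external
predictors are accurate on real data.

## Problem sizes and numerical choices

The shipped verification runs use 10,000 random proteins for the
scanner-vs-oracle comparison, 1,000 excluded-tripeptide decoys, a
400-protein evidence bundle for perfect-recovery checks, 1,000 planted
mitochondrial proteins for the noisy-sensitivity check, and a 1,000-gene
genome (≈ 7,400 introns) for the round-trip and rate-recovery statistics
— sizes at which the binomial/Poisson 99% intervals are tight enough to
be informative while the whole suite runs in well under a minute per
stage. Stochastic checks use exact quantile intervals
(`qbinom`/`qpois` at 0.005/0.995), not normal approximations. Tie-breaks
are total everywhere (best BLAST hit: bitscore, then e-value, then subject
id; candidate tables sorted by id), so identical inputs give byte-identical
outputs.

## Limitations

* The fusion thresholds reconstruct a combination rule that the source
  confidence scheme states only as tiers (`+`, `+?`, `-`); other
  reasonable reconstructions exist, which is why `strong_min` and the
  deciding-tool set are configuration, not constants.
* Whether PTS2 candidates should additionally be screened by the external
  predictor's PTS2 mode is not assumed; only the PTS1 predictor channel is
  integrated.
* Ortholog mapping for cross-species overlap is a curated input (the
  package counts pairs; it does not compute reciprocal best hits).
* Evidence dialect maps are best-effort reconstructions of predictor
  output formats, which drift between versions; all are user-overridable
  via the `generic` dialect.
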