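Synthetic stand-ins for curated cross-species inputs.

synthetic_ps_perox_candidates.txt  67 peroxisomal candidate ids for the focal
                                   species (63 placeholders + PPP, Nudt,
                                   myoIDH, DLDH named after the enzyme
                                   families shared across Archamoebae)
synthetic_mb_perox_candidates.txt  34 candidate ids for the partner species
synthetic_ortholog_map.tsv         curated ortholog pairs (id_a, id_b); only
                                   the four shared enzyme families pair ids
                                   present in both candidate lists

These are constructed examples with the same shape as curated inputs, not
data from any sequenced organism.
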