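# Gene-model config for the bundled synthetic 714-nt reporter gene.
# Coordinates are 1-based closed intervals on the coding strand.
gene_id: synthetic_cI
gap_interval: [354, 515]          # single-stranded gap filled by the enzyme
replicated_interval: [1, 515]     # gap plus strand-displaced stretch
scoring_region:                   # 99 nt (33 codons) in two intervals
  - [19, 66]
  - [340, 390]
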