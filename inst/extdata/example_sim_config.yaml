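# Example simulation config for `ampledit simulate`.
# Emulates an embryo dominated by the 9 bp deletion template allele with a
# minor template-plus-substitution variant (a 93/7 mixture).
embryo_id: demo
locus:
  length: 550
  key_region_length: 71
  n_poly_sites: 3
n_read_pairs: 5000
edits:
  - template: del9
    background: B
mixture:
  - allele: "9 bp DEL-B"
    freq: 0.93
  - allele: "WT-B"
    freq: 0.07
read_sim:
  read_length: 250
  mean_quality: 30
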