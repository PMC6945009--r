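# Reference triploid scenario: 6 Mbp genome, two reference-like and one
# divergent haplophase, ~60x depth, a 600 kb mid-arm duplication adding a
# reference-like copy, two N-gap stretches, CDS-aware InDel length bias.
# Divergence rates are chosen for statistical power at desk scale, not for
# biological fidelity to any particular cultivar.
seed: 1
chromosomes:
  - {name: chr01, length: 2000000}
  - {name: chr02, length: 2000000}
  - {name: chr03, length: 2000000}
baseline_ploidy: 3
n_ref_like: 2
divergent_snv_rate: 0.005
ref_like_snv_rate: 0.0005
hom_alt_snv_rate: 0.001
duplication: {chrom: chr02, start: 800001, end: 1400000, source: ref_like}
depth_per_copy: 20
depth_model: poisson
divergent_map_rate: 0.95
n_gaps:
  - {chrom: chr01, start: 400001, end: 600000}
  - {chrom: chr03, start: 1500001, end: 1600000}
genes: {count: 90, mean_cds_length: 900}
indel_rate: 0.0005
indel_max_len: 12
cds_mod3_enrichment: 3
fail_frac: 0.05
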