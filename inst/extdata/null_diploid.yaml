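# Negative control: a plain diploid with one reference-like and one
# divergent haplophase, no duplication, no mapping-rate penalty and no
# frame-preservation bias.  Heterozygous sites cluster at allele frequency
# 0.5; no copy-number segment other than the baseline should be called.
seed: 1
chromosomes:
  - {name: chr01, length: 2000000}
  - {name: chr02, length: 2000000}
  - {name: chr03, length: 2000000}
baseline_ploidy: 2
n_ref_like: 1
divergent_snv_rate: 0.005
ref_like_snv_rate: 0.0
hom_alt_snv_rate: 0.001
depth_per_copy: 20
depth_model: poisson
divergent_map_rate: 1.0
n_gaps:
  - {chrom: chr01, start: 400001, end: 600000}
genes: {count: 90, mean_cds_length: 900}
indel_rate: 0.0005
indel_max_len: 12
cds_mod3_enrichment: 1
fail_frac: 0.05
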