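schema_version: 1
thresholds:
  min_mapped_reads: 1.0e+07
  min_coverage_uniformity: 95.0
  min_median_mol_cov: 1500.0
  min_mol_uniformity: 80.0
  min_mean_read_length: 80.0
  min_aq20: 80.0
  max_mapd: 0.4
  cna_min_ratio: 1.15
  cna_max_p: 1.0e-05
  fusion_min_copies: 3.0
  internal_control_min_copies: 3.0
  ntc_max_reads: 6.0e+06
  ntc_max_read_length: 45.0
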