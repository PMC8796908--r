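seed: 42
simulate:
  preset_a: threespine
  preset_b: tubesnout
  n_snps: 5000
  n_genes: 120
  n_chromosomes: 2
  chromosome_length: 1000000
  n_selected_a: 6
  n_selected_b: 6
  convergent_fraction: 0.02
window_size: 50000
outlier_quantile: 0.999
p_success: 0.001
nullw:
  n_control: 2000
  alpha: 0.05
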