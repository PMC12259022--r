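# Example cswitch pipeline configuration.
# Top-level keys mirror synthetic_config(); the pipeline block holds stage
# parameters.
seed: 1
genome_length: 6000000
n_chroms: 3
n_smad_sites: 200
cobound_fraction: 0.5
dependence_effect_delta: 1.0
relocation_fraction_rho: 0.5
relocation_distance: 200000
n_replicates: 3
library_size: 1000000
peak_width: 600
background_rate: 0.01
n_genes: 300
repressed_set_sizes:
  bmp: 30
  cofactor: 20
  overlap: 8
pipeline:
  fdr: 0.1
  alpha: 0.01
  flank_window: 200000
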