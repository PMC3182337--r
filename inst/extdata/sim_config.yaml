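n_subjects: 20.0
time_points:
- 0.0
- 2.0
- 4.0
- 6.0
- 8.0
- 10.0
fold_changes:
- 2.0
- 2.5
- 3.0
- 3.5
genes_per_group: 10.0
n_null_genes: 960.0
sigma_e: 0.5
sigma_b: 0.3
missing_proportions:
- 0.0
- 0.25
- 0.5
- 0.7
n_replicates: 10.0
fdr_threshold: 0.1
seed: 1
note: sigma_e/sigma_b are package defaults; the reference design does not state them
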