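# Shared configuration for the analysis drivers (analysis/01 ... 05).
# Everything downstream is a pure function of these values.
seed: 20260927
n_genes: 1000
program_size: 40
n_samples: 200
beta: 1
mutation_effect: 2
n_signal_datasets: 7
n_null_datasets: 2
n_dead_datasets: 1
n_overlapping_signatures: 4
n_random_signatures: 4
overlap_fraction: 0.8
signature_length: 40
n_perm: 100
alpha: 0.05
rate_cutoff: 50
na_cut: 0.05
di_cut: 9
cor_threshold: 0.35
ic50_cutoff: -1.0
drfs_horizon: 3.0
n_cell_lines: 20
sens_fraction: 0.65
n_neoadjuvant: 508
neoadjuvant_baseline_hazard: 0.12
out_dir: results
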