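# Shared setup for the analysis drivers: load the package, read the study
# configuration and rebuild the (deterministic) simulation inputs.

library(sigscreen)

cfg_file <- file.path("analysis", "config.yaml")
if (!file.exists(cfg_file)) cfg_file <- "config.yaml"  # run from analysis/
CONFIG <- yaml::read_yaml(cfg_file)

OUT <- CONFIG$out_dir
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

base_sim_config <- function(seed_offset = 0L, ...) {
  sim_config(n_genes = CONFIG$n_genes, n_samples = CONFIG$n_samples,
             program_size = CONFIG$program_size, beta = CONFIG$beta,
             mutation_effect = CONFIG$mutation_effect,
             seed = CONFIG$seed + seed_offset, ...)
}

# The synthetic study: signal + null + dead-array datasets sharing one
# planted hazard program, and a matched signature collection.
build_study <- function() {
  n_total <- CONFIG$n_signal_datasets + CONFIG$n_null_datasets +
    CONFIG$n_dead_datasets
  sim <- simulate_registry(
    base_sim_config(),
    n_datasets = n_total,
    betas = c(rep(CONFIG$beta, CONFIG$n_signal_datasets),
              rep(0, CONFIG$n_null_datasets + CONFIG$n_dead_datasets)),
    dead_fraction = c(rep(0, n_total - CONFIG$n_dead_datasets),
                      rep(0.15, CONFIG$n_dead_datasets)))
  sigs <- simulate_signature_collection(
    sim$truth,
    n_overlapping = CONFIG$n_overlapping_signatures,
    n_random = CONFIG$n_random_signatures,
    overlap_fraction = CONFIG$overlap_fraction,
    length = CONFIG$signature_length,
    seed = CONFIG$seed + 1000L)
  list(sim = sim, signatures = sigs)
}

run_cfg <- function() {
  run_config(alpha = CONFIG$alpha, rate_cutoff = CONFIG$rate_cutoff,
             n_perm = CONFIG$n_perm, na_cut = CONFIG$na_cut,
             di_cut = CONFIG$di_cut, cor_threshold = CONFIG$cor_threshold,
             ic50_cutoff = CONFIG$ic50_cutoff,
             drfs_horizon = CONFIG$drfs_horizon, seed = CONFIG$seed)
}

write_tsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
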