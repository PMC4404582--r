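#!/usr/bin/env Rscript
# Stage 1 — materialize the synthetic study.
#
# Builds a registry of survival datasets sharing one planted hazard
# program (signal datasets carry it into survival; null datasets do not;
# dead-array datasets contain broken profiles that must be caught as N/A),
# plus a signature collection mixing planted-overlap and random
# signatures. Everything is written as TSV/GMT/YAML so later stages — or a
# user with real data — run from files alone.

source(file.path("analysis", "00_common.R"))

study <- build_study()

data_dir <- file.path(OUT, "data")
manifest <- write_registry(study$sim$registry, data_dir)
message("registry manifest: ", manifest)

gmt <- file.path(data_dir, "signatures.gmt")
write_signature_collection(study$signatures, gmt)
message("signature collection: ", gmt)

truth <- data.frame(gene = study$sim$truth$program_genes,
                    direction = ifelse(study$sim$truth$program_signs > 0,
                                       "up", "down"))
write_tsv(truth, "planted_program.tsv")

message(sprintf(
  "simulated %d datasets (%d signal, %d null, %d dead) x %d samples; %d signatures",
  length(study$sim$registry), CONFIG$n_signal_datasets,
  CONFIG$n_null_datasets, CONFIG$n_dead_datasets, CONFIG$n_samples,
  length(study$signatures)))
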