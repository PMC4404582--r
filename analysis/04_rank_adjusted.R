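#!/usr/bin/env Rscript
# Stage 4 — permutation-adjusted ranking over validated datasets.
#
# For each candidate cell, the adjusted P value is the fraction of
# length-matched random signatures with a strictly smaller log-rank P on
# the same dataset. Candidates are ranked by their adjusted median P over
# the validated datasets; the top set has median < alpha.

source(file.path("analysis", "00_common.R"))

registry <- read_registry(file.path(OUT, "data", "registry.yaml"))
signatures <- read_signature_collection(file.path(OUT, "data",
                                                  "signatures.gmt"))
ranking <- utils::read.delim(file.path(OUT, "signature_ranking.tsv"))
qc <- utils::read.delim(file.path(OUT, "dataset_qc.tsv"))
candidates <- ranking$signature_id[ranking$candidate]
validated <- qc$dataset_id[qc$verdict == "pass"]
stopifnot(length(validated) > 0)

screen <- run_screen(signatures[candidates], registry, alpha = CONFIG$alpha)
adjusted <- adjusted_p_matrix(screen, registry, signatures[candidates],
                              n_perm = CONFIG$n_perm, seed = CONFIG$seed)
write_tsv(adjusted, "adjusted_p.tsv")

adj_ranking <- rank_by_adjusted_median_p(adjusted, validated,
                                         alpha = CONFIG$alpha)
write_tsv(adj_ranking, "adjusted_ranking.tsv")

message(sprintf("top signatures (adjusted median P < %.2f): %s",
                CONFIG$alpha,
                paste(adj_ranking$signature_id[adj_ranking$top],
                      collapse = ", ")))
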