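#!/usr/bin/env Rscript
# Stage 2 — the log-rank screen.
#
# Reads the registry and signature collection written by stage 1, runs
# every signature against every dataset (Spearman-distance average-linkage
# clustering, first-bifurcation split, log-rank + Cox HR + c-index), and
# ranks signatures by their percent-significant rate. Candidates must
# predict outcome (P < alpha) in strictly more than half the datasets.

source(file.path("analysis", "00_common.R"))

registry <- read_registry(file.path(OUT, "data", "registry.yaml"))
signatures <- read_signature_collection(file.path(OUT, "data",
                                                  "signatures.gmt"))

screen <- run_screen(signatures, registry, alpha = CONFIG$alpha)
write_screen_matrix(screen,
                    long_path = file.path(OUT, "screen_long.tsv"),
                    wide_path = file.path(OUT, "screen_pvalues.tsv"))

ranking <- rank_signatures_by_rate(screen, cutoff = CONFIG$rate_cutoff)
write_tsv(ranking, "signature_ranking.tsv")

message(sprintf("%d log-rank tests scheduled (%d signatures x %d datasets)",
                nrow(screen), length(signatures), length(registry)))
message(sprintf("%d candidate signature(s) above the %d%% rate cutoff: %s",
                sum(ranking$candidate), CONFIG$rate_cutoff,
                paste(ranking$signature_id[ranking$candidate],
                      collapse = ", ")))
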