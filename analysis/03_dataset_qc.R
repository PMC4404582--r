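#!/usr/bin/env Rscript
# Stage 3 — random-signature nulls and dataset quality control.
#
# For every dataset and candidate signature length, builds a null of
# length-matched random signatures drawn from that dataset's own gene
# universe, then validates datasets: a dataset is rejected when its N/A
# rate exceeds 5%, or when its differential index (mean percent-significant
# of candidates minus mean percent-significant of random signatures) falls
# below 9 percentage points.

source(file.path("analysis", "00_common.R"))

registry <- read_registry(file.path(OUT, "data", "registry.yaml"))
signatures <- read_signature_collection(file.path(OUT, "data",
                                                  "signatures.gmt"))
ranking <- utils::read.delim(file.path(OUT, "signature_ranking.tsv"))
candidates <- ranking$signature_id[ranking$candidate]
stopifnot(length(candidates) > 0)

screen <- run_screen(signatures[candidates], registry, alpha = CONFIG$alpha)

lengths <- unique(vapply(signatures[candidates],
                         function(s) length(s$genes), integer(1)))
nulls <- lapply(registry, function(ds) {
  per_len <- lapply(lengths, function(L)
    build_null(ds, L, n_perm = CONFIG$n_perm, seed = CONFIG$seed))
  if (length(per_len) == 1L) per_len[[1L]] else per_len
})

qc <- validate_datasets(screen, nulls, na_cut = CONFIG$na_cut,
                        di_cut = CONFIG$di_cut, alpha = CONFIG$alpha)
write_tsv(qc, "dataset_qc.tsv")

message(sprintf("validated %d of %d datasets (%d fail_na, %d fail_di)",
                sum(qc$verdict == "pass"), nrow(qc),
                sum(qc$verdict == "fail_na"), sum(qc$verdict == "fail_di")))
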