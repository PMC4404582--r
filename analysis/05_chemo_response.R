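#!/usr/bin/env Rscript
# Stage 5 — chemosensitivity prediction in a neoadjuvant cohort.
#
# Regenerates (deterministically, from the shared config seed) a
# drug-sensitive cell-line panel and a neoadjuvant cohort carrying the
# same planted program as the survival study, then evaluates the top
# signature two ways: the prospective cell-line-centroid classifier
# (Spearman rho > 0.35 against the mean expression of log(IC50) < -1
# lines) and the retrospective clustering-based labels. Both are scored by
# PPV/NPV against pCR/RD, RCB class and 3-year DRFS, plus a Kaplan-Meier
# comparison of the predicted groups.

source(file.path("analysis", "00_common.R"))

adj_ranking <- utils::read.delim(file.path(OUT, "adjusted_ranking.tsv"))
top_id <- adj_ranking$signature_id[1L]
signatures <- read_signature_collection(file.path(OUT, "data",
                                                  "signatures.gmt"))
sig <- signatures[[top_id]]
message("evaluating top signature: ", top_id)

study <- build_study()  # deterministic: same planted program as stage 1
program <- study$sim$truth$program_genes

neo_cfg <- base_sim_config(baseline_hazard = CONFIG$neoadjuvant_baseline_hazard)
panel <- simulate_cellline_panel(neo_cfg, n_lines = CONFIG$n_cell_lines,
                                 sens_fraction = CONFIG$sens_fraction,
                                 program_genes = program)
neo <- simulate_neoadjuvant_cohort(neo_cfg,
                                   n_patients = CONFIG$n_neoadjuvant,
                                   program_genes = program)$dataset

lines <- select_sensitive_cell_lines(panel, cutoff = CONFIG$ic50_cutoff)
message(sprintf("%d drug-sensitive cell lines (log IC50 < %.1f)",
                length(lines), CONFIG$ic50_cutoff))
centroid <- build_centroid(panel, lines, sig)

preds <- list(
  centroid = classify_by_centroid(neo, centroid,
                                  threshold = CONFIG$cor_threshold),
  clustering = classify_by_clustering(neo, sig)
)

rows <- list()
for (method in names(preds)) {
  pred <- preds[[method]]
  for (ep in c("pCR/RD", "RCB", "DRFS3y")) {
    m <- response_metrics(pred, neo$clinical, ep,
                          horizon = CONFIG$drfs_horizon)
    rows[[paste(method, ep)]] <- data.frame(
      method = method, endpoint = ep, tp = m$tp, fp = m$fp, tn = m$tn,
      fn = m$fn, ppv = round_half_up(m$ppv, 1),
      npv = round_half_up(m$npv, 1),
      sensitivity = round_half_up(m$sensitivity, 1),
      specificity = round_half_up(m$specificity, 1),
      n_evaluable = m$n_evaluable, n_indeterminate = m$n_indeterminate)
  }
}
metrics <- do.call(rbind, rows)
rownames(metrics) <- NULL
write_tsv(metrics, "chemo_metrics.tsv")

pred_out <- do.call(rbind, lapply(names(preds), function(method)
  data.frame(method = method, as.data.frame(preds[[method]]))))
write_tsv(pred_out, "chemo_predictions.tsv")

km <- km_by_prediction(preds$centroid, neo$clinical$time, neo$clinical$event)
km_steps <- do.call(rbind, lapply(names(km$curves), function(g)
  data.frame(group = g, km$curves[[g]])))
write_tsv(km_steps, "chemo_km_curves.tsv")
message(sprintf("KM log-rank P (centroid groups): %.4g", km$logrank$p_value))
print(metrics[, c("method", "endpoint", "ppv", "npv", "n_evaluable")])
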