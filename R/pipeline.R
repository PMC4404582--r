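# End-to-end pipeline: screen -> random-signature nulls -> dataset QC and
# validation -> adjusted-P ranking -> (optional) chemo-response evaluation,
# with every artifact written as TSV/YAML under a run directory.

#' Assemble a run configuration
#'
#' Every screening threshold is surfaced here with its conventional default:
#' significance alpha 0.05, candidate cutoff > 50%, N/A-rate cut 5%,
#' differential-index cut 9 percentage points, centroid correlation
#' threshold 0.35, log(IC50) sensitivity cutoff -1, DRFS horizon 3 years.
#'
#' @param alpha log-rank significance threshold.
#' @param rate_cutoff candidate significant-rate cutoff (percent, strict).
#' @param n_perm random signatures per (dataset, length) null.
#' @param na_cut,di_cut dataset validation thresholds.
#' @param cor_threshold centroid classification threshold.
#' @param ic50_cutoff log(IC50) sensitivity cutoff.
#' @param drfs_horizon DRFS dichotomization horizon in years.
#' @param label_mode risk-label rule.
#' @param seed master seed.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(alpha = 0.05, rate_cutoff = 50, n_perm = 1000,
                       na_cut = 0.05, di_cut = 9, cor_threshold = 0.35,
                       ic50_cutoff = -1.0, drfs_horizon = 3.0,
                       label_mode = "by_direction", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(alpha = alpha, rate_cutoff = rate_cutoff, n_perm = n_perm,
                 na_cut = na_cut, di_cut = di_cut,
                 cor_threshold = cor_threshold, ic50_cutoff = ic50_cutoff,
                 drfs_horizon = drfs_horizon, label_mode = label_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full validation pipeline
#'
#' Stages: (1) screen every signature against every dataset; (2) rank by
#' significant rate and select candidates; (3) build length-matched random
#' nulls and validate datasets by N/A rate and differential index; (4) rank
#' candidates by adjusted median P over validated datasets; (5) optionally
#' evaluate chemo-response prediction on a neoadjuvant cohort with a
#' cell-line-centroid classifier. All tables are written as TSV under
#' \code{out_dir} together with a YAML run manifest; outputs are a pure
#' function of (inputs, config).
#'
#' @param signatures named list of \code{gene_signature}s.
#' @param registry a \code{dataset_registry}.
#' @param cfg a \code{\link{run_config}}.
#' @param out_dir output directory (created); NULL to skip writing.
#' @param panel optional \code{cellline_panel} for the chemo stage.
#' @param neo_cohort optional neoadjuvant \code{expression_dataset}.
#' @param chemo_signature signature id to use for the chemo stage (default:
#'   top-ranked candidate).
#' @return A list with \code{screen} (matrix), \code{ranking},
#'   \code{candidates}, \code{qc} (validation table), \code{validated_ids},
#'   \code{adjusted}, \code{adjusted_ranking}, and, when the chemo inputs
#'   are supplied, \code{chemo} (predictions, metrics, KM comparison).
#' @export
run_full_pipeline <- function(signatures, registry, cfg = run_config(),
                              out_dir = NULL, panel = NULL,
                              neo_cohort = NULL, chemo_signature = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  res <- list(config = cfg)

  # stage 1-2: screen and rate ranking
  screen <- run_screen(signatures, registry, alpha = cfg$alpha,
                       label_mode = cfg$label_mode)
  ranking <- rank_signatures_by_rate(screen, cutoff = cfg$rate_cutoff)
  candidates <- ranking$signature_id[ranking$candidate]
  res$screen <- screen
  res$ranking <- ranking
  res$candidates <- candidates

  # stage 3: nulls + dataset validation over candidate cells
  cand_sigs <- signatures[candidates]
  if (length(candidates) > 0L) {
    cand_matrix <- screen[screen$signature_id %in% candidates, , drop = FALSE]
    attributes(cand_matrix)[c("signature_ids", "dataset_ids", "alpha")] <-
      list(candidates, .matrix_datasets(screen), cfg$alpha)
    class(cand_matrix) <- class(screen)
    lengths <- unique(vapply(cand_sigs, function(s) length(s$genes),
                             integer(1)))
    nulls <- lapply(registry, function(ds) {
      per_len <- lapply(lengths, function(L) {
        build_null(ds, L, n_perm = cfg$n_perm, seed = cfg$seed)
      })
      if (length(per_len) == 1L) per_len[[1L]] else per_len
    })
    qc <- validate_datasets(cand_matrix, nulls, na_cut = cfg$na_cut,
                            di_cut = cfg$di_cut, alpha = cfg$alpha)
    validated_ids <- qc$dataset_id[qc$verdict == "pass"]

    # stage 4: adjusted-P ranking over validated datasets
    adjusted <- adjusted_p_matrix(cand_matrix, registry, cand_sigs,
                                  n_perm = cfg$n_perm, seed = cfg$seed)
    adj_ranking <- if (length(validated_ids)) {
      rank_by_adjusted_median_p(adjusted, validated_ids, alpha = cfg$alpha)
    } else NULL
    res$qc <- qc
    res$validated_ids <- validated_ids
    res$adjusted <- adjusted
    res$adjusted_ranking <- adj_ranking
  }

  # stage 5: chemo-response evaluation
  if (!is.null(panel) && !is.null(neo_cohort)) {
    if (is.null(chemo_signature)) {
      chemo_signature <- if (length(res$candidates)) res$candidates[1L] else
        ranking$signature_id[1L]
    }
    sig <- signatures[[chemo_signature]]
    lines <- select_sensitive_cell_lines(panel, cutoff = cfg$ic50_cutoff)
    centroid <- build_centroid(panel, lines, sig)
    pred <- classify_by_centroid(neo_cohort, centroid,
                                 threshold = cfg$cor_threshold)
    metrics <- list(
      pcr_rd = response_metrics(pred, neo_cohort$clinical, "pCR/RD"),
      rcb = response_metrics(pred, neo_cohort$clinical, "RCB"),
      drfs3y = response_metrics(pred, neo_cohort$clinical, "DRFS3y",
                                horizon = cfg$drfs_horizon)
    )
    km <- km_by_prediction(pred, neo_cohort$clinical$time,
                           neo_cohort$clinical$event)
    res$chemo <- list(signature_id = chemo_signature, n_lines = length(lines),
                      prediction = pred, metrics = metrics, km = km)
  }

  if (!is.null(out_dir)) .write_pipeline_artifacts(res, out_dir)
  res
}

.write_pipeline_artifacts <- function(res, out_dir) {
  write_screen_matrix(res$screen,
                      long_path = file.path(out_dir, "screen_long.tsv"),
                      wide_path = file.path(out_dir, "screen_pvalues.tsv"))
  .write_tsv(res$ranking, file.path(out_dir, "signature_ranking.tsv"))
  if (!is.null(res$qc)) {
    .write_tsv(res$qc, file.path(out_dir, "dataset_qc.tsv"))
    .write_tsv(res$adjusted, file.path(out_dir, "adjusted_p.tsv"))
    if (!is.null(res$adjusted_ranking)) {
      .write_tsv(res$adjusted_ranking,
                 file.path(out_dir, "adjusted_ranking.tsv"))
    }
  }
  if (!is.null(res$chemo)) {
    .write_tsv(as.data.frame(res$chemo$prediction),
               file.path(out_dir, "chemo_predictions.tsv"))
    mets <- do.call(rbind, lapply(res$chemo$metrics, function(m) {
      data.frame(endpoint = m$endpoint, tp = m$tp, fp = m$fp, tn = m$tn,
                 fn = m$fn, ppv = m$ppv, npv = m$npv,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 n_evaluable = m$n_evaluable,
                 n_indeterminate = m$n_indeterminate)
    }))
    .write_tsv(mets, file.path(out_dir, "chemo_metrics.tsv"))
  }
  cfg <- res$config
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' Materialize and run a self-contained synthetic demo
#'
#' Builds a miniature of the full study: a registry of signal and
#' noisy/null datasets sharing one planted hazard program, a signature
#' collection (planted-overlap and random), a drug-sensitive cell-line
#' panel and a neoadjuvant cohort, then runs the whole pipeline. All sizes
#' are deliberately small so the demo runs in minutes on one CPU.
#'
#' @param out_dir output directory; NULL to skip writing.
#' @param seed master seed.
#' @param n_signal,n_null,n_dead dataset counts: prognostic-signal datasets,
#'   null datasets (beta = 0) and dead-array datasets (forced N/A).
#' @param n_samples samples per dataset.
#' @param n_genes gene universe size.
#' @param n_overlapping,n_random signature counts.
#' @param n_perm random signatures per null.
#' @param cfg optional \code{\link{run_config}} overriding the defaults.
#' @return The \code{\link{run_full_pipeline}} result, plus
#'   \code{registry}, \code{signatures}, \code{truth}.
#' @export
make_demo <- function(out_dir = NULL, seed = 1L, n_signal = 7, n_null = 2,
                      n_dead = 1, n_samples = 200, n_genes = 1000,
                      n_overlapping = 4, n_random = 4, n_perm = 100,
                      cfg = NULL) {
  n_total <- n_signal + n_null + n_dead
  base_cfg <- sim_config(n_genes = n_genes, n_samples = n_samples,
                         program_size = 40, beta = 1, mutation_effect = 2,
                         seed = seed)
  sim <- simulate_registry(base_cfg, n_datasets = n_total,
                           betas = c(rep(1, n_signal), rep(0, n_null),
                                     rep(0, n_dead)),
                           dead_fraction = c(rep(0, n_signal + n_null),
                                             rep(0.15, n_dead)))
  sigs <- simulate_signature_collection(sim$truth,
                                        n_overlapping = n_overlapping,
                                        n_random = n_random,
                                        overlap_fraction = 0.8, length = 40,
                                        seed = seed + 1000L)
  panel <- simulate_cellline_panel(base_cfg, n_lines = 20,
                                   sens_fraction = 0.65,
                                   program_genes = sim$truth$program_genes)
  neo <- simulate_neoadjuvant_cohort(base_cfg, n_patients = max(n_samples, 150),
                                     program_genes = sim$truth$program_genes)
  if (is.null(cfg)) cfg <- run_config(n_perm = n_perm, seed = seed)
  res <- run_full_pipeline(sigs, sim$registry, cfg = cfg, out_dir = out_dir,
                           panel = panel, neo_cohort = neo$dataset)
  res$registry <- sim$registry
  res$signatures <- sigs
  res$truth <- sim$truth
  res
}
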