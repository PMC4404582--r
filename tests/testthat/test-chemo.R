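# Chemosensitivity prediction: DRFS dichotomization, sensitive-line
# selection, centroids, classification and response metrics.

test_that("DRFS dichotomizes with censoring-aware indeterminates", {
  expect_equal(as.character(dichotomize_drfs(2.0, 1)), "early_event")
  expect_equal(as.character(dichotomize_drfs(5.0, 0)), "survivor")
  expect_equal(as.character(dichotomize_drfs(5.0, 1)), "survivor")
  expect_equal(as.character(dichotomize_drfs(2.0, 0)), "indeterminate")
})

test_that("sensitive-line selection is strict and honors and/or", {
  cfg <- sim_config(n_genes = 100, program_size = 10, n_decoy_modules = 0,
                    seed = 71)
  panel <- simulate_cellline_panel(cfg, n_lines = 6, sens_fraction = 0.5)
  panel$log_ic50 <- matrix(
    c(-1.5, -1.0, -0.5, 0.2, -2.0, 1.0,    # taxane
      0.5, 0.5, 0.5, -1.2, 0.5, 0.5),      # anthracycline
    ncol = 2, dimnames = list(rownames(panel$log_ic50),
                              c("taxane", "anthracycline")))

  # boundary: log IC50 exactly -1.0 is excluded
  tax <- select_sensitive_cell_lines(panel, drugs = "taxane")
  expect_setequal(tax, c("CL001", "CL005"))

  # sensitive to anthracycline only is included under and/or
  both <- select_sensitive_cell_lines(panel,
                                      drugs = c("taxane", "anthracycline"))
  expect_setequal(both, c("CL001", "CL004", "CL005"))
  expect_true(all(tax %in% both))  # and/or monotonicity

  expect_error(select_sensitive_cell_lines(panel, drugs = "nonexistent"),
               "lacks drug")
  panel$log_ic50[] <- 2
  expect_error(select_sensitive_cell_lines(panel), "no sensitive")
})

test_that("generator panels yield the expected sensitive count", {
  cfg <- sim_config(seed = 72)
  panel <- simulate_cellline_panel(cfg, n_lines = 20, sens_fraction = 0.65)
  expect_length(select_sensitive_cell_lines(panel), 13)
})

test_that("centroids average gene values across lines", {
  cfg <- sim_config(n_genes = 60, program_size = 10, n_decoy_modules = 0,
                    seed = 73)
  panel <- simulate_cellline_panel(cfg, n_lines = 6, sens_fraction = 0.5)
  sig <- gene_signature("S", rownames(panel$expression)[1:10])
  lines <- rownames(panel$log_ic50)[1:2]
  cen <- build_centroid(panel, lines, sig)
  g <- names(cen$values)[1]
  expect_equal(cen$values[[g]], mean(panel$expression[g, lines]))
  expect_equal(cen$n_lines_used, 2)

  # invariant to line ordering
  cen_rev <- build_centroid(panel, rev(lines), sig)
  expect_equal(cen_rev$values, cen$values)

  expect_error(build_centroid(panel, lines[1], sig), "at least 2")

  sig_missing <- gene_signature("M", c(rownames(panel$expression)[1:6],
                                       paste0("ABS", 1:4)))
  expect_warning(cen_m <- build_centroid(panel, lines, sig_missing), "missing")
  expect_length(cen_m$values, 6)
  sig_few <- gene_signature("F", c(rownames(panel$expression)[1:3],
                                   paste0("ABS", 1:7)))
  expect_error(suppressWarnings(build_centroid(panel, lines, sig_few)),
               ">= 5")
})

test_that("centroid classification has the documented strict boundary", {
  # a 9-gene profile engineered to have Spearman rho exactly 0.35
  genes <- sprintf("G%02d", 1:9)
  cen <- structure(list(signature_id = "S",
                        values = setNames(as.numeric(1:9), genes),
                        n_lines_used = 2),
                   class = "drug_centroid")
  prof_boundary <- setNames(c(6, 5, 4, 3, 2, 1, 9, 8, 7), genes)
  m <- cbind(P1 = as.numeric(1:9),          # identical ranks: rho = 1
             P2 = prof_boundary,            # rho = 0.35 exactly
             P3 = as.numeric(9:1))          # reversed: rho = -1
  rownames(m) <- genes
  ds <- expression_dataset("NEO", m,
                           data.frame(sample_id = colnames(m),
                                      time = c(1, 2, 3), event = 1L),
                           endpoint = "DRFS")
  pred <- classify_by_centroid(ds, cen)
  expect_equal(pred$rho, c(1, 0.35, -1), tolerance = 1e-12)
  expect_equal(pred$label, c("sensitive", "insensitive", "insensitive"))
})

test_that("centroid classification is invariant to monotone transforms", {
  cfg <- sim_config(seed = 74)
  panel <- simulate_cellline_panel(cfg)
  neo <- simulate_neoadjuvant_cohort(cfg, n_patients = 40,
                                     program_genes = panel$program_genes)
  sig <- gene_signature("P", panel$program_genes)
  cen <- build_centroid(panel, select_sensitive_cell_lines(panel), sig)
  pred <- classify_by_centroid(neo$dataset, cen)

  ds_exp <- neo$dataset
  ds_exp$matrix <- exp(0.5 * ds_exp$matrix + 2)
  pred_exp <- classify_by_centroid(ds_exp, cen)
  expect_equal(pred_exp$rho, pred$rho, tolerance = 1e-12)
  expect_identical(pred_exp$label, pred$label)

  ds_const <- neo$dataset
  ds_const$matrix[, 1] <- 0
  expect_error(classify_by_centroid(ds_const, cen), "constant")
})

test_that("clustering-based prediction maps risk groups to response labels", {
  fix <- make_two_block_dataset(shift = 3, seed = 75)
  ds <- fix$ds
  dirs <- setNames(rep("up", length(ds$gene_ids)), ds$gene_ids)
  sig <- full_signature(ds, directions = dirs)
  pred <- classify_by_clustering(ds, sig)
  expect_equal(attr(pred, "method"), "clustering")
  # blocks map one-to-one onto sensitive/insensitive
  expect_length(unique(pred$label[fix$block == "A"]), 1)
  expect_length(unique(pred$label[fix$block == "B"]), 1)
  # high-risk block (higher mean over up-genes) is predicted insensitive
  mean_by_label <- tapply(colMeans(ds$matrix), pred$label, mean)
  expect_gt(mean_by_label[["insensitive"]], mean_by_label[["sensitive"]])

  sig_absent <- gene_signature("ABS", paste0("NOPE", 1:10))
  expect_error(classify_by_clustering(ds, sig_absent), "low_coverage")
})

test_that("cluster-predicted insensitive patients are enriched for RD", {
  hits <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(beta = 1, mutation_effect = 2, seed = 7600 + r)
    neo <- simulate_neoadjuvant_cohort(cfg, n_patients = 200,
                                       pcr_intercept = -0.8,
                                       pcr_slope = -1.5)
    sig <- program_signature(neo$truth)
    pred <- tryCatch(classify_by_clustering(neo$dataset, sig),
                     error = function(e) NULL)
    if (is.null(pred)) next
    rd <- neo$dataset$clinical$pcr == "RD"
    if (mean(rd[pred$label == "insensitive"]) >
          mean(rd[pred$label == "sensitive"])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("response metrics reproduce the confusion arithmetic", {
  pred <- data.frame(
    sample_id = sprintf("P%02d", 1:30),
    rho = NA_real_,
    label = c(rep("insensitive", 10), rep("sensitive", 20)))
  clinical <- data.frame(
    pcr = c(rep("RD", 8), rep("pCR", 2), rep("pCR", 17), rep("RD", 3)),
    rcb = c(rep("III", 8), rep("0", 2), rep("I", 17), rep("II", 3)),
    time = rep(5, 30), event = rep(0L, 30))
  met <- response_metrics(pred, clinical, "pCR/RD")
  expect_equal(met$ppv, 80)
  expect_equal(met$npv, 85)
  expect_equal(met$tp + met$fp + met$tn + met$fn, met$n_evaluable)

  met_rcb <- response_metrics(pred, clinical, "RCB")
  expect_equal(met_rcb$ppv, 80)
  expect_equal(met_rcb$npv, 85)

  # perfect predictor
  clin_perfect <- data.frame(
    pcr = c(rep("RD", 10), rep("pCR", 20)),
    time = rep(5, 30), event = 0L)
  met_p <- response_metrics(pred, clin_perfect, "pCR/RD")
  expect_equal(c(met_p$ppv, met_p$npv, met_p$sensitivity, met_p$specificity),
               rep(100, 4))

  pred_all <- pred
  pred_all$label <- "sensitive"
  expect_error(response_metrics(pred_all, clinical, "pCR/RD"), "PPV")
  pred_none <- pred
  pred_none$label <- "insensitive"
  expect_error(response_metrics(pred_none, clinical, "pCR/RD"), "NPV")
})

test_that("DRFS3y metrics exclude and count indeterminate patients", {
  pred <- data.frame(sample_id = sprintf("P%d", 1:6), rho = NA_real_,
                     label = rep(c("insensitive", "sensitive"), 3))
  clinical <- data.frame(
    time = c(1.0, 2.0, 4.0, 5.0, 2.5, 1.5),
    event = c(1L, 0L, 0L, 1L, 1L, 0L))
  # patients 2 and 6 are censored before 3y: indeterminate
  met <- response_metrics(pred, clinical, "DRFS3y")
  expect_equal(met$n_indeterminate, 2)
  expect_equal(met$n_evaluable, 4)
  expect_equal(met$tp, 2)   # patients 1 and 5: insensitive, early event
  expect_equal(met$fp, 1)   # patient 3: insensitive but followed past 3y
  expect_equal(met$ppv, 100 * 2 / 3)
  expect_equal(met$npv, 100)  # patient 4: sensitive, survivor
})

test_that("KM by prediction is label-symmetric and needs both groups", {
  set.seed(78)
  pred <- data.frame(sample_id = sprintf("P%d", 1:40), rho = NA_real_,
                     label = rep(c("sensitive", "insensitive"), 20))
  times <- rexp(40) + 0.05
  events <- rbinom(40, 1, 0.7)
  km <- km_by_prediction(pred, times, events)
  expect_named(km$curves, c("sensitive", "insensitive"))

  pred_sw <- pred
  pred_sw$label <- ifelse(pred$label == "sensitive", "insensitive",
                          "sensitive")
  expect_equal(km_by_prediction(pred_sw, times, events)$logrank$p_value,
               km$logrank$p_value, tolerance = 1e-12)

  pred_one <- pred
  pred_one$label <- "sensitive"
  expect_error(km_by_prediction(pred_one, times, events), "non-empty")
})
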