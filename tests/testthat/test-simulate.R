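# Synthetic cohort generators: determinism, validity and the planted
# statistical structure.

test_that("configuration validation catches impossible settings", {
  expect_error(sim_config(n_genes = 10, program_size = 20), "program_size")
  expect_error(sim_config(mutation_rate = 1.5), "mutation_rate")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(censor_horizon = -1), "censor_horizon")
})

test_that("survival datasets are pure functions of (config, seed)", {
  cfg <- sim_config(n_genes = 100, n_samples = 30, program_size = 10,
                    n_decoy_modules = 2, seed = 5)
  a <- simulate_survival_dataset(cfg)
  b <- simulate_survival_dataset(cfg)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$dataset$clinical, b$dataset$clinical)
  expect_identical(a$truth$program_genes, b$truth$program_genes)

  cfg2 <- sim_config(n_genes = 100, n_samples = 30, program_size = 10,
                     n_decoy_modules = 2, seed = 6)
  c <- simulate_survival_dataset(cfg2)
  expect_false(identical(a$dataset$matrix, c$dataset$matrix))
})

test_that("survival dataset respects the generating model", {
  cfg <- sim_config(n_samples = 300, seed = 11)
  sim <- simulate_survival_dataset(cfg)
  ds <- sim$dataset
  expect_true(all(ds$clinical$time > 0))
  expect_true(all(ds$clinical$event %in% 0:1))
  expect_true(all(ds$clinical$time <= cfg$censor_horizon + 1e-12 |
                    ds$clinical$event == 1))
  expect_equal(unname(sim$truth$program_score),
               unname(colMeans(ds$matrix[sim$truth$program_genes, ])))
  # mutants carry the program: score separates by mutation status
  expect_gt(mean(sim$truth$program_score[sim$truth$mutant == 1]),
            mean(sim$truth$program_score[sim$truth$mutant == 0]) + 0.5)
})

test_that("under beta = 0 the program score carries no survival signal", {
  reject <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_genes = 200, n_samples = 200, program_size = 20,
                      beta = 0, n_decoy_modules = 2, seed = 9000 + r)
    sim <- simulate_survival_dataset(cfg)
    p <- suppressWarnings(
      cor.test(sim$truth$program_score, sim$dataset$clinical$time,
               method = "kendall")$p.value)
    if (p < 0.05) reject <- reject + 1
  }
  # expected rejection rate is the 5% test level
  expect_lte(reject, ceiling(0.1 * n_rep))
})

test_that("a Cox fit on the program score recovers the generating beta", {
  ok <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = 300, beta = 1, mutation_effect = 2,
                      seed = 4000 + r)
    sim <- simulate_survival_dataset(cfg)
    fit <- survival::coxph(
      survival::Surv(time, event) ~ score,
      data = data.frame(sim$dataset$clinical,
                        score = sim$truth$program_score))
    if (abs(unname(coef(fit)) - 1) <= 0.3) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.8 * n_rep))
})

test_that("cell-line panels plant the requested sensitivity structure", {
  cfg <- sim_config(seed = 21)
  panel <- simulate_cellline_panel(cfg, n_lines = 20, sens_fraction = 0.65)
  below <- apply(panel$log_ic50 < -1, 1, any)
  expect_equal(sum(below), 13)
  expect_identical(unname(panel$sensitive[below]), rep(1L, 13))

  expect_error(simulate_cellline_panel(cfg, n_lines = 1), "n_lines")
  expect_error(simulate_cellline_panel(cfg, sens_fraction = 0), "sens_fraction")
  expect_error(simulate_cellline_panel(cfg, sens_fraction = 1), "sens_fraction")
})

test_that("sensitive lines have higher mean program expression", {
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(mutation_effect = 2, seed = 5000 + r)
    panel <- simulate_cellline_panel(cfg, n_lines = 20, sens_fraction = 0.65)
    prog <- panel$expression[panel$program_genes, ]
    s <- colMeans(prog[, panel$sensitive == 1])
    rgrp <- colMeans(prog[, panel$sensitive == 0])
    if (t.test(s, rgrp, alternative = "greater")$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("neoadjuvant cohorts calibrate pCR rate and RCB consistency", {
  cfg <- sim_config(n_genes = 200, program_size = 20, n_samples = 100,
                    n_decoy_modules = 2, seed = 31)
  neo0 <- simulate_neoadjuvant_cohort(cfg, n_patients = 2000,
                                      pcr_intercept = -1, pcr_slope = 0)
  rate <- mean(neo0$dataset$clinical$pcr == "pCR")
  expect_lt(abs(rate - plogis(-1)), 0.03)

  neo <- simulate_neoadjuvant_cohort(cfg, n_patients = 400)
  clin <- neo$dataset$clinical
  expect_true(all(clin$rcb[clin$pcr == "pCR"] %in% c("0", "I")))
  expect_true(all(clin$rcb[clin$pcr == "RD"] %in% c("II", "III")))
  expect_equal(neo$dataset$endpoint, "DRFS")
  # defaults emulate the ~25-30% response rates of real cohorts
  rates <- vapply(1:10, function(r) {
    cfg_r <- sim_config(n_genes = 200, program_size = 20, seed = 600 + r)
    mean(simulate_neoadjuvant_cohort(cfg_r,
                                     n_patients = 300)$dataset$clinical$pcr == "pCR")
  }, numeric(1))
  expect_gt(mean(rates), 0.20)
  expect_lt(mean(rates), 0.35)

  expect_error(simulate_neoadjuvant_cohort(cfg, n_patients = 10), "at least 20")
})

test_that("signature collections honor overlap fraction and length", {
  cfg <- sim_config(n_genes = 300, program_size = 30, n_samples = 30,
                    n_decoy_modules = 2, seed = 41)
  truth <- simulate_survival_dataset(cfg)$truth

  full <- simulate_signature_collection(truth, n_overlapping = 1, n_random = 0,
                                        overlap_fraction = 1, length = 30,
                                        seed = 1)
  expect_setequal(full$OV01$genes, truth$program_genes)

  none <- simulate_signature_collection(truth, n_overlapping = 1, n_random = 0,
                                        overlap_fraction = 0, length = 30,
                                        seed = 1)
  expect_length(intersect(none$OV01$genes, truth$program_genes), 0)

  mix <- simulate_signature_collection(truth, n_overlapping = 3, n_random = 2,
                                       overlap_fraction = 0.5, length = 40,
                                       seed = 2)
  expect_length(mix, 5)
  for (s in mix) expect_length(s$genes, 40)
  expect_length(intersect(mix$OV01$genes, truth$program_genes), 20)

  expect_error(
    simulate_signature_collection(truth, length = 1000, seed = 1),
    "universe")
})

test_that("registry datasets share one planted program", {
  cfg <- sim_config(n_genes = 200, n_samples = 40, program_size = 20,
                    n_decoy_modules = 2, seed = 8)
  sim <- simulate_registry(cfg, n_datasets = 3, betas = c(1, 0, 1),
                           dead_fraction = c(0, 0, 0.2))
  expect_length(sim$registry, 3)
  expect_length(sim$truth$program_genes, 20)
  # dead-array columns are constant
  m3 <- sim$registry$DS03$matrix
  n_dead <- sum(apply(m3, 2, function(x) diff(range(x)) == 0))
  expect_equal(n_dead, round(0.2 * 40))
  # datasets differ but share gene universe
  expect_false(identical(sim$registry$DS01$matrix, sim$registry$DS02$matrix))
  expect_identical(sim$registry$DS01$gene_ids, sim$registry$DS02$gene_ids)
})
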