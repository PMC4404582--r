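# Signature and dataset readers/writers and signature-to-dataset mapping.

write_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT-style collections parse with sizes, order and directions", {
  path <- write_gmt(c("S1\tfirst\tTP53\tBRCA1\tMYC",
                      "S2\tsecond\tA1\tA2\tA3\tA4\tA5"))
  sigs <- read_signature_collection(path)
  expect_named(sigs, c("S1", "S2"))
  expect_length(sigs$S1$genes, 3)
  expect_length(sigs$S2$genes, 5)
  expect_equal(sigs$S1$description, "first")

  path2 <- write_gmt("S1\tdesc\tTP53|up\tBRCA1|down\tMYC")
  sig <- read_signature_collection(path2)$S1
  expect_equal(sig$genes, c("TP53", "BRCA1", "MYC"))
  expect_equal(sig$directions[["TP53"]], "up")
  expect_equal(sig$directions[["BRCA1"]], "down")
})

test_that("duplicate genes collapse with a warning; malformed files error", {
  path <- write_gmt("S1\tdesc\tKIF23\tPLK1\tKIF23")
  expect_warning(sigs <- read_signature_collection(path), "KIF23")
  expect_equal(sigs$S1$genes, c("KIF23", "PLK1"))

  empty <- write_gmt(character(0))
  expect_error(read_signature_collection(empty), "empty")

  nogene <- write_gmt(c("S1\tdesc\tTP53", "S2\tdesc"))
  expect_error(read_signature_collection(nogene), "line 2")

  dup <- write_gmt(c("S1\tdesc\tTP53", "S1\tdesc\tMYC"))
  expect_error(read_signature_collection(dup), "duplicate signature")
})

test_that("signature collections round-trip through write/read exactly", {
  sigs <- list(
    A = gene_signature("A", c("TP53", "BRCA1"), description = "one",
                       directions = c(TP53 = "up", BRCA1 = "down")),
    B = gene_signature("B", c("MYC", "KRAS", "EGFR"), description = "two")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_signature_collection(sigs, path)
  back <- read_signature_collection(path)
  expect_equal(names(back), names(sigs))
  for (id in names(sigs)) {
    expect_equal(back[[id]]$genes, sigs[[id]]$genes)
    expect_equal(back[[id]]$directions[back[[id]]$genes %in%
                                         names(sigs[[id]]$directions)],
                 sigs[[id]]$directions)
  }
})

make_tsv_pair <- function(n_genes = 100, n_samples = 20, extra_clin = 0,
                          env = parent.frame()) {
  set.seed(42)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples + extra_clin))
  m <- matrix(round(rnorm(n_genes * n_samples), 4), n_genes,
              dimnames = list(NULL, samples[seq_len(n_samples)]))
  expr_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  write.table(data.frame(gene = genes, m, check.names = FALSE), expr_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  clin_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  clin <- data.frame(sample_id = samples,
                     time = seq_along(samples) + 0.5,
                     event = rep_len(c(0L, 1L), length(samples)))
  write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, clinical = clin_path)
}

test_that("expression datasets read with inner join on samples", {
  p <- make_tsv_pair()
  ds <- read_expression_dataset(p$expr, p$clinical, endpoint = "RFS", id = "T1")
  expect_s3_class(ds, "expression_dataset")
  expect_equal(ncol(ds$matrix), 20)
  expect_equal(nrow(ds$matrix), 100)

  # clinical has 25 samples, expression 20: restricted to the shared 20
  p2 <- make_tsv_pair(extra_clin = 5)
  ds2 <- read_expression_dataset(p2$expr, p2$clinical, id = "T2")
  expect_equal(ds2$sample_ids, sprintf("S%02d", 1:20))
})

test_that("duplicate gene rows collapse by per-gene maximum", {
  expr_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2\tS3\tS4\tS5\tS6\tS7\tS8\tS9\tS10",
               paste(c("AURKA", 5, 1, 1, 1, 1, 1, 1, 1, 1, 1), collapse = "\t"),
               paste(c("AURKA", 7, 0, 0, 0, 0, 0, 0, 0, 0, 0), collapse = "\t"),
               paste(c("TP53", rep(2, 10)), collapse = "\t")), expr_path)
  clin_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = paste0("S", 1:10), time = 1:10,
                         event = 1L),
              clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_expression_dataset(expr_path, clin_path, id = "DUP")
  expect_equal(nrow(ds$matrix), 2)
  expect_equal(ds$matrix["AURKA", "S1"], 7)   # max of 5 and 7
  expect_equal(ds$matrix["AURKA", "S2"], 1)
  expect_equal(ds$gene_ids, c("AURKA", "TP53"))
})

test_that("reader rejects disjoint samples, bad values and bad times", {
  p <- make_tsv_pair()
  clin_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = paste0("X", 1:5), time = 1:5, event = 1L),
              clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_dataset(p$expr, clin_path), "overlap")

  bad_expr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "TP53\t1.5\toops", "MYC\t1\t2"), bad_expr)
  clin2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("S1", "S2"), time = c(1, 2), event = 1L),
              clin2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_dataset(bad_expr, clin2), "S2")

  clin3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = sprintf("S%02d", 1:20),
                         time = c(-1, 2:20), event = 1L),
              clin3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_dataset(p$expr, clin3), "positive")
})

test_that("survival times convert to years by the declared unit", {
  p <- make_tsv_pair()
  ds_m <- read_expression_dataset(p$expr, p$clinical, time_unit = "months")
  ds_y <- read_expression_dataset(p$expr, p$clinical, time_unit = "years")
  expect_equal(ds_m$clinical$time, ds_y$clinical$time / 12)
})

test_that("registry round-trips through the YAML manifest", {
  cfg <- sim_config(n_genes = 50, n_samples = 15, program_size = 10,
                    n_decoy_modules = 1, seed = 3)
  sim <- simulate_registry(cfg, n_datasets = 2)
  dir <- withr::local_tempdir()
  manifest <- write_registry(sim$registry, dir)
  back <- read_registry(manifest)
  expect_equal(names(back), names(sim$registry))
  expect_equal(back$DS01$gene_ids, sim$registry$DS01$gene_ids)
  expect_equal(back$DS02$clinical$event, sim$registry$DS02$clinical$event)
  expect_equal(back$DS01$matrix, sim$registry$DS01$matrix, tolerance = 1e-9)
})

test_that("signature mapping is case-insensitive, bounded and order-invariant", {
  ds <- make_two_block_dataset()$ds
  sig_all <- gene_signature("ALL", tolower(ds$gene_ids))
  m_all <- map_signature_to_dataset(sig_all, ds)
  expect_equal(m_all$coverage, 1.0)
  expect_setequal(m_all$mapped_genes, ds$gene_ids)

  sig_half <- gene_signature("HALF", c(ds$gene_ids[1:5],
                                       paste0("FAKE", 1:5)))
  expect_equal(map_signature_to_dataset(sig_half, ds)$coverage, 0.5)

  sig_none <- gene_signature("NONE", paste0("FAKE", 1:4))
  m_none <- map_signature_to_dataset(sig_none, ds)
  expect_equal(m_none$coverage, 0.0)
  expect_length(m_none$mapped_genes, 0)

  # gene order in the signature must not matter
  sig_rev <- gene_signature("ALL", rev(tolower(ds$gene_ids)))
  expect_setequal(map_signature_to_dataset(sig_rev, ds)$mapped_genes,
                  m_all$mapped_genes)
})
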