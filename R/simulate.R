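# Synthetic cohorts with a planted prognostic gene program.
#
# The generator emulates the statistical structure the screen assumes: a
# latent "hazard program" gene set whose summarized expression acts
# multiplicatively on hazard, a binary TP53-like mutation covariate shifting
# program-gene expression, independent noise genes, administrative
# censoring, chemosensitive cell lines whose log(IC50) tracks program
# expression, and neoadjuvant cohorts where pCR probability and DRFS depend
# on the program.

#' Simulation configuration
#'
#' @param n_genes number of genes in the universe.
#' @param n_samples number of patients.
#' @param program_size number of planted hazard-program genes.
#' @param beta log-hazard per unit of program score (mean program-gene
#'   expression); beta = 1 roughly reproduces the hazard ratios near 2-3
#'   seen for strong prognostic signatures.
#' @param mutation_rate prevalence of the TP53-like binary mutation
#'   (default 0.3, the TP53 mutation frequency typical of breast tumors).
#' @param mutation_effect magnitude of the additive expression shift of
#'   program genes in mutant samples (log-scale units); each program gene
#'   carries a sign (up- or down-regulated in mutants, see
#'   \code{program_up_fraction}), mirroring the mixed-direction composition
#'   of TP53-associated signatures.
#' @param program_up_fraction fraction of program genes up-regulated in
#'   mutants (default 0.75; the rest are down-regulated). A purely uniform
#'   shift would leave within-profile gene ranks — and hence the Spearman
#'   sample-sample correlation the stratification uses — unchanged, so some
#'   direction heterogeneity is essential to the planted structure.
#' @param n_decoy_modules number of decoy co-expression modules (default
#'   10): gene blocks of \code{program_size}, disjoint from the hazard
#'   program, driven by independent binary latent factors with the same
#'   effect magnitude but no link to survival or mutation. They emulate the
#'   outcome-unrelated co-expression structure (subtype, proliferation,
#'   stroma) of real tumors; without them, a couple of program genes would
#'   be the only structure in an otherwise iid matrix and any signature
#'   touching them would cluster on the mutation split.
#' @param baseline_hazard exponential baseline event rate per year
#'   (default 0.15, giving a 10-year observed event fraction around 40-45%
#'   under the default censoring — typical of relapse-endpoint breast
#'   cancer cohorts with decade-long follow-up).
#' @param censor_horizon administrative censoring window in years; censoring
#'   times are Uniform(0, censor_horizon). Default 10, a typical follow-up
#'   length for the survival cohorts this emulates.
#' @param noise_sd per-gene expression standard deviation.
#' @param seed integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000, n_samples = 200, program_size = 50,
                       beta = 1, mutation_rate = 0.3, mutation_effect = 2,
                       program_up_fraction = 0.75, n_decoy_modules = 10,
                       baseline_hazard = 0.15, censor_horizon = 10,
                       noise_sd = 1, seed = 1L) {
  stopifnot_scalar_number(beta, "beta")
  if (program_size > n_genes) {
    stop("program_size must not exceed n_genes", call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (program_up_fraction < 0 || program_up_fraction > 1) {
    stop("program_up_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  if (censor_horizon <= 0) stop("censor_horizon must be positive", call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         program_size = as.integer(program_size), beta = beta,
         mutation_rate = mutation_rate, mutation_effect = mutation_effect,
         program_up_fraction = program_up_fraction,
         n_decoy_modules = as.integer(n_decoy_modules),
         baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# Core expression sampler shared by all generators: mutation status, the
# expression matrix (program genes shifted in mutants) and the program score.
.program_signs <- function(k, up_fraction) {
  n_up <- round(up_fraction * k)
  c(rep(1, n_up), rep(-1, k - n_up))
}

.simulate_expression <- function(cfg, n_samples, sample_prefix = "S",
                                 program_genes = NULL, program_signs = NULL) {
  gene_ids <- .gene_ids(cfg$n_genes)
  if (is.null(program_genes)) {
    program <- sort(sample.int(cfg$n_genes, cfg$program_size))
  } else {
    program <- match(program_genes, gene_ids)
    if (anyNA(program)) stop("program_genes outside the gene universe",
                             call. = FALSE)
  }
  if (is.null(program_signs)) {
    program_signs <- .program_signs(length(program), cfg$program_up_fraction)
  }
  mutant <- stats::rbinom(n_samples, 1L, cfg$mutation_rate)
  m <- matrix(stats::rnorm(cfg$n_genes * n_samples, sd = cfg$noise_sd),
              nrow = cfg$n_genes, ncol = n_samples,
              dimnames = list(gene_ids,
                              sprintf("%s%04d", sample_prefix, seq_len(n_samples))))
  # Signed bimodal program, centered on the cohort mean: wild-type samples
  # sit at -effect/2 * sign, mutants at +effect/2 * sign, so the mutant -
  # wild-type difference is exactly mutation_effect per gene and both
  # groups form coherent (anti-correlated) expression patterns — as in
  # real cohorts, where both TP53 states deviate from the cohort average.
  m[program, ] <- m[program, ] +
    cfg$mutation_effect * outer(program_signs, mutant - 0.5)
  # decoy co-expression modules: disjoint gene blocks driven by independent
  # binary latent factors, unrelated to mutation or survival
  if (cfg$n_decoy_modules > 0L) {
    pool <- sample(setdiff(seq_len(cfg$n_genes), program))
    n_blocks <- min(cfg$n_decoy_modules,
                    length(pool) %/% max(1L, cfg$program_size))
    for (b in seq_len(n_blocks)) {
      dg <- pool[((b - 1L) * cfg$program_size + 1L):(b * cfg$program_size)]
      z <- stats::rbinom(n_samples, 1L, 0.5)
      m[dg, ] <- m[dg, ] +
        cfg$mutation_effect *
        outer(.program_signs(length(dg), cfg$program_up_fraction), z - 0.5)
    }
  }
  score <- colMeans(m[program, , drop = FALSE])
  list(matrix = m, gene_ids = gene_ids, program_genes = gene_ids[program],
       program_signs = stats::setNames(program_signs, gene_ids[program]),
       mutant = mutant, score = score)
}

#' Simulate a survival-annotated expression dataset
#'
#' Mutation status is Bernoulli(\code{mutation_rate}); program-gene
#' expression is Normal noise shifted by \code{mutation_effect} in mutants;
#' the per-sample program score is the mean expression over program genes;
#' event times are Exponential with rate
#' \code{baseline_hazard * exp(beta * score)}; censoring is
#' Uniform(0, \code{censor_horizon}); the observed time is the minimum and
#' the event indicator marks uncensored failures.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param id dataset id.
#' @param endpoint endpoint label attached to the dataset.
#' @param program_genes optional fixed program gene ids (must be members of
#'   the gene universe); by default a fresh program is drawn from the seed.
#' @return A list with \code{dataset} (an \code{expression_dataset}) and
#'   \code{truth} (program genes, per-sample score, mutation status, the
#'   generating beta and the gene universe).
#' @export
simulate_survival_dataset <- function(cfg, id = "SIM1", endpoint = "RFS",
                                      program_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sim <- .simulate_expression(cfg, cfg$n_samples,
                                program_genes = program_genes)
    rate <- cfg$baseline_hazard * exp(cfg$beta * sim$score)
    t_event <- stats::rexp(cfg$n_samples, rate = rate)
    t_cens <- stats::runif(cfg$n_samples, 0, cfg$censor_horizon)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(
      sample_id = colnames(sim$matrix),
      time = time, event = event,
      tp53_mutant = sim$mutant,
      row.names = colnames(sim$matrix),
      stringsAsFactors = FALSE
    )
    ds <- expression_dataset(id, sim$matrix, clinical, endpoint = endpoint)
    truth <- structure(
      list(program_genes = sim$program_genes,
           program_signs = sim$program_signs, program_score = sim$score,
           mutant = sim$mutant, beta = cfg$beta, gene_universe = sim$gene_ids),
      class = "synthetic_truth"
    )
    list(dataset = ds, truth = truth)
  })
}

#' Simulate a cell-line panel with drug sensitivity
#'
#' A fraction \code{sens_fraction} of lines are drug-sensitive:
#' log(IC50) ~ Uniform(-3, -1.01) for at least one of the named drugs, and
#' mutant-like program-gene expression (the same signed
#' \code{mutation_effect} shift used for mutant tumors, so the program mean
#' is elevated). Resistant lines draw log(IC50) from Uniform(-0.99, 2) for
#' every drug. All lines are HER2-negative.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_lines number of cell lines (>= 2).
#' @param sens_fraction fraction of sensitive lines, strictly in (0, 1).
#' @param drugs drug names.
#' @param program_genes optional fixed program gene ids.
#' @return A list of class \code{cellline_panel} with \code{expression}
#'   (gene x line matrix), \code{log_ic50} (line x drug matrix),
#'   \code{her2_status}, \code{sensitive} (the generating truth) and
#'   \code{program_genes}.
#' @export
simulate_cellline_panel <- function(cfg, n_lines = 20, sens_fraction = 0.65,
                                    drugs = c("taxane", "anthracycline"),
                                    program_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_lines < 2) stop("n_lines must be at least 2", call. = FALSE)
  if (sens_fraction <= 0 || sens_fraction >= 1) {
    stop("sens_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    gene_ids <- .gene_ids(cfg$n_genes)
    if (is.null(program_genes)) {
      program <- sort(sample.int(cfg$n_genes, cfg$program_size))
    } else {
      program <- match(program_genes, gene_ids)
      if (anyNA(program)) stop("program_genes outside the gene universe",
                               call. = FALSE)
    }
    n_sens <- round(sens_fraction * n_lines)
    sensitive <- c(rep(1L, n_sens), rep(0L, n_lines - n_sens))
    line_ids <- sprintf("CL%03d", seq_len(n_lines))
    m <- matrix(stats::rnorm(cfg$n_genes * n_lines, sd = cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(gene_ids, line_ids))
    signs <- .program_signs(length(program), cfg$program_up_fraction)
    m[program, ] <- m[program, ] +
      cfg$mutation_effect * outer(signs, sensitive - 0.5)
    ic50 <- matrix(stats::runif(n_lines * length(drugs), -0.99, 2),
                   nrow = n_lines, dimnames = list(line_ids, drugs))
    for (i in which(sensitive == 1L)) {
      # sensitive to one drug or both ("and/or")
      which_drugs <- sample(c("first", "second", "both"), 1L)
      cols <- switch(which_drugs, first = 1L, second = min(2L, length(drugs)),
                     both = seq_along(drugs))
      ic50[i, cols] <- stats::runif(length(cols), -3, -1.01)
    }
    structure(
      list(expression = m, log_ic50 = ic50,
           her2_status = stats::setNames(rep("neg", n_lines), line_ids),
           sensitive = stats::setNames(sensitive, line_ids),
           program_genes = gene_ids[program],
           program_signs = stats::setNames(signs, gene_ids[program])),
      class = "cellline_panel"
    )
  })
}

#' Simulate a neoadjuvant chemotherapy cohort
#'
#' pCR probability follows
#' \code{plogis(pcr_intercept + pcr_slope * program_score)}; pCR-like
#' responders receive RCB class 0 or I, the rest II or III. Distant
#' relapse-free survival is Exponential with hazard multiplier
#' \code{exp(beta * score)} and a protective multiplier for pCR patients
#' (default 0.5, chosen so the 5-year DRFS gap between predicted response
#' groups is around 20 percentage points, the size reported for real
#' taxane-anthracycline cohorts); endpoint is DRFS.
#'
#' The default intercept/slope (-0.8, 2.5) give a cohort pCR rate of about
#' 26% — matching the 25-30% response rates typical of taxane-anthracycline
#' neoadjuvant cohorts — with responders concentrated among high-program
#' (mutant-like) tumors.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_patients cohort size (>= 20).
#' @param pcr_intercept,pcr_slope logistic model for pCR probability on the
#'   program score.
#' @param pcr_hazard_multiplier hazard multiplier applied to pCR patients.
#' @param id dataset id.
#' @param program_genes optional fixed program gene ids.
#' @return A list with \code{dataset} (endpoint DRFS; clinical covariates
#'   include \code{pcr} in \{pCR, RD\}, \code{rcb} and \code{her2}) and
#'   \code{truth}.
#' @export
simulate_neoadjuvant_cohort <- function(cfg, n_patients = 250,
                                        pcr_intercept = -0.8, pcr_slope = 2.5,
                                        pcr_hazard_multiplier = 0.5,
                                        id = "NEO1", program_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_patients < 20) stop("n_patients must be at least 20", call. = FALSE)
  with_seed(cfg$seed + 2L, {
    sim <- .simulate_expression(cfg, n_patients, sample_prefix = "P",
                                program_genes = program_genes)
    p_pcr <- stats::plogis(pcr_intercept + pcr_slope * sim$score)
    pcr <- stats::rbinom(n_patients, 1L, p_pcr)
    rcb <- ifelse(pcr == 1L,
                  sample(c("0", "I"), n_patients, replace = TRUE),
                  sample(c("II", "III"), n_patients, replace = TRUE))
    rate <- cfg$baseline_hazard * exp(cfg$beta * sim$score) *
      ifelse(pcr == 1L, pcr_hazard_multiplier, 1)
    t_event <- stats::rexp(n_patients, rate = rate)
    t_cens <- stats::runif(n_patients, 0, cfg$censor_horizon)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(
      sample_id = colnames(sim$matrix),
      time = time, event = event,
      pcr = ifelse(pcr == 1L, "pCR", "RD"), rcb = rcb,
      her2 = "neg", tp53_mutant = sim$mutant,
      row.names = colnames(sim$matrix),
      stringsAsFactors = FALSE
    )
    ds <- expression_dataset(id, sim$matrix, clinical, endpoint = "DRFS")
    truth <- structure(
      list(program_genes = sim$program_genes,
           program_signs = sim$program_signs, program_score = sim$score,
           mutant = sim$mutant, beta = cfg$beta, gene_universe = sim$gene_ids),
      class = "synthetic_truth"
    )
    list(dataset = ds, truth = truth)
  })
}

#' Simulate a signature collection around a planted program
#'
#' Builds \code{n_overlapping} signatures that each draw
#' \code{round(overlap_fraction * length)} genes from the planted program
#' (direction "up": program genes rise with hazard) and the rest from noise
#' genes, plus \code{n_random} signatures drawn uniformly from the gene
#' universe. All signatures have \code{length} genes.
#'
#' @param truth a \code{synthetic_truth}.
#' @param n_overlapping,n_random signature counts.
#' @param overlap_fraction fraction of each overlapping signature drawn from
#'   program genes.
#' @param length signature length.
#' @param seed integer seed.
#' @return A named list of \code{gene_signature} objects (overlapping
#'   signatures prefixed \code{OV}, random ones \code{RND}).
#' @export
simulate_signature_collection <- function(truth, n_overlapping = 5,
                                          n_random = 5, overlap_fraction = 1,
                                          length = 50, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  universe <- truth$gene_universe
  if (length > base::length(universe)) {
    stop("signature length exceeds the gene universe", call. = FALSE)
  }
  noise_pool <- setdiff(universe, truth$program_genes)
  n_prog <- round(overlap_fraction * length)
  n_prog <- min(n_prog, base::length(truth$program_genes))
  with_seed(seed, {
    sigs <- list()
    for (i in seq_len(n_overlapping)) {
      prog_part <- sample(truth$program_genes, n_prog)
      noise_part <- if (length - n_prog > 0) {
        sample(noise_pool, length - n_prog)
      } else character(0)
      genes <- c(prog_part, noise_part)
      prog_dirs <- if (!is.null(truth$program_signs)) {
        ifelse(truth$program_signs[prog_part] > 0, "up", "down")
      } else rep("up", n_prog)
      dirs <- stats::setNames(
        c(prog_dirs, rep("unknown", length - n_prog)), genes)
      sigs[[sprintf("OV%02d", i)]] <- gene_signature(
        sprintf("OV%02d", i), genes,
        description = sprintf("planted-overlap signature (%.0f%% program)",
                              100 * overlap_fraction),
        directions = dirs, phenotype_tag = "hazard program")
    }
    for (i in seq_len(n_random)) {
      sigs[[sprintf("RND%02d", i)]] <- gene_signature(
        sprintf("RND%02d", i), sample(universe, length),
        description = "random signature")
    }
    sigs
  })
}

#' Simulate a registry of survival datasets sharing one planted program
#'
#' The planted program gene set is drawn once from the master seed, then
#' per-dataset sub-seeds (\code{seed + index}) stream independent yet
#' reproducible cohorts that all carry the same program — the situation a
#' multi-dataset signature screen assumes.
#'
#' @param cfg base \code{\link{sim_config}} (its \code{seed} is the master
#'   seed).
#' @param n_datasets number of datasets.
#' @param betas per-dataset log-hazard effects (recycled); use 0 for null
#'   datasets with no prognostic structure.
#' @param dead_fraction per-dataset fraction of samples whose expression
#'   profile is made constant ("dead arrays", recycled). Non-zero values
#'   force stratification failures (N/A) for every signature.
#' @return A list with \code{registry} (a \code{dataset_registry}) and
#'   \code{truth} (the shared \code{synthetic_truth} of the first dataset;
#'   its program genes are common to all).
#' @export
simulate_registry <- function(cfg, n_datasets = 10, betas = cfg$beta,
                              dead_fraction = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  betas <- rep_len(betas, n_datasets)
  dead_fraction <- rep_len(dead_fraction, n_datasets)
  program <- with_seed(cfg$seed,
                       .gene_ids(cfg$n_genes)[sort(sample.int(cfg$n_genes,
                                                              cfg$program_size))])
  out <- vector("list", n_datasets)
  truth <- NULL
  for (i in seq_len(n_datasets)) {
    cfg_i <- cfg
    cfg_i$beta <- betas[i]
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_survival_dataset(cfg_i, id = sprintf("DS%02d", i),
                                     program_genes = program)
    if (dead_fraction[i] > 0) {
      n_dead <- max(1L, round(dead_fraction[i] * cfg$n_samples))
      sim$dataset$matrix[, seq_len(n_dead)] <- 0
    }
    out[[i]] <- sim$dataset
    if (is.null(truth)) truth <- sim$truth
  }
  list(registry = dataset_registry(out), truth = truth)
}
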