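# Shared fixtures, built in code at test time.

# A dataset of two sample blocks with distinct shared profiles (plus tiny
# jitter so profiles are non-constant but block structure is unambiguous).
make_two_block_dataset <- function(n_per_block = 10, n_genes = 30,
                                   shift = 4, seed = 1, jitter = 1e-6,
                                   times = NULL, events = NULL) {
  set.seed(seed)
  profile_a <- rnorm(n_genes)
  profile_b <- profile_a + shift * rep(c(1, -1), length.out = n_genes)
  n <- 2 * n_per_block
  m <- cbind(matrix(profile_a, n_genes, n_per_block),
             matrix(profile_b, n_genes, n_per_block))
  m <- m + matrix(rnorm(length(m), sd = jitter), nrow(m))
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  if (is.null(times)) times <- seq_len(n)
  if (is.null(events)) events <- rep(1L, n)
  clin <- data.frame(sample_id = colnames(m), time = times, event = events,
                     stringsAsFactors = FALSE)
  list(ds = expression_dataset("BLOCKS", m, clin),
       block = rep(c("A", "B"), each = n_per_block))
}

# Signature covering all genes of a dataset.
full_signature <- function(ds, id = "FULL", directions = NULL) {
  gene_signature(id, ds$gene_ids, directions = directions)
}

# A hand-built screen_matrix-shaped object for bookkeeping tests.
fake_screen_matrix <- function(cells, signature_ids = unique(cells$signature_id),
                               dataset_ids = unique(cells$dataset_id),
                               alpha = 0.05) {
  structure(cells, signature_ids = signature_ids, dataset_ids = dataset_ids,
            alpha = alpha, class = c("screen_matrix", "data.frame"))
}

fake_cells <- function(signature_id, dataset_id, p, status = NULL) {
  n <- max(length(signature_id), length(dataset_id), length(p))
  if (is.null(status)) status <- ifelse(is.na(p), "NA", "ok")
  data.frame(signature_id = rep_len(signature_id, n),
             dataset_id = rep_len(dataset_id, n),
             status = rep_len(status, n),
             na_reason = rep_len(ifelse(status == "ok", NA_character_,
                                        "low_coverage"), n),
             logrank_p = rep_len(p, n), hr = rep(NA_real_, n),
             ci_low = rep(NA_real_, n), ci_high = rep(NA_real_, n),
             c_index = rep(NA_real_, n), stringsAsFactors = FALSE)
}

fake_null <- function(dataset_id, p_values, length = 50, seed = 1) {
  structure(list(dataset_id = dataset_id, length = as.integer(length),
                 p_values = p_values, n_perm = base::length(p_values),
                 seed = as.integer(seed)),
            class = "random_signature_null")
}

# Planted-program signature with true directions.
program_signature <- function(truth, id = "PLANT") {
  gene_signature(id, truth$program_genes,
                 directions = ifelse(truth$program_signs > 0, "up", "down"))
}

# --- independent oracles ------------------------------------------------

# Two-sample log-rank statistic from first principles: per event time,
# observed vs hypergeometric-expected events in group 1.
oracle_logrank_chisq <- function(times, events, groups) {
  groups <- as.integer(factor(groups))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == 1L)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Product-limit estimator by direct multiplication.
oracle_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t <= at) {
      n <- sum(times >= t)
      d <- sum(times == t & events == 1)
      s <- s * (1 - d / n)
    }
  }
  s
}

# Harrell's c by exhaustive double loop under the stated pair rule.
oracle_concordance <- function(risk, times, events) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Two-sided Fisher exact P for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (fixed margins) no more probable than
# the observed one.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Cox partial log-likelihood for a binary covariate with untied event
# times, maximized by brute force.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    at_risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}
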