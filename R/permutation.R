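# Length-matched random-signature nulls, permutation-adjusted P values,
# N/A-rate and differential-index dataset QC, and adjusted-median-P ranking.

#' Draw a random signature from a dataset's gene universe
#'
#' Uniform sample without replacement; deterministic per
#' (seed, length, universe). Random signatures are drawn per dataset from
#' that dataset's own gene universe, so their coverage is always 1.
#'
#' @param universe character vector of gene ids.
#' @param length signature length.
#' @param seed integer seed.
#' @param id signature id.
#' @return A \code{gene_signature}.
#' @export
generate_random_signature <- function(universe, length, seed, id = NULL) {
  if (length > base::length(universe)) {
    stop("signature length exceeds the gene universe", call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("RANDL%d_S%d", length, seed)
  genes <- with_seed(seed, sample(universe, length))
  gene_signature(id, genes, description = "random signature")
}

# package-level cache so equal-length queries on the same dataset share the
# identical null vector
.null_cache <- new.env(parent = emptyenv())

#' Build (or fetch) a random-signature null for one dataset and length
#'
#' Generates \code{n_perm} length-matched random signatures from the
#' dataset's gene universe, stratifies each and records its log-rank P.
#' Stratification failures are recorded as NA entries (they count as
#' non-significant and non-smaller everywhere downstream). Results are
#' cached per (dataset id, length, seed, n_perm) so every same-length query
#' reuses the identical vector.
#'
#' @param ds an \code{expression_dataset}.
#' @param length signature length to match.
#' @param n_perm number of random signatures (default 1000).
#' @param seed integer seed.
#' @param use_cache set FALSE to force recomputation.
#' @return A \code{random_signature_null}: list with \code{dataset_id},
#'   \code{length}, \code{p_values} (length \code{n_perm}, NA = failure),
#'   \code{n_perm}, \code{seed}.
#' @export
build_null <- function(ds, length, n_perm = 1000, seed = 1L,
                       use_cache = TRUE) {
  # cheap content fingerprint so equal ids from different simulations
  # cannot collide in the cache
  fp <- sprintf("%dx%d:%.10g", nrow(ds$matrix), ncol(ds$matrix),
                sum(ds$matrix[, 1L]) + sum(ds$clinical$time))
  key <- paste(ds$id, fp, length, seed, n_perm, sep = "|")
  if (use_cache && !is.null(.null_cache[[key]])) return(.null_cache[[key]])
  p <- rep(NA_real_, n_perm)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  for (k in seq_len(n_perm)) {
    sig <- generate_random_signature(ds$gene_ids, length, seed = sub_seeds[k])
    cell <- screen_cell(sig, ds, statistics = "logrank")
    if (cell$status == "ok") p[k] <- cell$logrank_p
  }
  out <- structure(
    list(dataset_id = ds$id, length = as.integer(length), p_values = p,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "random_signature_null"
  )
  if (use_cache) .null_cache[[key]] <- out
  out
}

#' Clear the null cache
#' @return NULL, invisibly.
#' @export
clear_null_cache <- function() {
  rm(list = ls(.null_cache), envir = .null_cache)
  invisible(NULL)
}

#' Permutation-adjusted P value
#'
#' The fraction of random signatures achieving a strictly smaller log-rank P
#' than the observed one, with the raw count divided by \code{n_perm} (no
#' add-one smoothing; set \code{smooth = TRUE} for the (count + 1)/(n + 1)
#' variant). Null failures count as non-smaller.
#'
#' @param observed_p observed log-rank P in [0, 1].
#' @param null a \code{random_signature_null}.
#' @param smooth use add-one smoothing.
#' @return Adjusted P in [0, 1].
#' @export
adjusted_p <- function(observed_p, null, smooth = FALSE) {
  stopifnot(inherits(null, "random_signature_null"))
  if (null$n_perm == 0L) stop("empty null", call. = FALSE)
  if (!is.finite(observed_p) || observed_p < 0 || observed_p > 1) {
    stop("observed_p must lie in [0, 1]", call. = FALSE)
  }
  cnt <- sum(null$p_values < observed_p, na.rm = TRUE)
  if (smooth) (cnt + 1) / (null$n_perm + 1) else cnt / null$n_perm
}

#' N/A rate of a dataset across tested signatures
#'
#' @param matrix a \code{screen_matrix}.
#' @param dataset_id dataset to summarize.
#' @return Fraction of signatures whose cell is NA for that dataset.
#' @export
na_rate <- function(matrix, dataset_id) {
  rows <- matrix[matrix$dataset_id == dataset_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("dataset '%s' not in matrix", dataset_id),
                             call. = FALSE)
  sum(rows$status != "ok") / nrow(rows)
}

#' Differential index of a dataset
#'
#' Mean percent-significant of candidate signatures minus mean
#' percent-significant of random signatures, in percentage points. On a
#' single dataset each signature contributes 0 or 100 (significant or not),
#' so the means are the respective percent-significant fractions.
#'
#' @param candidate_rates per-candidate-signature percent-significant values
#'   on this dataset (0/100 indicators or percentages).
#' @param random_rates per-random-signature values, same convention.
#' @return Differential index in percentage points.
#' @export
differential_index <- function(candidate_rates, random_rates) {
  if (length(candidate_rates) == 0L || length(random_rates) == 0L) {
    stop("empty rate vector", call. = FALSE)
  }
  mean(candidate_rates) - mean(random_rates)
}

#' Per-dataset QC against a random-signature null
#'
#' @param matrix a \code{screen_matrix} of candidate signatures.
#' @param nulls named list of \code{random_signature_null} objects, one per
#'   dataset id (a list of several per dataset — one per candidate length —
#'   is also accepted; their P vectors are pooled).
#' @param alpha significance threshold (default: the matrix's).
#' @return A data.frame with one row per dataset: \code{dataset_id},
#'   \code{na_rate}, \code{mean_rate_candidates}, \code{mean_rate_random},
#'   \code{differential_index}.
#' @export
dataset_qc <- function(matrix, nulls, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(matrix, "alpha")
  dss <- .matrix_datasets(matrix)
  rows <- lapply(dss, function(d) {
    cells <- matrix[matrix$dataset_id == d, , drop = FALSE]
    nr <- sum(cells$status != "ok") / nrow(cells)
    cand <- 100 * (cells$status == "ok" & !is.na(cells$logrank_p) &
                     cells$logrank_p < alpha)
    nl <- nulls[[d]]
    if (is.null(nl)) stop(sprintf("missing null for dataset '%s'", d),
                          call. = FALSE)
    null_p <- if (inherits(nl, "random_signature_null")) nl$p_values else
      unlist(lapply(nl, `[[`, "p_values"))
    rand <- 100 * (!is.na(null_p) & null_p < alpha)
    data.frame(dataset_id = d, na_rate = nr,
               mean_rate_candidates = mean(cand),
               mean_rate_random = mean(rand),
               differential_index = differential_index(cand, rand),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validate datasets by N/A rate and differential index
#'
#' A dataset is rejected when its N/A rate is strictly above \code{na_cut}
#' (checked first), otherwise when its differential index is strictly below
#' \code{di_cut} (a DI exactly at the cut passes). Remaining datasets are
#' validated.
#'
#' @param matrix a \code{screen_matrix} of candidate signatures.
#' @param nulls as in \code{\link{dataset_qc}}.
#' @param na_cut N/A-rate threshold (default 0.05).
#' @param di_cut differential-index threshold in percentage points
#'   (default 9).
#' @param alpha significance threshold (default: the matrix's).
#' @return The \code{\link{dataset_qc}} table plus a \code{verdict} column
#'   in \{pass, fail_na, fail_di\}.
#' @export
validate_datasets <- function(matrix, nulls, na_cut = 0.05, di_cut = 9,
                              alpha = NULL) {
  qc <- dataset_qc(matrix, nulls, alpha = alpha)
  qc$verdict <- ifelse(qc$na_rate > na_cut, "fail_na",
                       ifelse(qc$differential_index < di_cut, "fail_di",
                              "pass"))
  qc
}

#' Adjusted P values for every candidate cell
#'
#' @param matrix a \code{screen_matrix} of candidate signatures.
#' @param registry the \code{dataset_registry} screened.
#' @param signatures the candidate signatures (for their lengths).
#' @param n_perm,seed null parameters (nulls are built/cached per dataset
#'   and length).
#' @return A data.frame with \code{signature_id}, \code{dataset_id},
#'   \code{observed_p}, \code{adjusted_p} (NA cells keep adjusted_p = NA).
#' @export
adjusted_p_matrix <- function(matrix, registry, signatures, n_perm = 1000,
                              seed = 1L) {
  rows <- lapply(seq_len(nrow(matrix)), function(i) {
    cell <- matrix[i, ]
    adj <- NA_real_
    if (cell$status == "ok") {
      sig <- signatures[[cell$signature_id]]
      nl <- build_null(registry[[cell$dataset_id]], length(sig$genes),
                       n_perm = n_perm, seed = seed)
      adj <- adjusted_p(cell$logrank_p, nl)
    }
    data.frame(signature_id = cell$signature_id,
               dataset_id = cell$dataset_id,
               observed_p = cell$logrank_p, adjusted_p = adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank signatures by adjusted median P over validated datasets
#'
#' Per signature: the median adjusted P over the validated datasets and the
#' percentage of validated datasets with adjusted P < alpha (failed cells
#' count as non-significant with adjusted P treated as 1 in the median).
#' Signatures are sorted ascending by median; the top set has median < alpha.
#'
#' @param adjusted table from \code{\link{adjusted_p_matrix}}.
#' @param validated_ids dataset ids that passed \code{validate_datasets}.
#' @param alpha significance threshold (default 0.05).
#' @return A data.frame with \code{signature_id}, \code{adjusted_median_p},
#'   \code{adjusted_significant_rate} (percent), \code{top}, sorted by rank.
#' @export
rank_by_adjusted_median_p <- function(adjusted, validated_ids, alpha = 0.05) {
  if (length(validated_ids) == 0L) stop("no validated datasets", call. = FALSE)
  sub <- adjusted[adjusted$dataset_id %in% validated_ids, , drop = FALSE]
  sigs <- unique(sub$signature_id)
  med <- vapply(sigs, function(s) {
    p <- sub$adjusted_p[sub$signature_id == s]
    p[is.na(p)] <- 1
    stats::median(p)
  }, numeric(1))
  rate <- vapply(sigs, function(s) {
    p <- sub$adjusted_p[sub$signature_id == s]
    100 * sum(!is.na(p) & p < alpha) / length(validated_ids)
  }, numeric(1))
  ord <- order(med, -rate, sigs)
  data.frame(signature_id = sigs[ord], adjusted_median_p = med[ord],
             adjusted_significant_rate = rate[ord],
             top = med[ord] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
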