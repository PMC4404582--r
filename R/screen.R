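# The signature x dataset screening matrix: per-cell stratify -> log-rank
# (+ Cox, c-index), significant-rate summaries and rate-based ranking.

#' Screen one signature against one dataset
#'
#' Maps the signature, stratifies the samples at the dendrogram's first
#' bifurcation, and for an ok stratification computes the two-group log-rank
#' test, the univariate Cox hazard ratio (high- vs low-risk under
#' \code{label_mode}) and Harrell's c-index. Any stratification failure, or
#' a degenerate survival configuration, yields an NA cell with its reason.
#'
#' @param sig a \code{gene_signature}.
#' @param ds an \code{expression_dataset}.
#' @param subset optional logical vector selecting samples (clinical subset
#'   screens, e.g. ER-negative).
#' @param label_mode risk-label rule, see \code{\link{assign_risk_labels}}.
#' @param min_coverage,min_group,min_group_frac stratification N/A
#'   thresholds.
#' @param statistics \code{"full"} computes log-rank, Cox HR and c-index;
#'   \code{"logrank"} computes the log-rank P only (used for the large
#'   random-signature nulls, where the other statistics are never read).
#' @return A one-row data.frame (a screen cell) with columns
#'   \code{signature_id}, \code{dataset_id}, \code{status},
#'   \code{na_reason}, \code{logrank_p}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{c_index}.
#' @export
screen_cell <- function(sig, ds, subset = NULL,
                        label_mode = "by_direction",
                        min_coverage = 0.5, min_group = 5,
                        min_group_frac = 0.05,
                        statistics = c("full", "logrank")) {
  statistics <- match.arg(statistics)
  cell <- data.frame(signature_id = sig$id, dataset_id = ds$id,
                     status = "NA", na_reason = NA_character_,
                     logrank_p = NA_real_, hr = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     c_index = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(subset)) {
    ds <- subset_dataset(ds, subset)
  }
  if (length(ds$sample_ids) < 10) {
    cell$na_reason <- "degenerate_group"
    return(cell)
  }
  mapped <- map_signature_to_dataset(sig, ds)
  ga <- stratify_two_groups(ds, mapped, min_coverage = min_coverage,
                            min_group = min_group,
                            min_group_frac = min_group_frac)
  if (ga$status != "ok") {
    cell$na_reason <- ga$na_reason
    return(cell)
  }
  clin <- ds$clinical
  ok <- tryCatch({
    lr <- logrank_two_groups(clin$time, clin$event, ga$labels)
    if (statistics == "logrank") {
      cell$status <- "ok"
      cell$logrank_p <- lr$p_value
      return(cell)
    }
    ga <- assign_risk_labels(ga, ds, mapped, sig = sig, mode = label_mode)
    if (ga$status != "ok") {
      cell$na_reason <- ga$na_reason
      return(cell)
    }
    risk <- as.integer(ga$risk_labels[as.character(ga$labels)] == "high_risk")
    cox <- tryCatch(cox_univariate(factor(risk, levels = 0:1), clin$time,
                                   clin$event),
                    error = function(e) NULL)
    cell$status <- "ok"
    cell$logrank_p <- lr$p_value
    if (!is.null(cox) && cox$converged) {
      cell$hr <- cox$hr
      cell$ci_low <- cox$ci[1L]
      cell$ci_high <- cox$ci[2L]
    }
    cell$c_index <- tryCatch(concordance_index(risk, clin$time, clin$event),
                             error = function(e) NA_real_)
    TRUE
  }, error = function(e) FALSE)
  if (!isTRUE(ok) && cell$status != "ok") {
    if (is.na(cell$na_reason)) cell$na_reason <- "degenerate_group"
  }
  cell
}

#' Restrict a dataset to a sample subset
#'
#' @param ds an \code{expression_dataset}.
#' @param keep logical vector over samples, or a predicate function applied
#'   to the clinical table returning one.
#' @return The restricted \code{expression_dataset} (id tagged with
#'   "_subset").
#' @export
subset_dataset <- function(ds, keep) {
  if (is.function(keep)) keep <- keep(ds$clinical)
  keep[is.na(keep)] <- FALSE
  expression_dataset(paste0(ds$id, "_subset"),
                     ds$matrix[, keep, drop = FALSE],
                     ds$clinical[keep, , drop = FALSE],
                     endpoint = ds$endpoint)
}

#' Run the full signature x dataset screen
#'
#' Every (signature, dataset) pair receives exactly one cell; failures
#' propagate as NA cells with a reason and never abort the grid. Each
#' dataset is tested on its native endpoint. Deterministic given its inputs.
#'
#' @param signatures named list of \code{gene_signature}s.
#' @param registry a \code{dataset_registry}.
#' @param subset_filter optional predicate on a clinical table (applied to
#'   every dataset before stratification), e.g.
#'   \code{function(cl) cl$er == "neg"}.
#' @param alpha significance threshold carried with the matrix.
#' @param ... passed to \code{\link{screen_cell}}.
#' @return A \code{screen_matrix}: long data.frame of cells with attributes
#'   \code{signature_ids}, \code{dataset_ids}, \code{alpha}.
#' @export
run_screen <- function(signatures, registry, subset_filter = NULL,
                       alpha = 0.05, ...) {
  stopifnot(length(registry) > 0)
  cells <- vector("list", length(signatures) * length(registry))
  k <- 0L
  for (ds in registry) {
    sub <- if (is.null(subset_filter)) NULL else subset_filter(ds$clinical)
    for (sig in signatures) {
      k <- k + 1L
      cells[[k]] <- screen_cell(sig, ds, subset = sub, ...)
      # keep the parent dataset id: subsets stay attached to their dataset
      cells[[k]]$dataset_id <- ds$id
    }
  }
  out <- do.call(rbind, cells)
  structure(out,
            signature_ids = vapply(signatures, `[[`, character(1), "id"),
            dataset_ids = vapply(registry, `[[`, character(1), "id"),
            alpha = alpha,
            class = c("screen_matrix", "data.frame"))
}

.matrix_datasets <- function(m) attr(m, "dataset_ids")
.matrix_signatures <- function(m) attr(m, "signature_ids")

#' Percentage of datasets in which a signature is significant
#'
#' NA cells count in the denominator: a failed stratification is a failed
#' prediction. The unrounded percentage is returned; reporting rounds half
#' up to whole percents via \code{\link{round_half_up}}.
#'
#' @param matrix a \code{screen_matrix}.
#' @param signature_id signature to summarize.
#' @param alpha significance threshold (default: the matrix's).
#' @return Unrounded percentage in [0, 100].
#' @export
significant_rate <- function(matrix, signature_id, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(matrix, "alpha")
  rows <- matrix[matrix$signature_id == signature_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("signature '%s' not in matrix",
                                     signature_id), call. = FALSE)
  n_ds <- length(.matrix_datasets(matrix))
  hits <- sum(rows$status == "ok" & rows$logrank_p < alpha, na.rm = TRUE)
  100 * hits / n_ds
}

#' Rank signatures by significant rate and select candidates
#'
#' Signatures are sorted by descending significant rate; candidates must be
#' significant in strictly more than \code{cutoff} percent of datasets
#' ("more than half"). Rate ties are broken by ascending median log-rank P,
#' then lexicographic id.
#'
#' @param matrix a \code{screen_matrix}.
#' @param cutoff candidate threshold in percent (default 50; strict).
#' @param alpha significance threshold (default: the matrix's).
#' @return A data.frame with \code{signature_id}, \code{rate},
#'   \code{rate_rounded}, \code{median_p}, \code{candidate}, ordered by
#'   rank.
#' @export
rank_signatures_by_rate <- function(matrix, cutoff = 50, alpha = NULL) {
  sigs <- .matrix_signatures(matrix)
  if (length(sigs) == 0L || nrow(matrix) == 0L) {
    return(data.frame(signature_id = character(0), rate = numeric(0),
                      rate_rounded = numeric(0), median_p = numeric(0),
                      candidate = logical(0)))
  }
  rate <- vapply(sigs, function(s) significant_rate(matrix, s, alpha),
                 numeric(1))
  med_p <- vapply(sigs, function(s) {
    p <- matrix$logrank_p[matrix$signature_id == s & matrix$status == "ok"]
    if (length(p) == 0L) 1 else stats::median(p)
  }, numeric(1))
  ord <- order(-rate, med_p, sigs)
  data.frame(signature_id = sigs[ord], rate = rate[ord],
             rate_rounded = round_half_up(rate[ord]),
             median_p = med_p[ord],
             candidate = rate[ord] > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a screen matrix
#'
#' Writes the long-format cell table and a wide P-value matrix
#' (signatures x datasets) as TSV.
#'
#' @param matrix a \code{screen_matrix}.
#' @param long_path,wide_path output paths (either may be NULL to skip).
#' @return Invisibly, the wide P matrix.
#' @export
write_screen_matrix <- function(matrix, long_path = NULL, wide_path = NULL) {
  if (!is.null(long_path)) {
    utils::write.table(as.data.frame(matrix), long_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sigs <- .matrix_signatures(matrix)
  dss <- .matrix_datasets(matrix)
  wide <- base::matrix(NA_real_, length(sigs), length(dss),
                       dimnames = list(sigs, dss))
  okc <- matrix[matrix$status == "ok", , drop = FALSE]
  wide[cbind(okc$signature_id, okc$dataset_id)] <- okc$logrank_p
  if (!is.null(wide_path)) {
    utils::write.table(data.frame(signature_id = rownames(wide), wide,
                                  check.names = FALSE),
                       wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(wide)
}
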