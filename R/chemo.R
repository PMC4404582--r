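# Neoadjuvant chemotherapy response prediction: retrospective cluster-based
# labels, the prospective drug-sensitive cell-line centroid classifier, and
# PPV/NPV/sensitivity/specificity scoring against pCR/RD, RCB and 3-year
# DRFS.

#' Dichotomize distant relapse-free survival at a horizon
#'
#' \code{early_event}: event within the horizon; \code{survivor}: followed
#' beyond the horizon (any event status); \code{indeterminate}: censored
#' before the horizon without an event — excluded from horizon metrics, with
#' the count always reported.
#'
#' @param time survival times in years (> 0).
#' @param event 0/1 event indicators.
#' @param horizon years (default 3, a typical median follow-up for
#'   neoadjuvant cohorts).
#' @return Factor with levels early_event, survivor, indeterminate.
#' @export
dichotomize_drfs <- function(time, event, horizon = 3.0) {
  .check_surv(time, event)
  out <- ifelse(time > horizon, "survivor",
                ifelse(event == 1, "early_event", "indeterminate"))
  factor(out, levels = c("early_event", "survivor", "indeterminate"))
}

#' Select drug-sensitive cell lines from a panel
#'
#' A line is sensitive when its log(IC50) is strictly below \code{cutoff}
#' for at least one of the named drugs ("and/or"). When HER2 status is
#' recorded, only HER2-negative lines are considered.
#'
#' @param panel a \code{cellline_panel}.
#' @param drugs drug names to consider.
#' @param cutoff log(IC50) threshold (default -1, strict).
#' @return Character vector of selected line ids.
#' @export
select_sensitive_cell_lines <- function(panel, drugs = NULL, cutoff = -1.0) {
  stopifnot(inherits(panel, "cellline_panel"))
  if (is.null(drugs)) drugs <- colnames(panel$log_ic50)
  missing <- setdiff(drugs, colnames(panel$log_ic50))
  if (length(missing)) {
    stop(sprintf("panel lacks drug(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ic <- panel$log_ic50[, drugs, drop = FALSE]
  sel <- rownames(ic)[apply(ic < cutoff, 1L, any)]
  if (!is.null(panel$her2_status)) {
    sel <- sel[panel$her2_status[sel] == "neg"]
  }
  if (length(sel) == 0L) {
    stop("no sensitive cell lines below the cutoff", call. = FALSE)
  }
  sel
}

#' Build a drug-sensitivity centroid for a signature
#'
#' Per-gene arithmetic mean of expression across the selected sensitive
#' lines, restricted to signature genes present in the panel (missing genes
#' are dropped with a warning).
#'
#' @param panel a \code{cellline_panel}.
#' @param lines selected line ids (>= 2).
#' @param sig a \code{gene_signature}.
#' @return A \code{drug_centroid}: list with \code{signature_id},
#'   \code{values} (named per-gene means) and \code{n_lines_used}.
#' @export
build_centroid <- function(panel, lines, sig) {
  stopifnot(inherits(panel, "cellline_panel"), inherits(sig, "gene_signature"))
  if (length(lines) < 2L) {
    stop("centroid requires at least 2 cell lines", call. = FALSE)
  }
  idx <- match(toupper(sig$genes), toupper(rownames(panel$expression)))
  present <- !is.na(idx)
  if (sum(present) < 5L) {
    stop(sprintf("only %d signature gene(s) present in the panel; need >= 5",
                 sum(present)), call. = FALSE)
  }
  if (any(!present)) {
    warning(sprintf("centroid for '%s': %d signature gene(s) missing from the panel",
                    sig$id, sum(!present)), call. = FALSE)
  }
  genes <- rownames(panel$expression)[idx[present]]
  vals <- rowMeans(panel$expression[genes, lines, drop = FALSE])
  structure(list(signature_id = sig$id, values = vals,
                 n_lines_used = length(lines)),
            class = "drug_centroid")
}

#' Classify patients by centroid correlation
#'
#' Spearman rank correlation between each patient profile and the centroid
#' over shared genes; a patient is predicted treatment-sensitive when the
#' correlation is strictly larger than \code{threshold} (rho exactly at the
#' threshold is insensitive). Rank correlation absorbs monotone platform
#' effects, so no cross-platform normalization is applied.
#'
#' @param ds an \code{expression_dataset} of patients.
#' @param centroid a \code{drug_centroid}.
#' @param threshold correlation threshold (default 0.35).
#' @return A \code{response_prediction}: data.frame with \code{sample_id},
#'   \code{rho}, \code{label} (sensitive/insensitive); attribute
#'   \code{method = "centroid"}.
#' @export
classify_by_centroid <- function(ds, centroid, threshold = 0.35) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(centroid, "drug_centroid"))
  idx <- match(toupper(names(centroid$values)), toupper(ds$gene_ids))
  present <- !is.na(idx)
  if (sum(present) < 5L) {
    stop("fewer than 5 centroid genes present in the patient dataset",
         call. = FALSE)
  }
  genes <- ds$gene_ids[idx[present]]
  cen <- centroid$values[present]
  sub <- ds$matrix[genes, , drop = FALSE]
  const <- apply(sub, 2L, function(x) diff(range(x)) == 0)
  if (any(const)) {
    stop(sprintf("constant patient profile(s): %s",
                 paste(colnames(sub)[const], collapse = ", ")), call. = FALSE)
  }
  rho <- as.numeric(stats::cor(sub, cen, method = "spearman"))
  out <- data.frame(sample_id = ds$sample_ids, rho = rho,
                    label = ifelse(rho > threshold, "sensitive", "insensitive"),
                    stringsAsFactors = FALSE)
  structure(out, method = "centroid", threshold = threshold,
            class = c("response_prediction", "data.frame"))
}

#' Classify patients by unsupervised clustering (retrospective)
#'
#' Reuses the screening stratification and risk labeling: the high-risk
#' group maps to predicted treatment-insensitive, the low-risk group to
#' sensitive.
#'
#' @param ds an \code{expression_dataset}.
#' @param sig a \code{gene_signature}.
#' @param label_mode see \code{\link{assign_risk_labels}}.
#' @return A \code{response_prediction} with \code{method = "clustering"}.
#' @export
classify_by_clustering <- function(ds, sig,
                                   label_mode = c("by_direction", "by_outcome")) {
  label_mode <- match.arg(label_mode)
  mapped <- map_signature_to_dataset(sig, ds)
  ga <- stratify_two_groups(ds, mapped)
  if (ga$status != "ok") {
    stop(sprintf("stratification failed (%s); no prediction", ga$na_reason),
         call. = FALSE)
  }
  ga <- assign_risk_labels(ga, ds, mapped, sig = sig, mode = label_mode)
  if (ga$status != "ok") {
    stop("risk labeling unresolved; no prediction", call. = FALSE)
  }
  risk <- ga$risk_labels[as.character(ga$labels)]
  out <- data.frame(sample_id = ds$sample_ids, rho = NA_real_,
                    label = ifelse(risk == "high_risk", "insensitive",
                                   "sensitive"),
                    stringsAsFactors = FALSE)
  structure(out, method = "clustering", label_mode = label_mode,
            class = c("response_prediction", "data.frame"))
}

#' Confusion metrics for a response prediction
#'
#' Positive = predicted insensitive. The condition-positive definition
#' depends on the endpoint: residual disease (\code{"pCR/RD"}), RCB class
#' II/III (\code{"RCB"}), or an early event on the 3-year DRFS clock
#' (\code{"DRFS3y"}; indeterminate patients are excluded and counted).
#'
#' @param pred a \code{response_prediction}.
#' @param clinical clinical table aligned with the prediction's samples
#'   (columns \code{pcr}, \code{rcb} or \code{time}/\code{event} as the
#'   endpoint requires).
#' @param endpoint one of "pCR/RD", "RCB", "DRFS3y".
#' @param horizon DRFS horizon in years (DRFS3y mode).
#' @return A list with the confusion counts (\code{tp}, \code{fp},
#'   \code{tn}, \code{fn}), \code{ppv}, \code{npv}, \code{sensitivity},
#'   \code{specificity} (percentages), \code{n_evaluable} and
#'   \code{n_indeterminate}.
#' @export
response_metrics <- function(pred, clinical, endpoint = c("pCR/RD", "RCB", "DRFS3y"),
                             horizon = 3.0) {
  endpoint <- match.arg(endpoint)
  stopifnot(nrow(pred) == nrow(clinical))
  positive_pred <- pred$label == "insensitive"
  n_indet <- 0L
  if (endpoint == "pCR/RD") {
    cond <- clinical$pcr == "RD"
    eval_mask <- !is.na(cond)
  } else if (endpoint == "RCB") {
    cond <- clinical$rcb %in% c("II", "III")
    eval_mask <- !is.na(clinical$rcb)
  } else {
    d <- dichotomize_drfs(clinical$time, clinical$event, horizon = horizon)
    cond <- d == "early_event"
    eval_mask <- d != "indeterminate"
    n_indet <- sum(!eval_mask)
  }
  pp <- positive_pred[eval_mask]
  cc <- cond[eval_mask]
  if (!any(pp)) stop("no predicted-insensitive patients; PPV undefined",
                     call. = FALSE)
  if (!any(!pp)) stop("no predicted-sensitive patients; NPV undefined",
                      call. = FALSE)
  tp <- sum(pp & cc); fp <- sum(pp & !cc)
  tn <- sum(!pp & !cc); fn <- sum(!pp & cc)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = 100 * tp / (tp + fp),
       npv = 100 * tn / (tn + fn),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       n_evaluable = sum(eval_mask), n_indeterminate = n_indet,
       endpoint = endpoint)
}

#' Kaplan-Meier comparison of predicted response groups
#'
#' @param pred a \code{response_prediction}.
#' @param times,events survival data aligned with the prediction.
#' @return A list with \code{curves} (named list of KM step data for the
#'   sensitive and insensitive groups) and \code{logrank} (chisq, p_value).
#' @export
km_by_prediction <- function(pred, times, events) {
  lab <- pred$label
  if (!all(c("sensitive", "insensitive") %in% lab)) {
    stop("both predicted groups must be non-empty", call. = FALSE)
  }
  list(
    curves = list(
      sensitive = km_curve(times[lab == "sensitive"],
                           events[lab == "sensitive"]),
      insensitive = km_curve(times[lab == "insensitive"],
                             events[lab == "insensitive"])
    ),
    logrank = logrank_two_groups(times, events, lab)
  )
}
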