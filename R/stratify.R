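# Two-group stratification by unsupervised hierarchical clustering on a
# signature's genes, N/A (failure) bookkeeping, risk labeling, and the
# mutation-enrichment clustering variant.

#' Stratify a dataset into two groups on a signature's genes
#'
#' Sample-to-sample distance is 1 minus the Spearman rank correlation of
#' expression profiles over the signature's mapped genes; samples are
#' clustered by average-linkage agglomerative clustering and the tree is cut
#' at its first bifurcation into exactly two groups.
#'
#' A stratification fails (status \code{"NA"}) when the log-rank test
#' downstream would be meaningless:
#' \itemize{
#'   \item \code{low_coverage}: fewer than \code{min_coverage} of the
#'     signature's genes are present in the dataset;
#'   \item \code{constant_expression}: some sample's profile over the mapped
#'     genes is constant, so its Spearman correlation is undefined;
#'   \item \code{degenerate_group}: the minority group has fewer than
#'     \code{max(min_group, min_group_frac * n)} samples.
#' }
#'
#' @param ds an \code{expression_dataset} with at least 10 samples.
#' @param mapped a mapping from \code{\link{map_signature_to_dataset}}.
#' @param min_coverage coverage floor (default 0.5).
#' @param min_group,min_group_frac minority-group floor: absolute count and
#'   fraction of samples (defaults 5 and 0.05).
#' @return A \code{group_assignment}: list with \code{dataset_id},
#'   \code{signature_id}, \code{status} ("ok" or "NA"), \code{na_reason},
#'   and for ok results \code{labels}, a per-sample factor with levels
#'   \code{group1}/\code{group2}.
#' @export
stratify_two_groups <- function(ds, mapped, min_coverage = 0.5,
                                min_group = 5, min_group_frac = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- length(ds$sample_ids)
  if (n < 10) {
    stop(sprintf("dataset '%s' has %d samples; at least 10 required", ds$id, n),
         call. = FALSE)
  }
  fail <- function(reason) {
    structure(list(dataset_id = ds$id, signature_id = mapped$signature_id,
                   status = "NA", na_reason = reason, labels = NULL,
                   risk_labels = NULL),
              class = "group_assignment")
  }
  if (mapped$coverage < min_coverage) return(fail("low_coverage"))
  sub <- ds$matrix[mapped$mapped_genes, , drop = FALSE]
  if (nrow(sub) < 2L) return(fail("constant_expression"))
  rng <- apply(sub, 2L, function(x) diff(range(x)))
  if (any(rng == 0)) return(fail("constant_expression"))

  rho <- stats::cor(sub, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = 2L)

  sizes <- tabulate(cl, nbins = 2L)
  floor_n <- max(min_group, min_group_frac * n)
  if (any(sizes < floor_n)) return(fail("degenerate_group"))

  labels <- factor(paste0("group", cl), levels = c("group1", "group2"))
  names(labels) <- ds$sample_ids
  structure(list(dataset_id = ds$id, signature_id = mapped$signature_id,
                 status = "ok", na_reason = NULL, labels = labels,
                 risk_labels = NULL),
            class = "group_assignment")
}

#' Attach high/low risk labels to a two-group assignment
#'
#' Two labeling rules are provided because the split itself is unsupervised:
#' \describe{
#'   \item{\code{by_direction}}{the high-risk group has the higher mean
#'     expression over the signature's up-regulated genes (all mapped genes
#'     if no directions are annotated) — usable prospectively;}
#'   \item{\code{by_outcome}}{the high-risk group has the higher
#'     Nelson-Aalen cumulative hazard at the median follow-up time —
#'     retrospective, valid for evaluation only.}
#' }
#' Exact ties are broken toward group1 = high_risk and flagged.
#'
#' @param ga an ok \code{group_assignment}.
#' @param ds the dataset it came from.
#' @param mapped the signature mapping used.
#' @param sig the \code{gene_signature} (for directions; only needed in
#'   \code{by_direction} mode).
#' @param mode labeling rule.
#' @return The assignment with \code{risk_labels} (named vector mapping
#'   group1/group2 to high_risk/low_risk) and a \code{tie} flag.
#' @export
assign_risk_labels <- function(ga, ds, mapped, sig = NULL,
                               mode = c("by_direction", "by_outcome")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ga, "group_assignment"))
  if (ga$status != "ok") stop("cannot label a failed stratification", call. = FALSE)
  g1 <- names(ga$labels)[ga$labels == "group1"]
  g2 <- names(ga$labels)[ga$labels == "group2"]

  if (mode == "by_direction") {
    genes <- mapped$mapped_genes
    have_directions <- FALSE
    if (!is.null(sig) && !is.null(sig$directions)) {
      up <- names(sig$directions)[sig$directions == "up"]
      up <- intersect(toupper(up), toupper(genes))
      if (length(up)) {
        genes <- genes[toupper(genes) %in% up]
        have_directions <- TRUE
      }
    }
    m1 <- mean(ds$matrix[genes, g1, drop = FALSE])
    m2 <- mean(ds$matrix[genes, g2, drop = FALSE])
    tie <- isTRUE(all.equal(m1, m2))
    if (tie && !have_directions) {
      # no direction information and nothing to break the tie: unresolved
      ga$status <- "NA"
      ga$na_reason <- "degenerate_group"
      return(ga)
    }
    score <- c(group1 = m1, group2 = m2)
  } else {
    clin <- ds$clinical
    med_fu <- stats::median(clin$time)
    na_at <- function(ids) {
      t <- clin[ids, "time"]; e <- clin[ids, "event"]
      sf <- survival::survfit(survival::Surv(t, e) ~ 1)
      ch <- -log(summary(sf, times = med_fu, extend = TRUE)$surv)
      if (!is.finite(ch)) ch <- max(-log(min(sf$surv[sf$surv > 0])), 0)
      ch
    }
    score <- c(group1 = na_at(g1), group2 = na_at(g2))
    tie <- isTRUE(all.equal(score[["group1"]], score[["group2"]]))
  }
  high <- if (tie || score[["group1"]] >= score[["group2"]]) "group1" else "group2"
  ga$risk_labels <- stats::setNames(
    ifelse(c("group1", "group2") == high, "high_risk", "low_risk"),
    c("group1", "group2"))
  ga$tie <- tie
  ga
}

#' Mutation enrichment across a two-cluster expression split
#'
#' Samples are clustered on the supplied expression submatrix with Euclidean
#' distance and complete linkage, cut into two clusters at the first
#' bifurcation, and the 2x2 cluster-by-mutation table is tested with
#' Fisher's exact test (two-sided).
#'
#' @param expr genes x samples numeric matrix (already restricted to a
#'   signature's genes).
#' @param mutation per-sample 0/1 mutation status, aligned with columns.
#' @return A list with \code{cluster} (per-sample 1/2), \code{fraction}
#'   (mutant fraction per cluster), \code{table} (2x2 counts) and
#'   \code{p_value}.
#' @export
mutation_cluster_enrichment <- function(expr, mutation) {
  stopifnot(is.matrix(expr), ncol(expr) == length(mutation))
  mutation <- as.integer(mutation)
  if (sum(mutation == 1L) < 2L || sum(mutation == 0L) < 2L) {
    stop("need at least 2 mutant and 2 wild-type samples", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(t(expr), method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2L)
  tab <- table(factor(cl, levels = 1:2),
               factor(mutation, levels = c(1L, 0L),
                      labels = c("mutant", "wild_type")))
  frac <- tab[, "mutant"] / rowSums(tab)
  list(cluster = cl,
       fraction = stats::setNames(as.numeric(frac), c("cluster1", "cluster2")),
       table = tab,
       p_value = stats::fisher.test(tab)$p.value)
}
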