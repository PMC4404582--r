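# Expression + clinical dataset container, TSV readers/writers and the
# dataset registry (YAML manifest) the screening modules consume.

.ENDPOINTS <- c("RFS", "DFS", "DRFS", "DMFS", "OS", "DSS")

#' Construct an expression dataset
#'
#' Bundles a genes-by-samples log-scale expression matrix with a per-sample
#' clinical table (survival time in years, 0/1 event indicator, endpoint
#' label and optional covariates such as ER, HER2, grade, pCR/RD, RCB class
#' or TP53 mutation status).
#'
#' @param id short unique identifier.
#' @param matrix numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param clinical data.frame with one row per sample, containing at least
#'   \code{time} (> 0, years) and \code{event} (0/1); rownames or a
#'   \code{sample_id} column identify samples.
#' @param endpoint survival endpoint label, one of RFS, DFS, DRFS, DMFS,
#'   OS, DSS.
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(id, matrix, clinical, endpoint = "RFS") {
  endpoint <- match.arg(endpoint, .ENDPOINTS)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("'matrix' needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop(sprintf("dataset '%s': duplicate gene ids", id), call. = FALSE)
  }
  if ("sample_id" %in% names(clinical)) {
    rownames(clinical) <- clinical$sample_id
  }
  if (ncol(matrix) != nrow(clinical)) {
    stop(sprintf("dataset '%s': %d expression columns but %d clinical rows",
                 id, ncol(matrix), nrow(clinical)), call. = FALSE)
  }
  if (!all(colnames(matrix) == rownames(clinical))) {
    clinical <- clinical[colnames(matrix), , drop = FALSE]
  }
  if (!all(c("time", "event") %in% names(clinical))) {
    stop("clinical table must contain 'time' and 'event' columns", call. = FALSE)
  }
  if (any(!is.finite(clinical$time)) || any(clinical$time <= 0)) {
    stop(sprintf("dataset '%s': survival times must be strictly positive", id),
         call. = FALSE)
  }
  if (!all(clinical$event %in% c(0, 1))) {
    stop(sprintf("dataset '%s': event indicator must be 0/1", id), call. = FALSE)
  }
  structure(
    list(id = id, matrix = matrix, gene_ids = rownames(matrix),
         sample_ids = colnames(matrix), clinical = clinical,
         endpoint = endpoint),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples, endpoint %s, %d events\n",
              x$id, nrow(x$matrix), ncol(x$matrix), x$endpoint,
              sum(x$clinical$event)))
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' The expression TSV has gene symbols in the first column and one column
#' per sample. The clinical TSV is keyed by sample id (first column or a
#' \code{sample_id} column) with at least \code{time} and \code{event}.
#' Samples are intersected between the two files (inner join, order taken
#' from the expression file); duplicate gene rows are collapsed by the
#' per-gene maximum, which preserves dynamic range for rank-based
#' similarity. Times are converted to years according to \code{time_unit}.
#'
#' @param expr_path expression TSV path.
#' @param clinical_path clinical TSV path.
#' @param endpoint endpoint label (RFS, DFS, DRFS, DMFS, OS, DSS).
#' @param id dataset id; defaults to the expression file name.
#' @param time_unit unit of the clinical \code{time} column.
#' @return An \code{expression_dataset}.
#' @export
read_expression_dataset <- function(expr_path, clinical_path, endpoint = "RFS",
                                    id = NULL,
                                    time_unit = c("years", "months", "days")) {
  time_unit <- match.arg(time_unit)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(expr_path))

  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  genes <- as.character(expr[[1L]])
  m <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(expr[, -1L, drop = FALSE], 2L,
                        function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    row_bad <- which(is.na(suppressWarnings(as.numeric(expr[[bad[1L] + 1L]]))))[1L]
    stop(sprintf("non-numeric expression value at gene row %d, sample column '%s' in '%s'",
                 row_bad, colnames(expr)[bad[1L] + 1L], expr_path), call. = FALSE)
  }
  storage.mode(m) <- "double"

  if (anyDuplicated(genes)) {
    # collapse duplicate gene rows by per-gene maximum
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(ix) {
      if (length(ix) == 1L) m[ix, ] else apply(m[ix, , drop = FALSE], 2L, max)
    }))
    m <- m[unique(genes), , drop = FALSE]  # restore first-occurrence order
  } else {
    rownames(m) <- genes
  }

  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  key <- if ("sample_id" %in% names(clin)) "sample_id" else names(clin)[1L]
  rownames(clin) <- as.character(clin[[key]])

  shared <- intersect(colnames(m), rownames(clin))
  if (length(shared) == 0L) {
    stop(sprintf("no overlapping samples between '%s' and '%s'",
                 expr_path, clinical_path), call. = FALSE)
  }
  shared <- colnames(m)[colnames(m) %in% shared]  # expression-file order
  m <- m[, shared, drop = FALSE]
  clin <- clin[shared, , drop = FALSE]

  div <- switch(time_unit, years = 1, months = 12, days = 365.25)
  clin$time <- clin$time / div

  expression_dataset(id, m, clin, endpoint = endpoint)
}

#' Write an expression dataset to TSV files
#'
#' @param ds an \code{expression_dataset}.
#' @param expr_path,clinical_path output paths.
#' @return A list with the two paths, invisibly.
#' @export
write_expression_dataset <- function(ds, expr_path, clinical_path) {
  df <- data.frame(gene = ds$gene_ids, ds$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- cbind(sample_id = rownames(ds$clinical), ds$clinical)
  utils::write.table(clin, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(expr = expr_path, clinical = clinical_path))
}

#' Build a dataset registry
#'
#' @param datasets list of \code{expression_dataset} objects with unique ids.
#' @return A named list of datasets with class \code{dataset_registry}.
#' @export
dataset_registry <- function(datasets) {
  ids <- vapply(datasets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate dataset id(s) in registry", call. = FALSE)
  }
  structure(stats::setNames(datasets, ids), class = "dataset_registry")
}

#' Read a dataset registry from a YAML manifest
#'
#' The manifest is a YAML list of entries
#' \code{\{id, expr_path, clinical_path, endpoint, time_unit\}}; relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return A \code{dataset_registry}.
#' @export
read_registry <- function(path) {
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  datasets <- lapply(manifest, function(e) {
    read_expression_dataset(resolve(e$expr_path), resolve(e$clinical_path),
                            endpoint = e$endpoint, id = e$id,
                            time_unit = if (is.null(e$time_unit)) "years" else e$time_unit)
  })
  dataset_registry(datasets)
}

#' Write a registry of datasets plus its YAML manifest
#'
#' @param registry a \code{dataset_registry}.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(registry, function(ds) {
    ep <- paste0(ds$id, "_expr.tsv")
    cp <- paste0(ds$id, "_clinical.tsv")
    write_expression_dataset(ds, file.path(dir, ep), file.path(dir, cp))
    list(id = ds$id, expr_path = ep, clinical_path = cp,
         endpoint = ds$endpoint, time_unit = "years")
  })
  manifest <- file.path(dir, "registry.yaml")
  yaml::write_yaml(unname(entries), manifest)
  invisible(manifest)
}
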