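# Gene signatures: construction, GMT-style reading and writing.

#' Construct a gene signature
#'
#' A signature is a named, ordered set of gene symbols with optional per-gene
#' up/down direction annotations (e.g. regulation direction in aggressive
#' tumors or in TP53-mutant samples).
#'
#' @param id short unique identifier.
#' @param genes character vector of gene symbols; duplicates are collapsed
#'   (first occurrence kept) with a warning.
#' @param description free-text description.
#' @param directions optional named character vector mapping a subset of
#'   \code{genes} to \code{"up"}, \code{"down"} or \code{"unknown"}.
#' @param phenotype_tag free-text phenotype label (e.g. "TP53 status").
#' @return An object of class \code{gene_signature}.
#' @export
gene_signature <- function(id, genes, description = "",
                           directions = NULL, phenotype_tag = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("signature 'id' must be a non-empty string", call. = FALSE)
  }
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop(sprintf("signature '%s' has no genes", id), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("signature '%s': duplicate gene symbol(s) collapsed: %s",
                    id, paste(dup, collapse = ", ")), call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  if (!is.null(directions)) {
    directions <- unlist(directions)
    bad <- setdiff(names(directions), genes)
    if (length(bad)) {
      stop(sprintf("signature '%s': directions for genes not in the signature: %s",
                   id, paste(bad, collapse = ", ")), call. = FALSE)
    }
    ok <- directions %in% c("up", "down", "unknown")
    if (!all(ok)) {
      stop(sprintf("signature '%s': invalid direction value(s)", id),
           call. = FALSE)
    }
  }
  structure(
    list(id = id, description = description, genes = genes,
         directions = directions, phenotype_tag = phenotype_tag),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes", x$id, length(x$genes)))
  if (!is.null(x$directions)) {
    cat(sprintf(" (%d up, %d down)",
                sum(x$directions == "up"), sum(x$directions == "down")))
  }
  cat("\n")
  invisible(x)
}

#' Read a GMT-style signature collection
#'
#' One signature per line: \code{id TAB description TAB gene1 TAB gene2 ...}.
#' A gene token may carry a direction suffix \code{"|up"} or \code{"|down"}.
#' Duplicate genes within a line are collapsed with a warning; blank lines
#' are skipped; line order is preserved.
#'
#' @param path path to the text file.
#' @return A named list of \code{gene_signature} objects.
#' @export
read_signature_collection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_idx <- which(nzchar(trimws(lines)))
  if (length(lines_idx) == 0L) {
    stop(sprintf("signature file '%s' is empty", path), call. = FALSE)
  }
  sigs <- vector("list", length(lines_idx))
  ids <- character(length(lines_idx))
  for (k in seq_along(lines_idx)) {
    i <- lines_idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("line %d of '%s': expected id, description and at least one gene",
                   i, path), call. = FALSE)
    }
    tokens <- fields[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) {
      stop(sprintf("line %d of '%s': no genes listed", i, path), call. = FALSE)
    }
    parts <- strsplit(tokens, "|", fixed = TRUE)
    genes <- vapply(parts, `[[`, character(1), 1L)
    dir_tok <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                      character(1))
    directions <- NULL
    if (any(!is.na(dir_tok))) {
      keep <- !is.na(dir_tok) & !duplicated(genes)
      directions <- stats::setNames(dir_tok[keep], genes[keep])
    }
    sigs[[k]] <- gene_signature(fields[1L], genes, description = fields[2L],
                                directions = directions)
    ids[k] <- fields[1L]
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate signature id(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(sigs, ids)
}

#' Write a signature collection in GMT-style format
#'
#' Inverse of \code{\link{read_signature_collection}}: directions are written
#' with the \code{"|up"} / \code{"|down"} suffix dialect (\code{"unknown"}
#' suffixes are omitted).
#'
#' @param sigs list of \code{gene_signature} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signature_collection <- function(sigs, path) {
  lines <- vapply(sigs, function(s) {
    tok <- s$genes
    if (!is.null(s$directions)) {
      d <- s$directions[tok]
      suff <- ifelse(is.na(d) | d == "unknown", "", paste0("|", d))
      tok <- paste0(tok, suff)
    }
    paste(c(s$id, s$description, tok), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map a signature onto a dataset's gene universe
#'
#' Exact, case-insensitive symbol matching; no identifier translation.
#' Coverage is the fraction of signature genes found in the dataset. A
#' coverage of zero is a valid result — downstream stratification decides
#' N/A status.
#'
#' @param sig a \code{gene_signature}.
#' @param ds an \code{expression_dataset}.
#' @return A list with \code{signature_id}, \code{dataset_id},
#'   \code{mapped_genes} (dataset-cased symbols) and \code{coverage}.
#' @export
map_signature_to_dataset <- function(sig, ds) {
  stopifnot(inherits(sig, "gene_signature"), inherits(ds, "expression_dataset"))
  idx <- match(toupper(sig$genes), toupper(ds$gene_ids))
  mapped <- ds$gene_ids[idx[!is.na(idx)]]
  structure(
    list(signature_id = sig$id, dataset_id = ds$id,
         mapped_genes = mapped,
         coverage = length(mapped) / length(sig$genes)),
    class = "mapped_signature"
  )
}
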