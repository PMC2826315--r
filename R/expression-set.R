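#' Expression set: a gene-by-sample matrix with mask, design and scale flag
#'
#' Light container for array expression data. `values` is a numeric
#' gene-by-sample matrix (rownames = gene ids, colnames = sample ids),
#' `mask` a logical matrix of the same shape (`TRUE` = excluded / missing:
#' masked entries are left out of every downstream statistic), `design` a
#' tibble describing the columns, and `log2` says whether values are on the
#' log2 scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must have
#'   unique rownames (gene ids) and colnames matching `design$sample_id`.
#' @param design tibble/data.frame with columns `sample_id`, `allele`,
#'   `tissue`, `replicate`, one row per matrix column.
#' @param mask logical matrix, same shape as `values`; `TRUE` marks an entry
#'   as missing. Defaults to `is.na(values)`.
#' @param log2 logical flag: are values log2-transformed?
#' @return An object of class `xset`.
#' @export
xset <- function(values, design, mask = NULL, log2 = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("`values` must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  design <- as_tibble(design)
  req <- c("sample_id", "allele", "tissue", "replicate")
  if (!all(req %in% names(design))) {
    stop("`design` needs columns: ", paste(req, collapse = ", "))
  }
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  if (!identical(colnames(values), as.character(design$sample_id))) {
    stop("colnames(values) must match design$sample_id (same order)")
  }
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  mask <- mask | is.na(values)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask, design = design, log2 = isTRUE(log2)),
    class = "xset"
  )
}

#' @export
print.xset <- function(x, ...) {
  cat(sprintf(
    "<xset> %d genes x %d samples (%s scale), %.1f%% masked\n",
    nrow(x$values), ncol(x$values),
    if (x$log2) "log2" else "raw",
    100 * mean(x$mask)
  ))
  tis <- table(x$design$tissue)
  cat("  samples:", paste(sprintf("%s=%d", names(tis), tis), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.xset <- function(x) dim(x$values)

#' Gene ids of an expression set
#' @param x an `xset`
#' @return character vector of gene ids
#' @export
gene_ids <- function(x) rownames(x$values)

#' Masked copy of the value matrix
#'
#' Returns the value matrix with masked entries replaced by `NA`, which is the
#' form every downstream statistic consumes (pairwise-complete handling).
#'
#' @param x an `xset`
#' @return numeric matrix with `NA` at masked entries
#' @export
masked_values <- function(x) {
  v <- x$values
  v[x$mask] <- NA_real_
  v
}

#' Subset an expression set by genes and/or samples
#'
#' @param x an `xset`
#' @param genes character vector of gene ids to keep (default all)
#' @param samples character vector of sample ids to keep (default all)
#' @param tissue optional tissue label; keep only samples of this tissue
#' @return an `xset`
#' @export
xset_subset <- function(x, genes = NULL, samples = NULL, tissue = NULL) {
  gi <- gene_ids(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, gi)
    if (length(missing) > 0) {
      stop("unknown gene ids: ", paste(head(missing, 5), collapse = ", "))
    }
    gi <- genes
  }
  si <- x$design$sample_id
  if (!is.null(tissue)) si <- x$design$sample_id[x$design$tissue %in% tissue]
  if (!is.null(samples)) si <- intersect(si, samples)
  if (length(si) == 0) stop("no samples left after subsetting")
  xset(
    values = x$values[gi, si, drop = FALSE],
    design = x$design[match(si, x$design$sample_id), , drop = FALSE],
    mask = x$mask[gi, si, drop = FALSE],
    log2 = x$log2
  )
}

#' Tidy an expression set into long format
#'
#' @param x an `xset`
#' @param ... unused
#' @return tibble with columns gene_id, sample_id, allele, tissue, replicate,
#'   value, masked
#' @export
tidy.xset <- function(x, ...) {
  long <- tibble(
    gene_id = rep(gene_ids(x), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    masked = as.vector(x$mask)
  )
  left_join(long, x$design, by = "sample_id")
}

#' Write / read the expression-set TSV trio
#'
#' `write_xset()` writes `<prefix>_expression.tsv` (gene_id + one column per
#' sample; masked entries written as NA) and `<prefix>_design.tsv`.
#' `read_xset()` reads them back.
#'
#' @param x an `xset`
#' @param prefix file path prefix
#' @return `write_xset()` the prefix, invisibly; `read_xset()` an `xset`.
#' @export
write_xset <- function(x, prefix) {
  v <- masked_values(x)
  expr <- as_tibble(v, rownames = "gene_id")
  readr::write_tsv(expr, paste0(prefix, "_expression.tsv"))
  readr::write_tsv(x$design, paste0(prefix, "_design.tsv"))
  invisible(prefix)
}

#' @rdname write_xset
#' @param log2 scale flag for the matrix being read
#' @export
read_xset <- function(prefix, log2 = FALSE) {
  expr <- readr::read_tsv(paste0(prefix, "_expression.tsv"),
    show_col_types = FALSE
  )
  design <- readr::read_tsv(paste0(prefix, "_design.tsv"),
    show_col_types = FALSE
  )
  v <- as.matrix(expr[, -1])
  rownames(v) <- expr$gene_id
  xset(v, design, log2 = log2)
}
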