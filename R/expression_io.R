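#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row names the samples. Duplicate gene identifiers are
#' collapsed to their per-gene mean (with a warning); duplicate sample
#' columns, ragged rows, non-numeric cells and missing values are rejected.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and at least one gene row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop("duplicate sample id(s) in header: ", paste(dup, collapse = ", "))
  }
  ncol_expected <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1L] + 1L
    stop("ragged row at line ", bad, ": expected ", ncol_expected,
         " fields, found ", widths[bad - 1L])
  }
  genes <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(samples)))
  )
  vals <- matrix(vals, nrow = length(samples))  # guards the 1-sample case
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[1L] + 1L
    stop("non-numeric or missing cell at line ", bad)
  }
  m <- t(vals)
  dimnames(m) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene id(s) by mean: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (sample, group, stage)
#'
#' The group column must only contain "case" and "control".
#'
#' @param path TSV path.
#' @return A data.frame with columns sample, group, stage.
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "stage")
  if (!all(need %in% names(ph))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(ph$group %in% c("case", "control"))) {
    stop("phenotype group values must be 'case' or 'control'")
  }
  if (anyDuplicated(ph$sample)) stop("duplicated sample id(s) in phenotype table")
  ph[need]
}

#' @rdname read_phenotype
#' @param ph Phenotype data.frame.
#' @export
write_phenotype <- function(ph, path) {
  utils::write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Standardise an expression matrix to log2 scale
#'
#' Microarray series are deposited either as linear intensities or already
#' log-transformed. When the matrix maximum exceeds `threshold` (or when
#' `force = TRUE`) every value is replaced by `log2(value + 1)`; otherwise the
#' matrix is returned unchanged. The decision is reported via [message()].
#'
#' @param m Expression matrix.
#' @param threshold Linear-scale detection threshold on the matrix maximum;
#'   values this large are not credible log2 intensities. Default 100.
#' @param force Apply the transform regardless of the detected scale.
#' @return The matrix, possibly log2-transformed.
#' @export
log_standardize <- function(m, threshold = 100, force = FALSE) {
  validate_expression(m)
  apply_it <- force || max(m) > threshold
  if (!apply_it) {
    message("log_standardize: matrix already on log scale (max = ",
            format(max(m)), "); unchanged")
    return(m)
  }
  if (any(m < 0)) stop("log_standardize: negative values cannot be log-transformed")
  message("log_standardize: applying log2(x + 1)")
  log2(m + 1)
}

#' Quantile-normalise an expression matrix across samples
#'
#' Forces every sample (column) onto the average empirical distribution: each
#' sample's r-th smallest value is replaced by the mean of the r-th smallest
#' values across samples, ties within a sample receiving the mean of the tied
#' ranks' row means. Delegates to [limma::normalizeQuantiles()] with
#' `ties = TRUE`.
#'
#' @param m Expression matrix with at least 2 samples; a single-sample matrix
#'   is returned unchanged with a warning.
#' @return The normalised matrix; afterwards all columns have identical
#'   sorted values.
#' @export
quantile_normalize <- function(m) {
  validate_expression(m)
  if (ncol(m) < 2L) {
    warning("quantile_normalize: single-sample matrix returned unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  message("quantile_normalize: normalised ", ncol(m), " samples")
  out
}
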