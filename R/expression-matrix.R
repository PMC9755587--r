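#' Validate a gene-by-sample TPM matrix
#'
#' Checks the invariants every downstream step relies on: a numeric matrix
#' with unique gene identifiers as row names and unique sample labels as
#' column names, all values finite and non-negative, at least one gene and at
#' least two samples (a profile over a single sample carries no pattern).
#'
#' @param x numeric matrix, genes as rows, samples as columns.
#' @return `x`, invisibly, if valid. Otherwise an error describing the first
#'   violated invariant, naming offending genes/samples where applicable.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene identifiers as rownames and sample labels as colnames")
  if (nrow(x) < 1L)
    stop("expression matrix must contain at least 1 gene")
  if (ncol(x) < 2L)
    stop("expression matrix must contain at least 2 samples; got ", ncol(x))
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample label(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop(sprintf(
      "invalid TPM value %s at (gene %s, sample %s): values must be finite and >= 0",
      format(x[i[1L], i[2L]]), rownames(x)[i[1L]], colnames(x)[i[2L]]))
  }
  invisible(x)
}

#' Read a TPM matrix from a tab-separated file
#'
#' The expected layout is the conventional expression-table one: first row a
#' header of sample labels, first column gene identifiers (e.g. Arabidopsis
#' locus tags such as AT5G18690), remaining cells numeric TPM. Use
#' `transpose = TRUE` for files with samples as rows.
#'
#' @param path path to a TSV file.
#' @param transpose logical; if `TRUE` the file holds genes as columns and is
#'   transposed after reading so that genes end up as rows.
#' @return validated numeric matrix, genes x samples, in file order.
#' @seealso [write_tpm_matrix()] for the inverse operation.
#' @export
read_tpm_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("matrix file must have an identifier column plus data columns: ", path)
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (length(bad)) {
    i <- if (is.matrix(bad)) bad[1L, ] else bad
    stop(sprintf("non-numeric cell %s at (gene %s, sample %s) in %s",
                 vals[i[1L], i[2L]], ids[i[1L]], colnames(vals)[i[2L]], path))
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  validate_expression_matrix(num)
  num
}

#' Write a TPM matrix as tab-separated values
#'
#' Values are formatted with `digits` significant digits (6 or more
#' guarantees that a write -> read round trip reproduces the matrix to the
#' printed precision).
#'
#' @param x validated expression matrix.
#' @param path output file path.
#' @param digits significant digits to print (minimum 6 recommended).
#' @param id_header header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(x, path, digits = 8L, id_header = "gene_id") {
  validate_expression_matrix(x)
  fmt <- apply(x, 2L, function(col) formatC(col, digits = digits, format = "g"))
  if (nrow(x) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, colnames(x)))
  out <- cbind(rownames(x), fmt)
  colnames(out) <- c(id_header, colnames(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a subset of samples
#'
#' Used to focus a tissue atlas on the samples of interest (for the floral
#' use case: the flower developmental series plus female and male structures)
#' before computing means and profiles.
#'
#' @param x validated expression matrix.
#' @param keep character vector of sample labels to keep, in the desired
#'   order; must name at least 2 existing samples.
#' @return the matrix restricted to `keep`, columns in `keep` order, gene set
#'   unchanged.
#' @export
subset_samples <- function(x, keep) {
  validate_expression_matrix(x)
  keep <- as.character(keep)
  unknown <- setdiff(keep, colnames(x))
  if (length(unknown))
    stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keep))
    stop("duplicate sample label(s) in keep: ",
         paste(unique(keep[duplicated(keep)]), collapse = ", "))
  if (length(keep) < 2L)
    stop("need at least 2 samples to define a profile; got ", length(keep))
  x[, keep, drop = FALSE]
}

#' Per-gene mean TPM across the matrix's samples
#'
#' The mean is always taken over the samples present in the matrix at call
#' time, so subsetting samples first changes (deliberately) which genes count
#' as expressed.
#'
#' @param x validated expression matrix.
#' @return data.frame with columns `gene_id`, `mean_tpm`, one row per gene in
#'   matrix order. `mean_tpm` is zero exactly when every value for that gene
#'   is zero.
#' @export
gene_means <- function(x) {
  validate_expression_matrix(x)
  data.frame(gene_id = rownames(x), mean_tpm = rowMeans(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a gene-mean table as two-column TSV
#' @param means data.frame from [gene_means()].
#' @param path output file path.
#' @param digits significant digits for `mean_tpm`.
#' @return `path`, invisibly.
#' @export
write_gene_means <- function(means, path, digits = 8L) {
  stopifnot(is.data.frame(means), all(c("gene_id", "mean_tpm") %in% names(means)))
  out <- data.frame(gene_id = means$gene_id,
                    mean_tpm = formatC(means$mean_tpm, digits = digits, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with zero mean expression
#'
#' Genes whose mean TPM over the current samples is zero are unexpressed in
#' every retained sample and carry no profile; they are eliminated before
#' normalization. Because TPM is non-negative the test is exact: the mean is
#' zero iff every value is zero, so no tolerance is involved.
#'
#' @param x validated expression matrix.
#' @return the matrix containing exactly the genes with mean > 0, relative
#'   order preserved. Errors if no gene would remain.
#' @export
drop_unexpressed <- function(x) {
  validate_expression_matrix(x)
  keep <- rowMeans(x) > 0
  if (!any(keep))
    stop("all genes have zero mean expression over the current samples; nothing to analyze")
  x[keep, , drop = FALSE]
}
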