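#' Mean-normalized expression profiles
#'
#' Transforms TPM into per-gene profiles: for gene g and sample s,
#' `z(g, s) = (tpm(g, s) - m(g)) / m(g)` where `m(g)` is the gene's mean TPM
#' over the matrix's samples. The transform is dimensionless, scale-free (a
#' gene's profile does not change if its whole TPM row is multiplied by a
#' positive constant) and every row sums to zero by algebra, so genes with
#' large and small expression levels become comparable patterns.
#'
#' @param x expression matrix that has already passed [drop_unexpressed()]
#'   (every gene mean strictly positive).
#' @return numeric matrix of the same shape holding the z values; every entry
#'   is >= -1.
#' @export
normalize_profiles <- function(x) {
  validate_expression_matrix(x)
  m <- rowMeans(x)
  if (any(m <= 0)) {
    off <- rownames(x)[m <= 0]
    stop("gene(s) with zero mean expression present (run drop_unexpressed first): ",
         paste(utils::head(off, 5L), collapse = ", "))
  }
  sweep(x, 1L, m, "/") - 1
}

#' L1 distance between two expression profiles
#'
#' The co-expression statistic: the sum over samples of absolute differences
#' between two genes' mean-normalized profiles. Zero means identical
#' profiles; larger values mean more dissimilar expression patterns. It is a
#' metric on profile space (non-negative, symmetric, triangle inequality).
#'
#' @param profile_a,profile_b named numeric vectors (one gene's z row each)
#'   over the identical ordered sample set.
#' @return non-negative scalar.
#' @export
delta_sum <- function(profile_a, profile_b) {
  na <- names(profile_a); nb <- names(profile_b)
  if (is.null(na) || is.null(nb) || !identical(na, nb)) {
    diff <- union(setdiff(na, nb), setdiff(nb, na))
    stop("profiles must share an identical ordered sample set; mismatch: ",
         if (length(diff)) paste(diff, collapse = ", ") else "same labels, different order")
  }
  sum(abs(profile_a - profile_b))
}

#' Rank all genes by profile distance to a query gene
#'
#' Computes the L1 profile distance from the query to every gene of the
#' normalized matrix (including the query itself, whose distance is exactly
#' zero) and sorts ascending. Ties are broken lexicographically by gene
#' identifier for reproducibility, except that the query is always first even
#' if other genes also sit at distance zero.
#'
#' @param z normalized profile matrix from [normalize_profiles()].
#' @param query gene identifier present in `z`.
#' @param top_k optional positive integer; keep only the first `top_k`
#'   entries of the ranking (the query is always retained).
#' @return data.frame with columns `rank`, `gene_id`, `dsum`, first row the
#'   query at `dsum = 0`. Carries the sample labels used as attribute
#'   `"sample_labels"` and the query as attribute `"query"`.
#' @export
rank_coexpressed <- function(z, query, top_k = NULL) {
  if (!is.matrix(z) || is.null(rownames(z)))
    stop("z must be a matrix with gene identifiers as rownames")
  if (!query %in% rownames(z)) stop("unknown query gene: ", query)
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1L) stop("top_k must be a positive integer")
  }
  qrow <- z[query, ]
  d <- rowSums(abs(sweep(z, 2L, qrow, "-")))
  d[query] <- 0  # exact, not subject to rounding
  ord <- order(d, rownames(z), method = "radix")
  ids <- rownames(z)[ord]
  d <- d[ord]
  qi <- match(query, ids)  # query first, ahead of any other zero-distance gene
  if (qi != 1L) {
    ids <- c(query, ids[-qi])
    d <- c(0, d[-qi])
  }
  if (!is.null(top_k) && top_k < length(ids)) {
    ids <- ids[seq_len(top_k)]
    d <- d[seq_len(top_k)]
  }
  res <- data.frame(rank = seq_along(ids), gene_id = ids, dsum = unname(d),
                    stringsAsFactors = FALSE)
  attr(res, "query") <- query
  attr(res, "sample_labels") <- colnames(z)
  res
}

#' Full co-expression ranking pipeline from a TPM matrix
#'
#' Convenience wrapper chaining sample subsetting, the zero-mean filter,
#' normalization and ranking. `mean_scope` resolves the one genuine ambiguity
#' of the procedure: with `"subset"` (default) gene means — and therefore the
#' zero filter and the normalization — are computed on the retained samples
#' only; with `"full"` they are computed on the full matrix first and the
#' profiles are subset afterwards (so profile rows need not sum to zero over
#' the retained samples).
#'
#' @param x validated expression matrix.
#' @param query gene identifier.
#' @param samples optional character vector of sample labels to rank over;
#'   `NULL` uses all samples.
#' @param top_k optional ranking truncation, see [rank_coexpressed()].
#' @param mean_scope `"subset"` or `"full"`, see Details.
#' @return ranking data.frame as from [rank_coexpressed()].
#' @export
coexpression_ranking <- function(x, query, samples = NULL, top_k = NULL,
                                 mean_scope = c("subset", "full")) {
  mean_scope <- match.arg(mean_scope)
  validate_expression_matrix(x)
  if (mean_scope == "subset") {
    if (!is.null(samples)) x <- subset_samples(x, samples)
    z <- normalize_profiles(drop_unexpressed(x))
  } else {
    z <- normalize_profiles(drop_unexpressed(x))
    if (!is.null(samples)) {
      samples <- as.character(samples)
      unknown <- setdiff(samples, colnames(z))
      if (length(unknown))
        stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
      if (length(samples) < 2L)
        stop("need at least 2 samples to define a profile; got ", length(samples))
      z <- z[, samples, drop = FALSE]  # z may be negative; bypass TPM validation
    }
  }
  rank_coexpressed(z, query, top_k = top_k)
}

#' Write a co-expression ranking as TSV
#' @param ranking data.frame from [rank_coexpressed()].
#' @param path output file path.
#' @param digits significant digits for `dsum`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, digits = 6L) {
  stopifnot(is.data.frame(ranking), all(c("rank", "gene_id", "dsum") %in% names(ranking)))
  out <- data.frame(rank = ranking$rank, gene_id = ranking$gene_id,
                    dsum = formatC(ranking$dsum, digits = digits, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
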