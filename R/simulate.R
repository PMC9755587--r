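# run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Named archetype expression shapes
#'
#' Qualitative tissue-series shapes used to plant co-expression modules:
#' `"peak"` (low baseline, one strong peak, the stigma-like pattern),
#' `"decreasing"` (high early in the series, declining), `"increasing"`
#' (the reverse) and `"flat"` (constant). These are simulation fixtures, not
#' claims about any real dataset.
#'
#' @param shape one of `"peak"`, `"decreasing"`, `"increasing"`, `"flat"`.
#' @param n_samples profile length.
#' @param peak_at peak position for `"peak"`, default the last sample.
#' @return non-negative numeric vector of length `n_samples`.
#' @export
archetype_profile <- function(shape = c("peak", "decreasing", "increasing", "flat"),
                              n_samples, peak_at = n_samples) {
  shape <- match.arg(shape)
  stopifnot(n_samples >= 2L, peak_at >= 1L, peak_at <= n_samples)
  switch(shape,
    peak = { p <- rep(1, n_samples); p[peak_at] <- 12; p },
    decreasing = 10 * 0.6^(seq_len(n_samples) - 1L),
    increasing = 10 * 0.6^(n_samples - seq_len(n_samples)),
    flat = rep(1, n_samples))
}

#' Simulate a TPM matrix with planted co-expression modules
#'
#' Module genes are an archetype profile multiplied by a gene-specific
#' positive scale factor and perturbed by multiplicative log-normal noise of
#' standard deviation `noise_sd` on the natural-log scale — so at
#' `noise_sd = 0` all members of a module have identical mean-normalized
#' profiles (pairwise L1 distance exactly 0). Background genes are drawn
#' independently log-normally per sample, and a fixed fraction of genes is
#' set identically to zero to exercise the unexpressed-gene filter.
#' Expression noise is multiplicative because TPM is non-negative and
#' right-skewed.
#'
#' @param n_genes total number of genes.
#' @param sample_labels ordered sample/tissue labels (>= 2).
#' @param modules list of modules, each a list with `size` (positive integer)
#'   and `profile` (non-negative archetype over the samples, not all zero);
#'   sizes must sum to <= `n_genes` after reserving the zero genes.
#' @param noise_sd log-scale multiplicative noise sd, >= 0.
#' @param zero_fraction fraction of genes set identically zero, in [0, 1);
#'   exactly `round(zero_fraction * n_genes)` genes are zeroed.
#' @param bg_meanlog,bg_sdlog log-normal location and scale of the background
#'   distribution, scalars or per-sample vectors.
#' @param seed integer seed; equal seeds give identical output.
#' @return list with `matrix` (validated TPM matrix, genes x samples) and
#'   `truth` (data.frame gene_id, group: "module<i>", "background" or "zero").
#' @export
simulate_tpm <- function(n_genes, sample_labels, modules = list(),
                         noise_sd = 0.1, zero_fraction = 0,
                         bg_meanlog = 1, bg_sdlog = 1.5, seed = 1L) {
  n_s <- length(sample_labels)
  if (n_s < 2L) stop("need at least 2 sample labels")
  if (anyDuplicated(sample_labels)) stop("sample labels must be unique")
  stopifnot(n_genes >= 1L, noise_sd >= 0, zero_fraction >= 0, zero_fraction < 1)
  bg_meanlog <- rep_len(bg_meanlog, n_s)
  bg_sdlog <- rep_len(bg_sdlog, n_s)
  if (any(bg_sdlog <= 0)) stop("background sdlog must be > 0")
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1L))
  for (m in modules) {
    if (length(m$profile) != n_s)
      stop("module profile length ", length(m$profile), " != number of samples ", n_s)
    if (any(m$profile < 0) || all(m$profile == 0))
      stop("module profiles must be non-negative and not all zero")
    if (m$size < 1L) stop("module sizes must be positive")
  }
  n_zero <- round(zero_fraction * n_genes)
  if (sum(sizes) + n_zero > n_genes)
    stop("module sizes plus zero genes exceed n_genes")

  gene_ids <- sprintf("AT0G%05d", seq_len(n_genes))
  group <- rep("background", n_genes)
  mat <- with_seed(seed, {
    x <- matrix(0, n_genes, n_s, dimnames = list(gene_ids, sample_labels))
    pos <- 1L
    for (j in seq_along(modules)) {
      idx <- seq.int(pos, length.out = sizes[j])
      pos <- pos + sizes[j]
      group[idx] <- paste0("module", j)
      scale_g <- stats::rlnorm(sizes[j], meanlog = bg_meanlog[1L], sdlog = 1)
      noise <- matrix(stats::rnorm(sizes[j] * n_s, 0, noise_sd), sizes[j], n_s)
      x[idx, ] <- outer(scale_g, modules[[j]]$profile) * exp(noise)
    }
    bg_idx <- seq.int(pos, n_genes)
    if (length(bg_idx)) {
      for (s in seq_len(n_s))
        x[bg_idx, s] <- stats::rlnorm(length(bg_idx), bg_meanlog[s], bg_sdlog[s])
      if (n_zero > 0L) {
        zi <- sample(bg_idx, n_zero)
        x[zi, ] <- 0
        group[zi] <- "zero"
      }
    } else if (n_zero > 0L) stop("no background genes left to zero out")
    x
  })
  validate_expression_matrix(mat)
  list(matrix = mat,
       truth = data.frame(gene_id = gene_ids, group = group,
                          stringsAsFactors = FALSE))
}

#' Simulate a qPCR plate with known fold changes
#'
#' Generative model on the Cq (cycle) scale with additive normal noise, the
#' conventional qPCR error model. For target gene g in sample s, biological
#' replicate b, technical replicate t:
#' `Cq = base(g) - log2(fold_g(s)) + bio_effect(s, b) + tech_noise`.
#' Reference genes share the same `bio_effect(s, b)` (a plate/sample-wide
#' offset affecting all genes of a cDNA preparation alike) and add their own
#' technical noise, so the offset cancels exactly in dCt. The calibrator
#' sample's true fold is 1 for every target by definition.
#'
#' @param sample_labels tissue/stage labels; default the five reproductive
#'   samples of the emulated design (pistil stages 11/12/14, anther stage 12,
#'   silique stage 17).
#' @param calibrator sample all folds are relative to; default
#'   `"anther_st12"`.
#' @param target_folds named list: target gene -> named numeric vector of
#'   true fold changes per sample (entry for the calibrator must be 1).
#' @param target_base_cq named numeric, base Cq per target at fold 1;
#'   recycled default 26.
#' @param ref_base_cq named numeric, constant Cq level per reference gene;
#'   default the three-reference design `RCE1`, `TUA2`, `YLS8` at 22/23/24
#'   cycles.
#' @param n_bio,n_tech biological and technical replicates; default 3 and 3,
#'   the emulated design.
#' @param cq_noise_sd technical noise sd in cycles, >= 0.
#' @param bio_noise_sd biological (sample-preparation) offset sd in cycles
#'   (non-negative).
#' @param seed integer seed.
#' @return list with `cq` (long-format validated Cq table) and `truth`
#'   (data.frame target, sample, fold).
#' @export
simulate_plate <- function(sample_labels = c("pistil_st11", "pistil_st12",
                                             "anther_st12", "pistil_st14",
                                             "silique_st17"),
                           calibrator = "anther_st12",
                           target_folds,
                           target_base_cq = NULL,
                           ref_base_cq = c(RCE1 = 22, TUA2 = 23, YLS8 = 24),
                           n_bio = 3L, n_tech = 3L,
                           cq_noise_sd = 0.1, bio_noise_sd = 0,
                           seed = 1L) {
  stopifnot(n_bio >= 1L, n_tech >= 1L, cq_noise_sd >= 0, bio_noise_sd >= 0)
  if (!calibrator %in% sample_labels) stop("calibrator not among sample labels: ", calibrator)
  if (is.null(names(target_folds)) || any(names(target_folds) == ""))
    stop("target_folds must be a named list (target gene -> fold per sample)")
  if (is.null(names(ref_base_cq)) || length(ref_base_cq) < 1L)
    stop("need at least one named reference gene level")
  targets <- names(target_folds)
  if (is.null(target_base_cq)) target_base_cq <- stats::setNames(rep(26, length(targets)), targets)
  for (g in targets) {
    f <- target_folds[[g]]
    if (is.null(names(f)) || !all(sample_labels %in% names(f)))
      stop("fold vector for ", g, " must be named with every sample label")
    if (any(f <= 0)) stop("true fold changes must be > 0 (gene ", g, ")")
    if (f[[calibrator]] != 1)
      stop("calibrator fold must be 1 by definition (gene ", g, " has ", f[[calibrator]], ")")
  }
  refs <- names(ref_base_cq)
  overlap <- intersect(targets, refs)
  if (length(overlap)) stop("gene(s) both target and reference: ", paste(overlap, collapse = ", "))

  cq <- with_seed(seed, {
    bio_eff <- matrix(stats::rnorm(length(sample_labels) * n_bio, 0, bio_noise_sd),
                      length(sample_labels), n_bio,
                      dimnames = list(sample_labels, NULL))
    grid <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                        gene = c(targets, refs), sample = sample_labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base <- ifelse(grid$gene %in% targets,
                   target_base_cq[grid$gene] -
                     log2(mapply(function(g, s) if (g %in% targets) target_folds[[g]][[s]] else 1,
                                 grid$gene, grid$sample)),
                   ref_base_cq[grid$gene])
    val <- base + bio_eff[cbind(match(grid$sample, sample_labels), grid$bio_rep)] +
      stats::rnorm(nrow(grid), 0, cq_noise_sd)
    data.frame(sample = grid$sample, gene = grid$gene,
               role = ifelse(grid$gene %in% targets, "target", "reference"),
               bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
               cq = val, stringsAsFactors = FALSE)
  })
  validate_cq_table(cq)
  truth <- do.call(rbind, lapply(targets, function(g)
    data.frame(target = g, sample = sample_labels,
               fold = as.numeric(target_folds[[g]][sample_labels]),
               stringsAsFactors = FALSE)))
  list(cq = cq, truth = truth)
}

#' Write a long-format Cq table as CSV
#' @param cq validated Cq table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path) {
  validate_cq_table(cq)
  utils::write.csv(cq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
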