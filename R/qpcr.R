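#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Cq on log10 template dilution. The slope of a
#' perfect doubling chemistry is -1/log10(2) = -3.3219 cycles per tenfold
#' dilution; amplification efficiency is derived from the slope by the
#' closed form `E = (10^(-1/slope) - 1) * 100` (percent), so that slope
#' -1/log10(k) maps to (k - 1) * 100 for any per-cycle gain k.
#'
#' @param series data.frame with numeric columns `log10_dilution` and `cq`
#'   (a tenfold series 1:10, 1:100, 1:1000 gives -1, -2, -3), at least 3
#'   points with distinct dilutions.
#' @param gene_id optional identifier carried through to the result.
#' @return list of class `"standard_curve_fit"` with `gene_id`, `slope`,
#'   `intercept`, `r_squared` (squared Pearson correlation) and
#'   `efficiency_pct`.
#' @export
fit_standard_curve <- function(series, gene_id = NA_character_) {
  stopifnot(is.data.frame(series),
            all(c("log10_dilution", "cq") %in% names(series)))
  x <- as.numeric(series$log10_dilution)
  y <- as.numeric(series$cq)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("standard-curve points must be finite numbers")
  if (length(x) < 3L)
    stop("standard curve needs at least 3 dilution points; got ", length(x))
  if (length(unique(x)) < 2L)
    stop("all dilution values identical; cannot fit a line")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (slope == 0) stop("zero slope: no dilution response, efficiency undefined")
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  structure(list(
    gene_id = gene_id,
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    efficiency_pct = (10^(-1 / slope) - 1) * 100
  ), class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("standard curve%s: slope %.4f, intercept %.3f, R2 %.4f, E %.2f%%\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$slope, x$intercept, x$r_squared, x$efficiency_pct))
  invisible(x)
}

#' Quality control of a standard-curve fit
#'
#' A primer pair passes when the coefficient of determination exceeds 0.980
#' and the amplification efficiency lies between 90% and 110% (inclusive
#' bounds on E, strict on R squared). A failing fit reports every violated
#' bound.
#'
#' @param fit a `"standard_curve_fit"`.
#' @param r2_min minimum R squared (exclusive), default 0.980.
#' @param efficiency_range inclusive percent bounds on E, default c(90, 110).
#' @return list with logical `pass` and character vector `reasons` (empty on
#'   pass).
#' @export
qc_standard_curve <- function(fit, r2_min = 0.980, efficiency_range = c(90, 110)) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  reasons <- character(0)
  if (!(fit$r_squared > r2_min))
    reasons <- c(reasons, sprintf("R squared %.4f not above %.3f", fit$r_squared, r2_min))
  if (fit$efficiency_pct < efficiency_range[1L])
    reasons <- c(reasons, sprintf("efficiency %.2f%% below %g%%",
                                  fit$efficiency_pct, efficiency_range[1L]))
  if (fit$efficiency_pct > efficiency_range[2L])
    reasons <- c(reasons, sprintf("efficiency %.2f%% above %g%%",
                                  fit$efficiency_pct, efficiency_range[2L]))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Read per-primer standard-curve series from CSV
#'
#' Expected header: `gene,log10_dilution,cq`.
#' @param path CSV file path.
#' @return data.frame with those three columns.
#' @export
read_standard_curves <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "log10_dilution", "cq")
  if (!all(need %in% names(df)))
    stop("standard-curve file must have header gene,log10_dilution,cq: ", path)
  df$log10_dilution <- as.numeric(df$log10_dilution)
  df$cq <- as.numeric(df$cq)
  if (anyNA(df$log10_dilution) || anyNA(df$cq))
    stop("non-numeric dilution or cq value in ", path)
  df
}

#' Fit and QC standard curves for every primer pair in a series table
#' @param series data.frame as from [read_standard_curves()].
#' @param ... passed to [qc_standard_curve()].
#' @return data.frame with one row per gene: slope, intercept, r_squared,
#'   efficiency_pct, pass, reasons (";"-joined).
#' @export
fit_standard_curves <- function(series, ...) {
  rows <- lapply(split(series, series$gene), function(d) {
    fit <- fit_standard_curve(d, gene_id = d$gene[1L])
    qc <- qc_standard_curve(fit, ...)
    data.frame(gene = d$gene[1L], slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, efficiency_pct = fit$efficiency_pct,
               pass = qc$pass, reasons = paste(qc$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long-format Cq table from CSV
#'
#' Expected header: `sample,gene,role,bio_rep,tech_rep,cq` with
#' `role` in {target, reference}. A gene must carry a single role across the
#' table, and (sample, gene, bio_rep, tech_rep) tuples must be unique.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cq_table(df)
  df
}

#' Validate a long-format Cq table
#' @param cq data.frame with columns sample, gene, role, bio_rep, tech_rep, cq.
#' @return `cq`, invisibly, if valid.
#' @export
validate_cq_table <- function(cq) {
  need <- c("sample", "gene", "role", "bio_rep", "tech_rep", "cq")
  miss <- setdiff(need, names(cq))
  if (length(miss)) stop("Cq table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(cq$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'; got: ",
         paste(unique(setdiff(cq$role, c("target", "reference"))), collapse = ", "))
  role_per_gene <- tapply(cq$role, cq$gene, function(r) length(unique(r)))
  if (any(role_per_gene > 1L))
    stop("gene(s) with conflicting roles: ",
         paste(names(role_per_gene)[role_per_gene > 1L], collapse = ", "))
  if (!any(cq$role == "reference"))
    stop("Cq table contains no reference gene")
  if (!all(is.finite(cq$cq)) || any(cq$cq <= 0))
    stop("all Cq values must be finite positive cycle numbers")
  if (any(cq$bio_rep < 1L) || any(cq$tech_rep < 1L))
    stop("replicate indices must be integers >= 1")
  key <- paste(cq$sample, cq$gene, cq$bio_rep, cq$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- cq[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate well: sample %s, gene %s, bio_rep %s, tech_rep %s",
                 d$sample, d$gene, d$bio_rep, d$tech_rep))
  }
  invisible(cq)
}

#' Reference genes of a Cq table
#' @param cq validated Cq table.
#' @return character vector of gene identifiers tagged `reference`.
#' @export
reference_genes <- function(cq) sort(unique(cq$gene[cq$role == "reference"]))

#' Average technical replicates to one Cq per (sample, gene, biological rep)
#'
#' Technical replicates measure pipetting/instrument noise on the same cDNA
#' and are averaged before any quantification; biological replicates are kept
#' separate so that downstream error bars reflect biology.
#'
#' @param cq validated Cq table.
#' @return data.frame with columns `sample`, `gene`, `role`, `bio_rep`, `cq`
#'   (mean over technical replicates) and `n_tech`.
#' @export
aggregate_technical <- function(cq) {
  validate_cq_table(cq)
  agg <- stats::aggregate(cq$cq,
                          by = list(sample = cq$sample, gene = cq$gene,
                                    role = cq$role, bio_rep = cq$bio_rep),
                          FUN = mean)
  n <- stats::aggregate(cq$cq,
                        by = list(sample = cq$sample, gene = cq$gene,
                                  role = cq$role, bio_rep = cq$bio_rep),
                        FUN = length)
  agg$n_tech <- n$x
  names(agg)[names(agg) == "x"] <- "cq"
  agg[order(agg$sample, agg$gene, agg$bio_rep), , drop = FALSE]
}

#' Relative expression by the 2^-ddCt method with multiple reference genes
#'
#' For every biological replicate b of sample s:
#' `dCt(s, b) = Cq_target(s, b) - mean of the reference genes' Cq(s, b)`
#' (arithmetic mean on the Cq scale, i.e. geometric mean of reference
#' quantities); `ddCt(s, b) = dCt(s, b) - dCt_cal` where `dCt_cal` averages
#' the calibrator sample's per-replicate dCt; `fold(s, b) = 2^-ddCt(s, b)`.
#' Fold changes are summarized per sample as mean and SEM over biological
#' replicates. Quantification assumes perfect doubling (the literal 2);
#' amplification efficiency is a QC gate, not a correction.
#'
#' @param agg aggregated table from [aggregate_technical()].
#' @param target target gene identifier.
#' @param calibrator sample label all fold changes are expressed against
#'   (fold 1 by construction, up to replicate noise).
#' @param refs reference gene identifiers; default: all genes tagged
#'   `reference` in `agg`.
#' @return list of class `"relative_expression"` with
#'   `per_rep` (sample, bio_rep, dct, ddct, fold) and
#'   `per_sample` (sample, n_bio, mean_fold, sem_fold), plus the target,
#'   calibrator and reference set used.
#' @export
delta_delta_ct <- function(agg, target, calibrator, refs = NULL) {
  stopifnot(is.data.frame(agg),
            all(c("sample", "gene", "role", "bio_rep", "cq") %in% names(agg)))
  if (is.null(refs)) refs <- sort(unique(agg$gene[agg$role == "reference"]))
  if (!length(refs)) stop("no reference genes available")
  if (!target %in% agg$gene) stop("target gene not in table: ", target)
  if (!calibrator %in% agg$sample) stop("calibrator sample not in table: ", calibrator)

  tgt <- agg[agg$gene == target, , drop = FALSE]
  if (!nrow(tgt)) stop("no rows for target ", target)
  key <- function(s, b) paste(s, b, sep = "\r")
  ref_rows <- agg[agg$gene %in% refs, , drop = FALSE]
  per_rep <- do.call(rbind, lapply(seq_len(nrow(tgt)), function(i) {
    s <- tgt$sample[i]; b <- tgt$bio_rep[i]
    r <- ref_rows[key(ref_rows$sample, ref_rows$bio_rep) == key(s, b), , drop = FALSE]
    have <- unique(r$gene)
    miss <- setdiff(refs, have)
    if (length(miss))
      stop(sprintf("missing reference measurement(s) for sample %s, bio_rep %s: %s",
                   s, b, paste(miss, collapse = ", ")))
    data.frame(sample = s, bio_rep = b,
               dct = tgt$cq[i] - mean(r$cq[match(refs, r$gene)]),
               stringsAsFactors = FALSE)
  }))
  cal <- per_rep$dct[per_rep$sample == calibrator]
  if (!length(cal)) stop("calibrator sample has no target measurements: ", calibrator)
  dct_cal <- mean(cal)
  per_rep$ddct <- per_rep$dct - dct_cal
  per_rep$fold <- 2^(-per_rep$ddct)

  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  per_sample <- do.call(rbind, lapply(split(per_rep, per_rep$sample), function(d) {
    data.frame(sample = d$sample[1L], n_bio = nrow(d),
               mean_fold = mean(d$fold), sem_fold = sem(d$fold),
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  structure(list(target = target, calibrator = calibrator, refs = refs,
                 per_rep = per_rep, per_sample = per_sample),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression of %s (calibrator %s; refs %s)\n",
              x$target, x$calibrator, paste(x$refs, collapse = ", ")))
  print(x$per_sample, ...)
  invisible(x)
}

#' Full qPCR relative-quantification pipeline with significance testing
#'
#' Chains technical-replicate aggregation, 2^-ddCt fold changes against the
#' calibrator and a one-way ANOVA with Dunnett contrasts of every sample
#' against the calibrator. By default the test runs on the per-replicate dCt
#' values (log2 scale, variance-stabilized); `test_on = "fold"` tests the
#' linear-scale fold changes instead.
#'
#' @param cq validated long-format Cq table.
#' @param target target gene identifier.
#' @param calibrator calibrator sample label (the control group of the
#'   Dunnett family).
#' @param alpha family-wise significance level, default 0.05.
#' @param test_on `"dct"` (default) or `"fold"`.
#' @return data.frame with one row per sample: `sample`, `n_bio`,
#'   `mean_fold`, `sem_fold`, `p_adjusted` (NA for the calibrator) and
#'   `label` (ns/*/**/***/****); the ANOVA table is attached as attribute
#'   `"anova"`, the per-replicate folds as attribute `"per_rep"`.
#' @export
quantify_expression <- function(cq, target, calibrator, alpha = 0.05,
                                test_on = c("dct", "fold")) {
  test_on <- match.arg(test_on)
  agg <- aggregate_technical(cq)
  rel <- delta_delta_ct(agg, target, calibrator)
  vals <- if (test_on == "dct") rel$per_rep$dct else rel$per_rep$fold
  dn <- dunnett_vs_control(vals, rel$per_rep$sample, control = calibrator,
                           alpha = alpha)
  out <- rel$per_sample
  idx <- match(out$sample, dn$comparisons$group)
  out$p_adjusted <- dn$comparisons$p_adjusted[idx]
  out$label <- ifelse(is.na(out$p_adjusted), NA_character_,
                      significance_label(out$p_adjusted))
  attr(out, "anova") <- dn$anova
  attr(out, "per_rep") <- rel$per_rep
  attr(out, "target") <- target
  attr(out, "calibrator") <- calibrator
  out
}
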