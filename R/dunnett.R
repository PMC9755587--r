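#' Joint probability that all Dunnett contrasts stay within +/- q
#'
#' Computes `P(max_i |T_i| <= q)` for the family of two-sided Dunnett
#' statistics `T_i = (mean_i - mean_0) / (S * sqrt(1/n_i + 1/n_0))` under the
#' null, with a shared control mean and a pooled variance estimate on `df`
#' degrees of freedom. The statistics are equicorrelated through the control
#' only, so the multivariate-t probability factorizes conditionally on the
#' control mean and on the pooled scale; the two remaining integrals are done
#' by deterministic adaptive quadrature (target accuracy well below 1e-6),
#' which keeps adjusted p values exactly reproducible run to run. Unequal
#' group sizes use the exact correlation structure.
#'
#' @param q non-negative quantile.
#' @param n_control control-group size.
#' @param n_groups integer vector of treatment-group sizes (one per contrast).
#' @param df residual (pooled-variance) degrees of freedom.
#' @return probability between 0 and 1.
#' @export
pdunnett <- function(q, n_control, n_groups, df) {
  stopifnot(q >= 0, n_control >= 1, all(n_groups >= 1), df >= 1)
  if (q == 0) return(0)
  if (!is.finite(q)) return(1)
  ci <- sqrt(1 / n_groups + 1 / n_control)
  sn <- sqrt(n_groups)
  s0 <- sqrt(n_control)
  # conditional on control deviation a and pooled scale u = S/sigma,
  # the contrasts are independent normals
  inner <- function(u) {
    f <- function(a) {
      pr <- stats::dnorm(a * s0) * s0
      for (k in seq_along(n_groups)) {
        w <- q * u * ci[k]
        pr <- pr * (stats::pnorm((a + w) * sn[k]) - stats::pnorm((a - w) * sn[k]))
      }
      pr
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
  }
  # density of U = S/sigma where df * U^2 ~ chi^2_df
  log_cu <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
  outer_f <- function(u) {
    du <- exp(log_cu + (df - 1) * log(u) - df * u^2 / 2)
    vapply(u, inner, numeric(1L)) * du
  }
  p <- stats::integrate(outer_f, 0, Inf, rel.tol = 1e-8, abs.tol = 1e-10)$value
  min(max(p, 0), 1)
}

#' Two-sided Dunnett critical value
#'
#' Solves `P(max |T_i| <= q) = 1 - alpha` for q by root finding on
#' [pdunnett()].
#'
#' @inheritParams pdunnett
#' @param alpha family-wise error rate.
#' @return critical value q.
#' @export
qdunnett <- function(alpha, n_control, n_groups, df) {
  stopifnot(alpha > 0, alpha < 1)
  stats::uniroot(function(q) pdunnett(q, n_control, n_groups, df) - (1 - alpha),
                 lower = 1e-8, upper = 60, tol = 1e-9)$root
}

#' One-way ANOVA with Dunnett contrasts against a control group
#'
#' Fits the usual one-way ANOVA (pooled within-group variance) and tests
#' every non-control group against the control with two-sided Dunnett-
#' adjusted p values, `p_i = 1 - P(max_j |T_j| <= |t_i|)` under the joint
#' null distribution of the whole family. Significance labels follow the
#' star convention ns / * / ** / *** / **** at adjusted-p cut points
#' 0.033, 0.002, 0.0002 and 0.0001.
#'
#' @param values numeric vector of observations (e.g. per-biological-replicate
#'   dCt values or fold changes).
#' @param groups group label per observation.
#' @param control label of the control group (e.g. the calibrator sample).
#' @param alpha family-wise level used to flag `significant`, default 0.05.
#' @return list with `anova` (data.frame: F, df1, df2, p) and `comparisons`
#'   (data.frame: group, n, mean, diff from control, t, p_adjusted, label,
#'   significant). With exactly two groups the adjusted p reduces to the
#'   ordinary pooled-variance two-sided t-test p.
#' @export
dunnett_vs_control <- function(values, groups, control, alpha = 0.05) {
  groups <- as.character(groups)
  control <- as.character(control)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups) stop("control group not present: ", control)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L))
    stop("every group needs >= 2 replicate values; offending group(s): ",
         paste(names(ns)[ns < 2L], collapse = ", "))
  means <- tapply(values, groups, mean)
  N <- length(values); k <- length(lev)
  df_resid <- N - k
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(ns * (means - mean(values))^2)
  s2 <- ss_within / df_resid
  f_stat <- (ss_between / (k - 1)) / s2
  anova_tab <- data.frame(F = f_stat, df1 = k - 1, df2 = df_resid,
                          p = stats::pf(f_stat, k - 1, df_resid, lower.tail = FALSE))

  trt <- setdiff(lev, control)
  n0 <- ns[[control]]
  ni <- as.numeric(ns[trt])
  diffs <- as.numeric(means[trt] - means[[control]])
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  if (s2 == 0) {
    if (any(diffs != 0)) {
      warning("zero pooled variance with unequal group means; reporting p = 0")
      p_adj <- ifelse(diffs != 0, 0, 1)
      tstat <- ifelse(diffs != 0, Inf * sign(diffs), 0)
    } else {
      p_adj <- rep(1, length(trt))
      tstat <- rep(0, length(trt))
    }
  } else {
    tstat <- diffs / se
    p_adj <- vapply(abs(tstat), function(q)
      1 - pdunnett(q, n_control = n0, n_groups = ni, df = df_resid),
      numeric(1L))
    p_adj <- pmin(pmax(p_adj, 0), 1)
  }
  comparisons <- data.frame(
    group = trt, n = ni, mean = as.numeric(means[trt]), diff = diffs,
    t = tstat, p_adjusted = p_adj,
    label = significance_label(p_adj),
    significant = p_adj < alpha,
    stringsAsFactors = FALSE)
  rownames(comparisons) <- NULL
  list(anova = anova_tab, comparisons = comparisons,
       control = control, alpha = alpha, df = df_resid, pooled_sd = sqrt(s2))
}

#' Star significance labels
#'
#' Pure step function of the adjusted p value at the cut points used in the
#' figures: p < 0.0001 "****", p < 0.0002 "***", p < 0.002 "**",
#' p < 0.033 "*", otherwise "ns".
#'
#' @param p numeric vector of (adjusted) p values between 0 and 1.
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.0001, "****",
         ifelse(p < 0.0002, "***",
         ifelse(p < 0.002, "**",
         ifelse(p < 0.033, "*", "ns"))))
  out[is.na(p)] <- NA_character_
  out
}
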