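doubling_series <- function(base = 20) {
  d <- c(-1, -2, -3)
  data.frame(log10_dilution = d, cq = base - (1 / log10(2)) * d)
}

test_that("standard-curve fit recovers the doubling closed form", {
  fit <- fit_standard_curve(doubling_series())
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(fit$efficiency_pct, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 20, tolerance = 1e-9)
})

test_that("efficiency follows E = (10^(-1/slope) - 1) * 100", {
  # slope -3.6: E = (10^(1/3.6) - 1) * 100, evaluated independently
  s <- data.frame(log10_dilution = c(-1, -2, -3), cq = 23.6 + 3.6 * (-c(-1, -2, -3) - 1))
  fit <- fit_standard_curve(s)
  expect_equal(fit$slope, -3.6, tolerance = 1e-9)
  expect_equal(fit$efficiency_pct, (10^(1 / 3.6) - 1) * 100, tolerance = 1e-9)
  expect_equal(round(fit$efficiency_pct, 2), 89.57)
  # slope -1/log10(k) maps to (k - 1) * 100 for any per-cycle gain k
  for (k in c(2, 1.9, 2.1)) {
    d <- c(-1, -2, -3, -4)
    f <- fit_standard_curve(data.frame(log10_dilution = d, cq = 25 - d / log10(k)))
    expect_equal(f$efficiency_pct, (k - 1) * 100, tolerance = 1e-9)
  }
})

test_that("plate-wide Cq shifts move the intercept only", {
  set.seed(4)
  d <- c(-1, -2, -3)
  s <- data.frame(log10_dilution = d, cq = 20 - 3.4 * d + rnorm(3, 0, 0.1))
  f1 <- fit_standard_curve(s)
  s$cq <- s$cq + 5
  f2 <- fit_standard_curve(s)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$efficiency_pct, f1$efficiency_pct)
  expect_equal(f2$intercept, f1$intercept + 5)
})

test_that("curve fitting rejects degenerate series", {
  expect_error(fit_standard_curve(data.frame(log10_dilution = c(-1, -2), cq = c(1, 2))),
               "at least 3")
  expect_error(fit_standard_curve(data.frame(log10_dilution = rep(-1, 3), cq = 1:3)),
               "identical")
})

test_that("QC applies the printed bounds: R2 > 0.980, 90 <= E <= 110", {
  pass <- list(gene_id = "g", slope = -1 / log10(2), intercept = 20,
               r_squared = 0.999, efficiency_pct = 100)
  class(pass) <- "standard_curve_fit"
  expect_true(qc_standard_curve(pass)$pass)

  low_e <- pass; low_e$efficiency_pct <- (10^(1 / 3.6) - 1) * 100  # 89.57
  qc <- qc_standard_curve(low_e)
  expect_false(qc$pass)
  expect_match(qc$reasons, "efficiency", all = FALSE)

  low_r2 <- pass; low_r2$r_squared <- 0.975
  qc <- qc_standard_curve(low_r2)
  expect_false(qc$pass)
  expect_match(qc$reasons, "R squared", all = FALSE)

  high_e <- pass; high_e$efficiency_pct <- 115
  expect_match(qc_standard_curve(high_e)$reasons, "above", all = FALSE)
  # boundary: inclusive on E
  edge <- pass; edge$efficiency_pct <- 90
  expect_true(qc_standard_curve(edge)$pass)
})

test_that("per-gene curve table round-trips through CSV and flags failures", {
  df <- rbind(cbind(gene = "GOOD", doubling_series()),
              cbind(gene = "BAD",
                    data.frame(log10_dilution = c(-1, -2, -3), cq = c(23.6, 27.2, 30.8))))
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  res <- fit_standard_curves(read_standard_curves(p))
  expect_identical(res$pass, c(FALSE, TRUE))  # split() sorts: BAD, GOOD
  expect_match(res$reasons[res$gene == "BAD"], "below 90")
})

test_that("technical replicates average per (sample, gene, bio rep)", {
  cq <- data.frame(sample = "s1",
                   gene = rep(c("g", "ref"), each = 3),
                   role = rep(c("target", "reference"), each = 3),
                   bio_rep = 1, tech_rep = 1:3,
                   cq = c(20.0, 20.2, 20.4, 18, 18, 18))
  agg <- aggregate_technical(cq)
  expect_equal(agg$cq[agg$gene == "g"], 20.2)
  expect_identical(agg$n_tech, c(3L, 3L))
  # single technical replicate passes through unchanged
  one <- cq[c(1, 4), ]
  expect_equal(aggregate_technical(one)$cq[1], 20.0)
})

test_that("aggregation matches a loop oracle on a full synthetic design", {
  sim <- simulate_plate(target_folds = list(
    A = c(pistil_st11 = 2, pistil_st12 = 0.5, anther_st12 = 1,
          pistil_st14 = 4, silique_st17 = 1),
    B = c(pistil_st11 = 1, pistil_st12 = 1, anther_st12 = 1,
          pistil_st14 = 0.25, silique_st17 = 8),
    C = c(pistil_st11 = 3, pistil_st12 = 3, anther_st12 = 1,
          pistil_st14 = 1, silique_st17 = 1),
    D = c(pistil_st11 = 1, pistil_st12 = 2, anther_st12 = 1,
          pistil_st14 = 1, silique_st17 = 0.5)),
    cq_noise_sd = 0.2, bio_noise_sd = 0.4, seed = 19)
  agg <- aggregate_technical(sim$cq)
  orc <- oracle_tech_means(sim$cq)
  key <- function(d) paste(d$sample, d$gene, d$bio_rep)
  expect_setequal(key(agg), key(orc))
  expect_equal(agg$cq[match(key(orc), key(agg))], orc$cq)
})

test_that("Cq table validation catches structural defects", {
  cq <- data.frame(sample = "s1", gene = c("g", "r"), role = c("target", "reference"),
                   bio_rep = 1, tech_rep = 1, cq = c(20, 21))
  expect_silent(validate_cq_table(cq))
  dup <- rbind(cq, cq[1, ])
  expect_error(validate_cq_table(dup), "duplicate well")
  norole <- cq; norole$role <- c("target", "housekeeper")
  expect_error(validate_cq_table(norole), "role")
  noref <- cq; noref$role <- c("target", "target")
  expect_error(validate_cq_table(noref), "no reference")
  neg <- cq; neg$cq[1] <- -2
  expect_error(validate_cq_table(neg), "positive")
})

test_that("ddCt inverts powers-of-two arithmetic exactly", {
  # sample: Cq_target 24, refs at 20; calibrator: Cq_target 26, refs at 20
  cq <- expand.grid(sample = c("cal", "s"), gene = c("T", "R1", "R2", "R3"),
                    bio_rep = 1:2, tech_rep = 1, stringsAsFactors = FALSE)
  cq$role <- ifelse(cq$gene == "T", "target", "reference")
  cq$cq <- ifelse(cq$gene == "T", ifelse(cq$sample == "cal", 26, 24), 20)
  rel <- delta_delta_ct(aggregate_technical(cq), "T", "cal")
  ps <- rel$per_sample
  expect_equal(ps$mean_fold[ps$sample == "s"], 4.0)   # ddCt = -2
  expect_equal(ps$mean_fold[ps$sample == "cal"], 1.0) # calibrator vs itself
  expect_equal(ps$sem_fold, c(0, 0))
})

test_that("ddCt is invariant to per-bio-rep plate-wide Cq offsets", {
  sim <- simulate_plate(target_folds = list(
    A = c(pistil_st11 = 0.25, pistil_st12 = 0.5, anther_st12 = 1,
          pistil_st14 = 2, silique_st17 = 4)),
    cq_noise_sd = 0.07, bio_noise_sd = 0, seed = 5)
  base <- delta_delta_ct(aggregate_technical(sim$cq), "A", "anther_st12")
  shifted <- sim$cq
  # add a distinct constant to every well of each (sample, bio rep) plate
  off <- (match(shifted$sample, unique(shifted$sample)) * 10 + shifted$bio_rep) / 3
  shifted$cq <- shifted$cq + off
  res <- delta_delta_ct(aggregate_technical(shifted), "A", "anther_st12")
  expect_equal(res$per_rep$fold, base$per_rep$fold, tolerance = 1e-12)
})

test_that("reference-gene order does not matter", {
  sim <- simulate_plate(target_folds = list(
    A = c(pistil_st11 = 0.5, pistil_st12 = 2, anther_st12 = 1,
          pistil_st14 = 1, silique_st17 = 3)),
    cq_noise_sd = 0.1, bio_noise_sd = 0.3, seed = 21)
  agg <- aggregate_technical(sim$cq)
  r1 <- delta_delta_ct(agg, "A", "anther_st12", refs = c("RCE1", "TUA2", "YLS8"))
  r2 <- delta_delta_ct(agg, "A", "anther_st12", refs = c("YLS8", "RCE1", "TUA2"))
  expect_equal(r1$per_sample, r2$per_sample)
})

test_that("missing reference measurements are reported by cell", {
  cq <- expand.grid(sample = c("cal", "s"), gene = c("T", "R1"),
                    bio_rep = 1:2, tech_rep = 1, stringsAsFactors = FALSE)
  cq$role <- ifelse(cq$gene == "T", "target", "reference")
  cq$cq <- 20
  broken <- cq[!(cq$sample == "s" & cq$gene == "R1" & cq$bio_rep == 2), ]
  expect_error(delta_delta_ct(aggregate_technical(broken), "T", "cal"),
               "missing reference.*R1")
})

test_that("noisy plate estimate lands in the Monte-Carlo band for fold 0.25", {
  sim <- simulate_plate(target_folds = list(
    A = c(pistil_st11 = 0.25, pistil_st12 = 1, anther_st12 = 1,
          pistil_st14 = 1, silique_st17 = 1)),
    cq_noise_sd = 0.1, bio_noise_sd = 0, n_bio = 3, n_tech = 3, seed = 7)
  rel <- delta_delta_ct(aggregate_technical(sim$cq), "A", "anther_st12")
  est <- rel$per_sample$mean_fold[rel$per_sample$sample == "pistil_st11"]
  expect_gte(est, 0.20)
  expect_lte(est, 0.31)
})

test_that("quantify_expression assembles folds, adjusted p and labels", {
  sim <- simulate_plate(target_folds = list(
    A = c(pistil_st11 = 0.25, pistil_st12 = 0.5, anther_st12 = 1,
          pistil_st14 = 2, silique_st17 = 4)),
    cq_noise_sd = 0.1, bio_noise_sd = 0.5, seed = 7)
  res <- quantify_expression(sim$cq, "A", "anther_st12")
  expect_identical(nrow(res), 5L)
  expect_true(is.na(res$p_adjusted[res$sample == "anther_st12"]))
  others <- res[res$sample != "anther_st12", ]
  expect_true(all(others$p_adjusted >= 0 & others$p_adjusted <= 1))
  expect_identical(others$label, significance_label(others$p_adjusted))
  an <- attr(res, "anova")
  expect_equal(an$df1, 4); expect_equal(an$df2, 10)
  # the two testing scales exist and differ in general
  res_f <- quantify_expression(sim$cq, "A", "anther_st12", test_on = "fold")
  expect_false(identical(res$p_adjusted, res_f$p_adjusted))
})
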