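---
title: "Profile-distance co-expression ranking and qPCR relative quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-distance co-expression ranking and qPCR relative quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprofiler)
```

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## Co-expression by profile distance

### The model

A tissue atlas is a gene × sample matrix of TPM values. Absolute TPM levels
span orders of magnitude between genes, so patterns are compared after
per-gene mean normalization:

$$z_g(s) = \frac{x_g(s) - m_g}{m_g}, \qquad m_g = \frac{1}{|S|}\sum_{s \in S} x_g(s),$$

over the selected sample set $S$. Two algebraic identities follow and are
enforced as tests: every profile sums to zero ($\sum_s z_g(s) = 0$), and the
profile is invariant to multiplying the gene's whole TPM row by any $c > 0$.
Each value is bounded below by $-1$ (expression cannot be negative).
Genes with $m_g = 0$ carry no profile and are removed first; because TPM is
non-negative, $m_g = 0$ exactly when every value is zero, so this filter is
exact and needs no tolerance.

Similarity to a query gene $q$ is the L1 distance between profiles,

$$\Delta\mathrm{sum}(g, q) = \sum_{s \in S} \lvert z_g(s) - z_q(s)\rvert,$$

a metric (non-negative, symmetric, triangle inequality — property-tested on
random triples). Ranking ascends in $\Delta\mathrm{sum}$; the query itself
scores exactly 0 and is always listed first. The L1 form makes the
statistic robust to a single discrepant tissue relative to squared-error
alternatives, and no secondary similarity measure (correlation etc.) is
offered: the distance is the statistic.

### Tie-breaking and numerics

Equal distances are ordered lexicographically by gene identifier — the
choice is arbitrary but deterministic, which testing requires. The query is
pinned first even when other genes (e.g. exact scaled copies) also sit at
distance 0. Distances accumulate in double precision with straightforward
summation; profiles here have at most ~100 entries, so compensated
summation would be noise-level pedantry.

### The sample scope of the mean

When ranking is restricted to a sample subset (say, reproductive tissues of
a larger atlas), the mean could be taken either over the full atlas or over
the subset. Both readings are defensible; `coexpression_ranking()` exposes
the choice as `mean_scope` with default `"subset"` — means, the zero filter
and the normalization are computed on the samples present at call time, so
each operation is self-contained. Under `"full"`, profiles are normalized
on the full matrix and sliced afterwards; they then no longer sum to zero
over the retained samples, which is expected, not a bug. The same switch
also answers whether a developmental series and organ samples should be
pooled for the mean: pool them in one matrix or subset them, as the
question demands.

### How many co-expressed genes to inspect

`top_k` truncates the ranking for reporting. No default is imposed: the
biologically meaningful cut depends on the query and is the user's call;
the full ranking is always computable.

## qPCR relative quantification

### Standard-curve QC

Per primer pair, Cq is regressed on $\log_{10}$ dilution over a tenfold
series (at least three points). Efficiency derives from the slope by
$E = (10^{-1/\mathrm{slope}} - 1) \times 100\,\%$; a slope of
$-1/\log_{10} 2 \approx -3.32$ is perfect doubling ($E = 100\,\%$). A
primer pair passes QC iff $R^2 > 0.980$ and $90\,\% \le E \le 110\,\%$
(strict on $R^2$, inclusive on $E$; boundary values pass on $E$). $E$ is a
QC gate only: quantification uses the literal 2 of $2^{-\Delta\Delta Ct}$,
and an efficiency-corrected mode is deliberately not offered — mixing
per-primer efficiencies into the fold formula changes the estimand and is
out of scope for this version.

### Replicate flow

The canonical design is 5 tissue samples × 3 biological × 3 technical
replicates, with 3 reference genes. Technical replicates (same cDNA,
repeated wells) are averaged to one Cq per biological replicate *before*
any quantity is formed; biological replicates are carried through
separately so that error bars measure biology:

1. $\Delta Ct(s, b) = Cq_{\mathrm{target}}(s, b) - \overline{Cq}_{\mathrm{refs}}(s, b)$,
   where the reference summary is the arithmetic mean of the reference-gene
   Cqs — on the log scale this is the geometric mean of reference
   quantities, the standard multi-reference reading of the method.
2. $\Delta\Delta Ct(s, b) = \Delta Ct(s, b) - \overline{\Delta Ct}_{\mathrm{cal}}$,
   with the calibrator's per-replicate $\Delta Ct$ values averaged to one
   constant. Replicates are not paired across tissues (biological replicate
   2 of a pistil has no relation to replicate 2 of an anther), so a per-rep
   pairing would be arbitrary; averaging is the defensible aggregate. The
   calibrator's own mean fold is 1 in expectation, exactly 1 when noise is
   absent.
3. $\mathrm{fold}(s, b) = 2^{-\Delta\Delta Ct(s, b)}$; per sample, mean and
   SEM ($\mathrm{sd}/\sqrt{n_{\mathrm{bio}}}$) over biological replicates.

Any Cq offset shared by target and references within one (sample,
biological replicate) — a pipetting or cDNA-input effect — cancels exactly
in step 1; this shift invariance is tested end to end.

### Testing scale

ANOVA + Dunnett runs by default on the per-replicate $\Delta Ct$ values
(`test_on = "dct"`): fold changes are log-normal-ish and
variance-heterogeneous, while $\Delta Ct$ is the log2 quantity the
measurement actually produces. `test_on = "fold"` exposes the linear-scale
alternative, since common statistics packages accept either and the choice
is rarely reported. The star labels (ns, \*, \*\*, \*\*\*, \*\*\*\*) are a
pure step function of the *adjusted* p at 0.033, 0.002, 0.0002, 0.0001 —
the thresholds follow a widespread graphing-software convention; applying
them to adjusted rather than raw p is an assumption, documented here.

### Dunnett computation

The two-sided Dunnett-adjusted p for contrast $i$ is
$1 - P(\max_j |T_j| \le |t_i|)$ under the joint null of the family
$T_j = (\bar y_j - \bar y_0) / (S\sqrt{1/n_j + 1/n_0})$ with pooled
variance $S^2$ on $N - k$ degrees of freedom. The statistics are correlated
only through the shared control and scale, so conditioning on the control
mean and on $S/\sigma$ makes them independent normals; the probability is a
double integral evaluated by nested adaptive quadrature (inner relative
tolerance 1e-9, outer 1e-8 — comfortably below the 1e-6 accuracy the
adjusted p needs). This is deliberately *not* delegated to a quasi-Monte-
Carlo multivariate-t routine: the quadrature is deterministic, so adjusted
p values are bit-reproducible; the library routine instead serves as an
independent oracle in the test suite (agreement to 1e-5). Unequal group
sizes enter through the exact correlation structure. With a single
contrast the computation reduces to the pooled two-sample t-test
(verified to 1e-6).

Degenerate inputs: a group with fewer than 2 values is an error (no
variance is estimable); zero pooled variance with unequal means yields the
limiting p of 0 with a warning; identical data everywhere yields p = 1 and
"ns".

## The synthetic-data generators

### What they emulate

`simulate_tpm()` emulates a tissue atlas: background genes are independent
log-normals per sample (expression is non-negative and right-skewed);
planted-module genes share an archetype profile times a gene-specific
positive scale, perturbed by multiplicative log-normal noise of sd
`noise_sd` on the natural-log scale; a fixed fraction of genes is
identically zero to exercise the unexpressed filter. Archetype shapes
(peak, decreasing, increasing, flat) mirror qualitative tissue-series
patterns; they are fixtures, not claims about real data. Zeroed genes are
drawn from the background only — planting a module and then silencing part
of it would make module-recovery truth tables incoherent.

`simulate_plate()` emulates the qPCR design on the Cq scale with additive
normal noise (the conventional cycle-scale error model): target Cq is a
base level minus $\log_2$ of the true fold, plus a biological offset shared
with the reference genes of the same (sample, replicate), plus technical
noise per well. Because references share the biological offset, it cancels
in $\Delta Ct$ — setting `bio_noise_sd` large with zero technical noise
recovers folds exactly, an end-to-end demonstration of the shift
invariance.

Defaults state the emulated world once: 5 tissue samples (pistil stages
11/12/14, anther stage 12, silique stage 17), calibrator anther stage 12,
3 biological × 3 technical replicates, three reference genes at
22–24 cycles, target base 26 cycles, technical noise 0.1 cycles.

### What they do not emulate

Real RNA-seq matrices have correlated backgrounds (co-regulation is
pervasive, not confined to one planted module), compositional TPM coupling
across genes, and count noise at low expression; real plates have
between-run effects, occasional dropouts, and reference genes that are only
approximately stable. A green recovery test therefore establishes that the
*procedure* inverts its own stated generative model — correctness of the
implementation, not performance on any real atlas. Conversely the
generators are first-class, seeded, and byte-reproducible, so every
pipeline claim is checkable without downloads.

## Known limitations

- Reproducing a specific published co-expression list requires the
  corresponding public expression matrix; with one supplied as TSV,
  `exprofiler rank` computes the ranking directly, but no such matrix ships
  with the package.
- No efficiency-corrected quantification, absolute quantification, melt
  analysis, or inter-run calibration.
- The ranking is a nearest-neighbor list, not a network: no clustering or
  enrichment is layered on top, by design.
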