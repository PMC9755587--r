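# Independent brute-force oracles: element-wise loops, no shared code with
# the implementation under test.

oracle_row_means <- function(x) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- 0
    for (j in seq_len(ncol(x))) s <- s + x[i, j]
    out[i] <- s / ncol(x)
  }
  names(out) <- rownames(x)
  out
}

oracle_delta_sum <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + abs(a[[j]] - b[[j]])
  s
}

oracle_normalize <- function(x) {
  z <- x
  for (i in seq_len(nrow(x))) {
    m <- sum(x[i, ]) / ncol(x)
    for (j in seq_len(ncol(x))) z[i, j] <- (x[i, j] - m) / m
  }
  z
}

# full all-pairs ranking for a query; same tie rule (dsum, then gene id,
# query pinned first) applied to independently computed distances
oracle_ranking <- function(z, query) {
  ids <- rownames(z)
  d <- vapply(ids, function(g) oracle_delta_sum(z[g, ], z[query, ]), numeric(1))
  ord <- order(d, ids, method = "radix")
  ids <- ids[ord]; d <- d[ord]
  qi <- match(query, ids)
  if (qi != 1) { ids <- c(query, ids[-qi]); d <- c(0, d[-qi]) }
  data.frame(gene_id = ids, dsum = unname(d), stringsAsFactors = FALSE)
}

oracle_tech_means <- function(cq) {
  keys <- unique(cq[, c("sample", "gene", "bio_rep")])
  keys$cq <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- cq$sample == keys$sample[i] & cq$gene == keys$gene[i] &
      cq$bio_rep == keys$bio_rep[i]
    keys$cq[i] <- mean(cq$cq[sel])
  }
  keys
}

random_tpm_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, 1, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}
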