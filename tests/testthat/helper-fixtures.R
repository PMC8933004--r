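library(data.table)

# Small simulated dataset shared across tests; regenerated in code, nothing
# stored on disk.
make_toy_data <- function(n_cpgs = 300, n_genes = 30, n_samples = 120,
                          seed = 42, effect_spec = list()) {
  ann <- generate_annotation(n_cpgs, n_genes, c("1" = 10e6), seed = seed)
  covars <- generate_covariates(n_samples, seed = seed + 1)
  omics <- generate_omics(ann$cpgs, ann$genes, covars, effect_spec,
                          seed = seed + 2)
  pairs <- pair_cis(ann$cpgs, ann$genes)
  list(ann = ann, covars = covars, omics = omics, pairs = pairs)
}

# Brute-force cis pairing: double loop over all CpG x gene combinations.
brute_force_pairs <- function(cpgs, genes, window_bp = 5e5, strict = FALSE) {
  res <- list()
  for (i in seq_len(nrow(cpgs))) {
    for (j in seq_len(nrow(genes))) {
      if (cpgs$chrom[i] != genes$chrom[j]) next
      if (!(cpgs$chrom[i] %in% as.character(1:22))) next
      t <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j]
      d <- if (genes$strand[j] == "+") cpgs$pos[i] - t else t - cpgs$pos[i]
      inside <- if (strict) abs(d) < window_bp else abs(d) <= window_bp
      if (inside) {
        res[[length(res) + 1]] <- data.table(cpg_id = cpgs$cpg_id[i],
                                             gene_id = genes$gene_id[j],
                                             signed_dist = as.integer(d))
      }
    }
  }
  out <- rbindlist(res)
  if (nrow(out)) setorder(out, cpg_id, gene_id)
  out
}

# Independent OLS oracle: normal-equations solve, two-sided t on the first
# coefficient.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  t <- b / se
  list(beta = b[, 1], se = se, t = t[, 1],
       p = 2 * pt(abs(t[, 1]), df, lower.tail = FALSE))
}
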