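test_that("annotation generation validates input and is deterministic", {
  expect_error(generate_annotation(0, 10), "positive")
  expect_error(generate_annotation(10, 0), "positive")
  expect_error(generate_annotation(10, 5, c("1" = 8e5), window_bp = 5e5),
               "smaller than 2x")
  expect_error(generate_annotation(10, 5, c(X = 5e6)), "autosome")

  a1 <- generate_annotation(200, 20, c("1" = 10e6), seed = 1)
  a2 <- generate_annotation(200, 20, c("1" = 10e6), seed = 1)
  expect_identical(a1, a2)
  a3 <- generate_annotation(200, 20, c("1" = 10e6), seed = 2)
  expect_false(identical(a1$cpgs$pos, a3$cpgs$pos))

  expect_true(all(a1$cpgs$pos >= 1 & a1$cpgs$pos <= 10e6))
  expect_true(all(a1$genes$start <= a1$genes$end))
  expect_setequal(unique(a1$genes$strand), c("+", "-"))
  expect_false(anyDuplicated(a1$cpgs$cpg_id) > 0)
})

test_that("every gene acquires cis CpGs at realistic densities", {
  ann <- generate_annotation(1000, 50, c("1" = 10e6), seed = 7)
  # brute-force scan: count CpGs within 500 kb of each TSS
  t <- tss(ann$genes)
  n_cis <- vapply(seq_len(50), function(j)
    sum(abs(ann$cpgs$pos - t[j]) <= 5e5), integer(1))
  expect_true(all(n_cis >= 1))
})

test_that("omics generation is deterministic, bounded, and records truth", {
  d <- make_toy_data(seed = 11)
  expect_true(all(d$omics$meth >= 0 & d$omics$meth <= 1))
  expect_false(anyNA(d$omics$meth))
  expect_false(anyNA(d$omics$expr))
  d2 <- make_toy_data(seed = 11)
  expect_identical(d$omics, d2$omics)

  # every planted pair lies inside the cis window used at generation
  planted <- d$omics$truth[mechanism != "null"]
  expect_true(nrow(planted) > 0)
  expect_true(all(abs(planted$signed_dist) <= 5e5))

  # no planted effects -> truth has only null rows
  om0 <- generate_omics(d$ann$cpgs, d$ann$genes, d$covars,
                        list(n_true_pairs = 0), seed = 3)
  expect_true(all(om0$truth$mechanism == "null"))
  expect_true(all(om0$truth$true_beta == 0))

  expect_error(generate_omics(d$ann$cpgs, d$ann$genes, d$covars,
                              list(n_true_pairs = 1e6), seed = 3),
               "true pairs")
})

test_that("noiseless expression is exactly linear in planted methylation", {
  ann <- generate_annotation(50, 5, c("1" = 5e6), seed = 5)
  covars <- generate_covariates(40, seed = 5)
  om <- generate_omics(ann$cpgs, ann$genes, covars,
                       list(n_true_pairs = 1, beta_range = c(1, 1),
                            sign_mix = 1, noise_sd = 0,
                            confound_expr = 0),
                       seed = 5)
  pl <- om$truth[mechanism == "direct"]
  expect_equal(nrow(pl), 1)
  y <- om$expr[pl$gene_id, ]
  x <- om$meth[pl$cpg_id, ]
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)["x"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("planted effect sizes are recovered by OLS within 3 SE", {
  ann <- generate_annotation(100, 10, c("1" = 8e6), seed = 9)
  covars <- generate_covariates(300, seed = 9)
  om <- generate_omics(ann$cpgs, ann$genes, covars,
                       list(n_true_pairs = 5, beta_range = c(2, 2),
                            noise_sd = 0.5),
                       seed = 9)
  planted <- om$truth[mechanism == "direct"]
  for (r in seq_len(nrow(planted))) {
    f <- fit_pair(om$meth[planted$cpg_id[r], ], om$expr[planted$gene_id[r], ],
                  covars)
    expect_lt(abs(f$beta - planted$true_beta[r]), 3 * f$se)
  }
})

test_that("genotype chains shift methylation and propagate to expression", {
  ann <- generate_annotation(100, 10, c("1" = 8e6), seed = 13)
  covars <- generate_covariates(400, seed = 13)
  om <- generate_omics(ann$cpgs, ann$genes, covars,
                       list(n_true_pairs = 6, beta_range = c(1, 2),
                            sign_mix = 0, noise_sd = 0.1),
                       seed = 13)
  expect_error(generate_genotypes(om, ann$cpgs,
                                  list(maf_range = c(0, 0.5)), seed = 1),
               "maf_range")
  expect_error(generate_genotypes(om, ann$cpgs,
                                  list(n_chains = 100), seed = 1),
               "chains")

  g <- generate_genotypes(om, ann$cpgs,
                          list(n_chains = 3, snp_effect_on_meth = 1,
                               n_null_snps = 5), seed = 13)
  chains <- g$truth[mechanism == "snp_driven"]
  expect_equal(nrow(chains), 3)
  for (r in seq_len(nrow(chains))) {
    dos <- g$geno$dosage[chains$snp_id[r], ]
    # positive SNP->CpG effect and negative CpG->gene effect (sign_mix=0):
    # SNP->CpG slope positive, SNP->gene slope negative
    m_slope <- coef(lm(g$meth[chains$cpg_id[r], ] ~ dos))[2]
    e_slope <- coef(lm(g$expr[chains$gene_id[r], ] ~ dos))[2]
    expect_gt(m_slope, 0)
    expect_lt(e_slope, 0)
    expect_equal(sign(m_slope) * sign(chains$true_beta[r]), sign(e_slope))
  }

  # zero SNP effect leaves omics untouched
  g0 <- generate_genotypes(om, ann$cpgs,
                           list(n_chains = 3, snp_effect_on_meth = 0,
                                n_null_snps = 5), seed = 13)
  expect_equal(g0$meth, om$meth)
  expect_equal(g0$expr, om$expr)
})

test_that("simulated CpG metadata carries the requested eCpG tilt", {
  ann <- generate_annotation(4000, 20, c("1" = 20e6), seed = 17)
  e <- rep(c(TRUE, FALSE), c(1000, 3000))
  meta <- simulate_cpg_metadata(ann$cpgs, e, shift = 1.5, seed = 17)
  expect_true(all(meta$icc >= 0 & meta$icc <= 1))
  expect_gt(median(meta$icc[e]), median(meta$icc[!e]))
  expect_gt(mean(meta$state_Enh[e]), mean(meta$state_Enh[!e]))
  expect_lt(mean(meta$state_Quies[e]), mean(meta$state_Quies[!e]))
})

test_that("CpG symbol maps annotate CpGs inside gene bodies and promoters", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = c("1", "1"),
    start = c(1000L, 50000L), end = c(2000L, 60000L),
    strand = c("+", "-"), symbol = c("A", "B"))
  cpgs <- data.table::data.table(
    cpg_id = c("c_in_body", "c_in_prom", "c_far", "c_minus_prom"),
    chrom = "1", pos = c(1500L, 900L, 30000L, 61000L))
  m <- cpg_symbol_map(cpgs, genes, promoter_bp = 1500)
  expect_equal(m[["c_in_body"]], "A")
  expect_equal(m[["c_in_prom"]], "A")   # within 1500 bp upstream of + TSS
  expect_equal(m[["c_far"]], character(0))
  expect_equal(m[["c_minus_prom"]], "B")  # upstream of - strand TSS (end)
})
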