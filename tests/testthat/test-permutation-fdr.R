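test_that("expression permutation is deterministic, label-preserving, and reserved at 0", {
  d <- make_toy_data(n_cpgs = 20, n_genes = 5, n_samples = 50, seed = 61)
  e <- d$omics$expr
  expect_identical(permute_expression(e, 0, 99), e)
  p1 <- permute_expression(e, 1, 99)
  p1b <- permute_expression(e, 1, 99)
  expect_identical(p1, p1b)
  p2 <- permute_expression(e, 2, 99)
  expect_false(identical(p1, p2))
  # same permutation applied to all genes: row sets of values preserved
  expect_equal(sort(unname(p1[1, ])), sort(unname(e[1, ])))
  expect_equal(rowSums(p1), rowSums(e))
  expect_identical(colnames(p1), colnames(e))
  expect_error(permute_expression(e, -1, 99), ">= 0")
})

test_that("per-CpG minimum p matches a brute-force group-by", {
  set.seed(71)
  assoc <- data.table::data.table(
    cpg_id = sample(sprintf("cg%02d", 1:50), 400, replace = TRUE),
    log_p = log(runif(400)))
  mp <- min_p_per_cpg(assoc)
  brute <- tapply(exp(assoc$log_p), assoc$cpg_id, min)
  expect_equal(mp$min_p, as.numeric(brute[mp$cpg_id]), tolerance = 1e-12)
  # simple cases
  one <- min_p_per_cpg(data.table::data.table(cpg_id = "a", log_p = log(0.3)))
  expect_equal(one$min_p, 0.3)
  three <- min_p_per_cpg(data.table::data.table(
    cpg_id = "a", log_p = log(c(0.5, 0.01, 0.2))))
  expect_equal(three$min_p, 0.01)
})

test_that("beta MLE recovers the closed-form law of uniform minima", {
  set.seed(81)
  # min of k iid uniforms is Beta(1, k)
  x <- matrix(runif(5000 * 30), 5000)
  mins <- apply(x, 1, min)
  f <- fit_beta_mle(mins)
  expect_true(f$converged)
  expect_lt(abs(f$a - 1) / 1, 0.1)
  expect_lt(abs(f$b - 30) / 30, 0.1)

  # iid uniforms themselves are Beta(1, 1)
  f1 <- fit_beta_mle(runif(5000))
  expect_lt(abs(f1$a - 1), 0.1)
  expect_lt(abs(f1$b - 1), 0.1)

  # the optimized likelihood is no worse than at the moment estimates
  y <- rbeta(2000, 2.5, 7)
  fy <- fit_beta_mle(y)
  m <- mean(y); v <- var(y)
  cm <- m * (1 - m) / v - 1
  ll_mom <- sum(dbeta(pmin(pmax(y, 1e-300), 1 - 1e-12),
                      m * cm, (1 - m) * cm, log = TRUE))
  expect_gte(fy$loglik, ll_mom - 1e-6)

  expect_error(fit_beta_mle(runif(5)), "at least 20")
  degen <- fit_beta_mle(rep(0.5, 100))
  expect_false(degen$converged)
})

test_that("vectorized beta fits agree with the scalar optimizer", {
  set.seed(83)
  k <- sample(5:50, 30, replace = TRUE)
  m <- t(vapply(k, function(ki) rbeta(200, 1, ki), numeric(200)))
  rownames(m) <- sprintf("cg%02d", seq_len(nrow(m)))
  fits <- fit_beta_rows(m)
  expect_true(all(fits$converged))
  for (i in c(1, 10, 25)) {
    f <- fit_beta_mle(m[i, ])
    expect_equal(fits$a[i], f$a, tolerance = 1e-4)
    expect_equal(fits$b[i], f$b, tolerance = 1e-4)
  }
})

test_that("empirical p is the beta CDF with a rank fallback", {
  f11 <- structure(list(a = 1, b = 1, converged = TRUE), class = "beta_fit")
  expect_equal(empirical_p(0.3, f11), 0.3)
  expect_equal(empirical_p(1, f11), 1)
  f12 <- structure(list(a = 1, b = 2, converged = TRUE), class = "beta_fit")
  expect_equal(empirical_p(0.1, f12), 1 - (1 - 0.1)^2)
  bad <- structure(list(converged = FALSE), class = "beta_fit")
  expect_error(empirical_p(0.1, bad), "rank fallback")
  expect_equal(empirical_p(0.1, bad, min_p_perm = c(0.05, 0.2, 0.5)),
               (1 + 1) / (3 + 1))
})

test_that("BH selection and the genome-wide threshold follow the bracketing rule", {
  pe <- data.table::data.table(cpg_id = c("a", "b", "c", "d"),
                               p_emp = c(0.001, 0.002, 0.9, 0.95))
  # hand BH: sorted p = .001 .002 .9 .95; thresholds .0125 .025 .0375 .05
  sel <- bh_select(pe, alpha = 0.05)
  expect_setequal(sel$significant, c("a", "b"))
  expect_equal(sel$p_emp_genomewide, (0.002 + 0.9) / 2)
  sel2 <- bh_select(pe, alpha = 0.05, rule = "largest_significant")
  expect_equal(sel2$p_emp_genomewide, 0.002)

  none <- bh_select(data.table::data.table(cpg_id = letters[1:4],
                                           p_emp = rep(1, 4)))
  expect_length(none$significant, 0)
  expect_true(is.na(none$p_emp_genomewide))

  # uniform empirical p-values yield (almost) no discoveries
  set.seed(91)
  hits <- replicate(20, {
    u <- data.table::data.table(cpg_id = sprintf("c%04d", 1:1000),
                                p_emp = runif(1000))
    length(bh_select(u)$significant)
  })
  expect_lt(mean(hits), 1)
})

test_that("nominal thresholds invert the beta CDF and are monotone", {
  f11 <- structure(list(a = 1, b = 1, converged = TRUE), class = "beta_fit")
  expect_equal(nominal_threshold(f11, 0.05), 0.05)
  f12 <- structure(list(a = 1, b = 2, converged = TRUE), class = "beta_fit")
  expect_equal(nominal_threshold(f12, 0.19), 0.1)
  expect_gt(nominal_threshold(f12, 0.3), nominal_threshold(f12, 0.19))
})

test_that("eQTM calling is hierarchical and assigns directions", {
  assoc <- data.table::data.table(
    cpg_id = c("a", "a", "b", "c"),
    gene_id = c("g1", "g2", "g3", "g4"),
    signed_dist = c(10L, -20L, 5L, 0L),
    beta = c(-1, 0.5, 2, -3),
    se = 0.1, tstat = 1,
    p = c(0.0005, 0.01, 1e-9, 1e-12),
    log_p = log(c(0.0005, 0.01, 1e-9, 1e-12)))
  thresholds <- list(nominal = data.table::data.table(
    cpg_id = c("a", "b"), nominal_p = c(0.001, 1e-6)))
  rec <- call_eqtms(assoc, thresholds)
  # CpG a: only the p=0.0005 pair passes; CpG b passes; CpG c is not an
  # eCpG so its p=1e-12 pair contributes nothing
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$cpg_id, c("a", "b"))
  expect_equal(rec[cpg_id == "a", direction], "inverse")
  expect_equal(rec[cpg_id == "b", direction], "positive")
  expect_equal(rec[cpg_id == "a", log2fc_per_10pct], -0.1)
})

test_that("discovery respects hierarchy and the beta null approximates ranks", {
  d <- make_toy_data(n_cpgs = 250, n_genes = 25, n_samples = 120, seed = 95,
                     effect_spec = list(prop_true_cpgs = 0.15))
  disc <- eqtm_discover(d$pairs, d$omics$meth, d$omics$expr, d$covars,
                        n_perm = 200, seed = 95)
  # hierarchical containment
  expect_true(all(disc$eqtms$cpg_id %in% disc$bh$significant))
  # every eQTM's pair p is below its CpG's nominal threshold
  nom <- disc$thresholds$nominal
  merged <- disc$eqtms[nom, on = "cpg_id", nomatch = NULL]
  expect_true(all(merged$p < merged$nominal_p))
  # beta-based empirical p tracks the direct rank-based one
  fits <- disc$beta_fits
  rank_p <- vapply(seq_len(nrow(fits)), function(i) {
    row <- disc$null_minp[fits$cpg_id[i], ]
    (sum(row <= fits$min_p[i]) + 1) / (length(row) + 1)
  }, numeric(1))
  mid <- fits$p_emp > 0.005 & fits$p_emp < 0.995
  rho <- cor(fits$p_emp[mid], rank_p[mid], method = "spearman")
  expect_gt(rho, 0.99)
})

test_that("discovery is deterministic under a fixed seed", {
  d <- make_toy_data(n_cpgs = 80, n_genes = 10, n_samples = 60, seed = 97)
  d1 <- eqtm_discover(d$pairs, d$omics$meth, d$omics$expr, d$covars,
                      n_perm = 20, seed = 5)
  d2 <- eqtm_discover(d$pairs, d$omics$meth, d$omics$expr, d$covars,
                      n_perm = 20, seed = 5)
  expect_identical(d1$eqtms, d2$eqtms)
  expect_identical(d1$null_minp, d2$null_minp)
})
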