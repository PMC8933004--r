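#' Permute the sample columns of an expression matrix
#'
#' One random permutation of the sample labels is applied identically to
#' all genes, preserving the gene-gene correlation structure while breaking
#' every methylation-expression and covariate-expression link. Permutation
#' index 0 is reserved for the observed (identity) data and is never used
#' as a null permutation. The permutation is a deterministic function of
#' `(master_seed, perm_index)` so permuted datasets can be regenerated
#' independently and in any order.
#'
#' @param expr_mat genes x samples matrix.
#' @param perm_index integer in `1..n_perm` (0 returns the matrix
#'   unchanged).
#' @param master_seed master integer seed of the discovery run.
#' @return matrix of the same shape with columns permuted; column names
#'   keep the original sample order (the values move, not the labels).
#' @export
permute_expression <- function(expr_mat, perm_index, master_seed) {
  if (perm_index == 0) return(expr_mat)
  if (perm_index < 0) stop_("perm_index must be >= 0")
  set.seed(derive_seed(master_seed, perm_index))
  perm <- sample.int(ncol(expr_mat))
  out <- expr_mat[, perm, drop = FALSE]
  colnames(out) <- colnames(expr_mat)
  out
}

#' Per-CpG minimum p-value over its paired genes
#'
#' The CpG-level test statistic: the smallest association p-value a CpG
#' attains across all genes it is paired with. Computed on the log scale to
#' avoid underflow ties at numeric zero.
#'
#' @param assoc association table from [run_model()] (needs `cpg_id`,
#'   `log_p`).
#' @return `data.table` (cpg_id, min_p, min_log_p); CpGs with no pairs are
#'   simply absent.
#' @export
min_p_per_cpg <- function(assoc) {
  out <- assoc[, .(min_log_p = min(log_p)), by = cpg_id]
  out[, min_p := exp(min_log_p)]
  data.table::setcolorder(out, c("cpg_id", "min_p", "min_log_p"))
  out[]
}

# Negative log-likelihood and analytic gradient of Beta(a, b) in
# (log a, log b) parametrization, given sufficient statistics.
.beta_negll <- function(par, n, slx, sl1x) {
  a <- exp(par[1]); b <- exp(par[2])
  -(n * (lgamma(a + b) - lgamma(a) - lgamma(b)) + (a - 1) * slx + (b - 1) * sl1x)
}
.beta_negll_grad <- function(par, n, slx, sl1x) {
  a <- exp(par[1]); b <- exp(par[2])
  dab <- digamma(a + b)
  ga <- n * (dab - digamma(a)) + slx
  gb <- n * (dab - digamma(b)) + sl1x
  -c(ga * a, gb * b)
}

#' Maximum-likelihood beta-distribution fit
#'
#' Fits Beta(a, b) by maximum likelihood with a method-of-moments start and
#' quasi-Newton optimization on (log a, log b). Used to approximate the
#' permutation null distribution of per-CpG minimum p-values, which for
#' minima of (correlated) uniforms is well described by a beta law. Input
#' values are clamped to `[1e-300, 1 - 1e-12]` before fitting. Degenerate
#' input (all values identical) yields a non-converged fit; downstream
#' consumers then fall back to the rank-based empirical p-value.
#'
#' @param x numeric vector in (0, 1), length >= 20.
#' @return list of class `beta_fit`: `a`, `b`, `loglik`, `converged`.
#' @export
fit_beta_mle <- function(x) {
  if (length(x) < 20) stop_("need at least 20 values to fit a beta null")
  x <- pmin(pmax(x, 1e-300), 1 - 1e-12)
  if (stats::sd(x) == 0) {
    return(structure(list(a = NA_real_, b = NA_real_, loglik = NA_real_,
                          converged = FALSE), class = "beta_fit"))
  }
  m <- mean(x); v <- stats::var(x)
  v <- min(v, m * (1 - m) * 0.999)  # moment start must be feasible
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  n <- length(x); slx <- sum(log(x)); sl1x <- sum(log1p(-x))
  opt <- stats::optim(start, .beta_negll, .beta_negll_grad,
                      n = n, slx = slx, sl1x = sl1x,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  structure(list(a = a, b = b, loglik = -opt$value,
                 converged = opt$convergence == 0 && is.finite(a) && is.finite(b)),
            class = "beta_fit")
}

#' Vectorized beta MLE across the rows of a minimum p-value matrix
#'
#' Fits one Beta(a, b) per row (CpGs x permutations) by damped Newton
#' iteration on (a, b) from method-of-moments starts, run simultaneously
#' for all CpGs; rows that fail to converge are refit with
#' [fit_beta_mle()], and rows with zero variance are flagged
#' non-converged. Agrees with the scalar optimizer at the tolerance.
#'
#' @param min_p_mat numeric matrix with row names (CpG ids), values in
#'   (0, 1).
#' @param tol gradient convergence tolerance.
#' @param maxit maximum Newton iterations.
#' @return `data.table`: cpg_id, a, b, loglik, converged.
#' @export
fit_beta_rows <- function(min_p_mat, tol = 1e-8, maxit = 100) {
  x <- pmin(pmax(min_p_mat, 1e-300), 1 - 1e-12)
  n <- ncol(x)
  m <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  degen <- v == 0
  v <- pmin(pmax(v, 1e-12), m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  a <- pmax(m * common, 1e-3)
  b <- pmax((1 - m) * common, 1e-3)
  slx <- rowSums(log(x)) / n
  sl1x <- rowSums(log1p(-x)) / n
  active <- !degen
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    dab <- digamma(a + b)
    g1 <- dab - digamma(a) + slx
    g2 <- dab - digamma(b) + sl1x
    tab <- trigamma(a + b)
    h11 <- tab - trigamma(a)
    h22 <- tab - trigamma(b)
    det <- h11 * h22 - tab^2
    da <- -(h22 * g1 - tab * g2) / det
    db <- -(h11 * g2 - tab * g1) / det
    # damp steps that would leave the positive quadrant
    step <- rep(1, length(a))
    bad <- active & (a + da <= 0 | b + db <= 0)
    while (any(bad)) {
      step[bad] <- step[bad] / 2
      bad <- active & (a + step * da <= 0 | b + step * db <= 0) & step > 1e-8
    }
    conv <- pmax(abs(g1), abs(g2)) < tol
    upd <- active & !conv
    a[upd] <- a[upd] + step[upd] * da[upd]
    b[upd] <- b[upd] + step[upd] * db[upd]
    active <- upd
  }
  converged <- !degen & !active & is.finite(a) & is.finite(b)
  # refit stragglers with the scalar optimizer
  for (i in which(!converged & !degen)) {
    f <- fit_beta_mle(x[i, ])
    if (f$converged) {
      a[i] <- f$a; b[i] <- f$b; converged[i] <- TRUE
    }
  }
  ll <- n * (lgamma(a + b) - lgamma(a) - lgamma(b)) +
    (a - 1) * slx * n + (b - 1) * sl1x * n
  a[degen] <- NA_real_; b[degen] <- NA_real_; ll[degen] <- NA_real_
  data.table::data.table(cpg_id = rownames(min_p_mat), a = a, b = b,
                         loglik = ll, converged = converged)
}

#' Empirical p-value of an observed minimum p under the beta null
#'
#' The probability, under the fitted beta approximation of the permutation
#' null, of observing a minimum p-value at least as small as the observed
#' one: the beta CDF at `min_p_obs`. When the fit did not converge the
#' rank-based estimate `(r + 1) / (n_perm + 1)` is used instead (and
#' requires the permutation vector).
#'
#' @param min_p_obs observed minimum p-value (scalar or vector, recycled
#'   against the fit parameters).
#' @param fit a `beta_fit` or a list/table with elements `a`, `b`,
#'   `converged`.
#' @param min_p_perm permutation minima, used only for the rank fallback.
#' @return empirical p-value(s) in (0, 1].
#' @export
empirical_p <- function(min_p_obs, fit, min_p_perm = NULL) {
  if (isTRUE(fit$converged)) {
    return(stats::pbeta(min_p_obs, fit$a, fit$b))
  }
  if (is.null(min_p_perm))
    stop_("beta fit did not converge and no permutation minima were given for the rank fallback")
  (sum(min_p_perm <= min_p_obs) + 1) / (length(min_p_perm) + 1)
}

#' CpG-level Benjamini-Hochberg selection and genome-wide threshold
#'
#' Applies Benjamini-Hochberg FDR control at level `alpha` to the per-CpG
#' empirical p-values and derives the genome-wide empirical p-value
#' threshold as the point closest to the FDR boundary: by default the
#' midpoint between the largest significant and the smallest non-significant
#' empirical p-value (the `"largest_significant"` rule uses the boundary
#' value itself).
#'
#' @param p_emp `data.table` (cpg_id, p_emp).
#' @param alpha FDR level (default 0.05).
#' @param rule `"midpoint"` (default) or `"largest_significant"`.
#' @return list: `significant` (cpg_id vector), `p_emp_genomewide`
#'   (NA when nothing is significant), `fdr` table with BH-adjusted values.
#' @export
bh_select <- function(p_emp, alpha = 0.05, rule = c("midpoint", "largest_significant")) {
  rule <- match.arg(rule)
  if (nrow(p_emp) == 0) stop_("empty empirical p-value table")
  dt <- data.table::copy(p_emp)
  data.table::setorder(dt, p_emp, cpg_id)  # stable tie-break
  dt[, p_adj := stats::p.adjust(p_emp, method = "BH")]
  dt[, significant := p_adj <= alpha]
  sig <- dt[significant == TRUE, cpg_id]
  thr <- NA_real_
  if (length(sig) > 0) {
    hi <- max(dt[significant == TRUE, p_emp])
    lo_ns <- dt[significant == FALSE, p_emp]
    thr <- if (rule == "largest_significant" || length(lo_ns) == 0) hi
           else (hi + min(lo_ns)) / 2
  }
  list(significant = sig, p_emp_genomewide = thr, fdr = dt[])
}

#' Per-CpG nominal p-value threshold by inverse beta CDF
#'
#' Translates the genome-wide empirical p-value threshold back to the
#' pair-level p-value scale of one CpG: the quantile of its fitted null
#' beta distribution at the genome-wide empirical threshold.
#'
#' @param fit `beta_fit` (or a,b pair); must have converged.
#' @param p_emp_genomewide genome-wide empirical p-value threshold in (0,1).
#' @return nominal pair-level p-value threshold for this CpG.
#' @export
nominal_threshold <- function(fit, p_emp_genomewide) {
  if (!isTRUE(fit$converged %||% TRUE)) stop_("beta fit did not converge")
  stats::qbeta(p_emp_genomewide, fit$a, fit$b)
}

#' Call significant eQTMs from the association table and thresholds
#'
#' The hierarchical rule: only CpGs that passed CpG-level BH selection
#' ("eCpGs") contribute records, and within an eCpG every paired gene whose
#' association p-value falls below that CpG's nominal threshold becomes an
#' eQTM. Direction is `inverse` for negative methylation coefficients and
#' `positive` otherwise.
#'
#' @param assoc association table from [run_model()].
#' @param thresholds list with `nominal` (`data.table`: cpg_id, nominal_p)
#'   covering every significant CpG, as produced by [eqtm_discover()].
#' @return `data.table` of eQTM records: cpg_id, gene_id, beta,
#'   log2fc_per_10pct, se, p, signed_dist, direction, nominal_p.
#' @export
call_eqtms <- function(assoc, thresholds) {
  nom <- thresholds$nominal
  rec <- assoc[nom, on = "cpg_id", nomatch = NULL]
  rec <- rec[p < nominal_p]
  rec[, `:=`(direction = ifelse(beta < 0, "inverse", "positive"),
             log2fc_per_10pct = effect_log2fc_per_10pct(beta))]
  data.table::setcolorder(rec, c("cpg_id", "gene_id", "beta",
                                 "log2fc_per_10pct", "se", "p",
                                 "signed_dist", "direction", "nominal_p"))
  rec[]
}

#' Full CpG-level permutation discovery of cis eQTMs
#'
#' Runs the complete multiple-testing procedure: (1) the observed
#' association scan; (2) `n_perm` scans on expression matrices with
#' permuted sample columns, recording for each CpG the minimum p-value per
#' permutation; (3) a maximum-likelihood beta fit to each CpG's permutation
#' minima; (4) the empirical p-value of each CpG's observed minimum under
#' its beta null; (5) Benjamini-Hochberg selection of eCpGs at `alpha` and
#' the genome-wide empirical threshold; (6) per-eCpG nominal pair-level
#' thresholds by inverse beta CDF; and (7) the final eQTM calls.
#'
#' @param pairs candidate pair set from [pair_cis()].
#' @param meth_mat,expr_mat omics matrices (features x samples).
#' @param covars covariate table.
#' @param model association model flag.
#' @param n_perm number of permuted expression datasets (default 100).
#' @param alpha CpG-level FDR (default 0.05).
#' @param seed master seed controlling all permutations.
#' @param rule genome-wide threshold rule, see [bh_select()].
#' @return list: `assoc` (observed scan), `null_minp` (CpGs x n_perm
#'   matrix), `beta_fits`, `p_emp`, `bh`, `thresholds` (incl. per-CpG
#'   `nominal`), and `eqtms`.
#' @export
eqtm_discover <- function(pairs, meth_mat, expr_mat, covars,
                          model = "cell_adjusted", n_perm = 100,
                          alpha = 0.05, seed = 1,
                          rule = "midpoint") {
  eng <- scan_engine(pairs, meth_mat, expr_mat, covars, model)
  obs <- scan_stats(eng)
  assoc <- pairs[, .(cpg_id, gene_id, signed_dist)]
  assoc[, `:=`(beta = obs$beta, se = obs$se, tstat = obs$tstat,
               p = exp(obs$log_p), log_p = obs$log_p,
               n_used = eng$n, model = model)]

  cpg_ids <- sort(unique(pairs$cpg_id))
  cpg_of_pair <- match(pairs$cpg_id, cpg_ids)
  null_minp <- matrix(NA_real_, length(cpg_ids), n_perm,
                      dimnames = list(cpg_ids, NULL))
  for (j in seq_len(n_perm)) {
    ep <- permute_expression(expr_mat, j, seed)
    st <- scan_stats(eng, ep)
    mlp <- tapply(st$log_p, cpg_of_pair, min)
    null_minp[as.integer(names(mlp)), j] <- exp(mlp)
  }

  fits <- fit_beta_rows(null_minp)
  obs_min <- min_p_per_cpg(assoc)
  fits <- fits[obs_min, on = "cpg_id"]
  fits[, p_emp := NA_real_]
  conv <- fits$converged
  fits[conv == TRUE, p_emp := stats::pbeta(min_p, a, b)]
  if (any(!conv)) {
    ri <- which(!conv)
    ranks <- vapply(ri, function(i) {
      row <- match(fits$cpg_id[i], rownames(null_minp))
      (sum(null_minp[row, ] <= fits$min_p[i]) + 1) / (n_perm + 1)
    }, numeric(1))
    fits[ri, p_emp := ranks]
  }

  bh <- bh_select(fits[, .(cpg_id, p_emp)], alpha = alpha, rule = rule)
  nominal <- data.table::data.table(cpg_id = character(0), nominal_p = numeric(0))
  if (length(bh$significant) > 0 && !is.na(bh$p_emp_genomewide)) {
    sf <- fits[cpg_id %in% bh$significant]
    nominal <- sf[, .(cpg_id, nominal_p = NA_real_)]
    thr <- bh$p_emp_genomewide
    nominal[sf$converged, nominal_p := stats::qbeta(thr, sf$a[sf$converged],
                                                    sf$b[sf$converged])]
    for (i in which(!sf$converged)) {
      # rank-based fallback: the matching quantile of this CpG's permutation minima
      nominal[i, nominal_p := as.numeric(
        stats::quantile(null_minp[sf$cpg_id[i], ], probs = thr, na.rm = TRUE))]
    }
  }
  thresholds <- list(alpha = alpha, p_emp_genomewide = bh$p_emp_genomewide,
                     nominal = nominal)
  eqtms <- call_eqtms(assoc, thresholds)
  list(assoc = assoc[], null_minp = null_minp, beta_fits = fits[],
       p_emp = fits[, .(cpg_id, p_emp)],
       bh = bh, thresholds = thresholds, eqtms = eqtms)
}
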