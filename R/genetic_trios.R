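#' Principal components of a genotype dosage matrix
#'
#' Truncated decomposition of the column-centered dosage matrix (samples in
#' columns); the leading components capture genetic ancestry structure and
#' enter the QTL models as covariates.
#'
#' @param dosage SNPs x samples dosage matrix.
#' @param k number of components (capped at the matrix rank).
#' @return samples x k matrix of PC scores, columns `PC1..PCk`.
#' @export
genotype_pcs <- function(dosage, k = 20) {
  x <- t(dosage)
  x <- scale(x, center = TRUE, scale = FALSE)
  k <- min(k, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  scores
}

#' Test one SNP against one molecular target (meQTL or eQTL)
#'
#' OLS of the target (methylation of a CpG or log2 expression of a gene)
#' on the allele dosage, adjusted for the covariates and optional genotype
#' PCs; the p-value is the two-sided t-test on the dosage coefficient —
#' the same engine as the pair association model.
#'
#' @param dosage per-sample dosage vector in \[0,2\].
#' @param target per-sample methylation or expression vector.
#' @param covars covariate table.
#' @param kind `"meQTL"` or `"eQTL"` (label only).
#' @param pcs optional samples x k PC score matrix.
#' @param model covariate model flag, as in [build_design()].
#' @return one-row `data.table`: beta, se, tstat, p, n_used, kind.
#' @export
test_qtl <- function(dosage, target, covars, kind = c("meQTL", "eQTL"),
                     pcs = NULL, model = "cell_adjusted") {
  kind <- match.arg(kind)
  if (stats::sd(dosage) == 0) stop_("constant dosage vector")
  X <- build_design(covars, model)
  if (!is.null(pcs)) X <- cbind(X, pcs)
  D <- cbind(dosage = dosage, X)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) stop_("rank-deficient QTL design")
  fit <- stats::lm.fit(D, target)
  df <- length(target) - ncol(D)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(qr.R(qr_d))
  kk <- which(qr_d$pivot == 1L)
  se <- sqrt(rss / df * XtXinv[kk, kk])
  beta <- unname(fit$coefficients["dosage"])
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.table::data.table(beta = beta, se = se, tstat = tval, p = p,
                         n_used = length(target), kind = kind)
}

#' Scan SNP-target candidate pairs for QTL effects
#'
#' Runs [test_qtl()] over a candidate list of SNP-target pairs (all
#' combinations when no list is given).
#'
#' @param dosage SNPs x samples matrix.
#' @param target_mat targets x samples matrix (methylation or expression).
#' @param covars covariate table.
#' @param kind `"meQTL"` or `"eQTL"`.
#' @param candidates optional `data.table` (snp_id, target_id); defaults
#'   to all SNP x target combinations.
#' @param pcs optional PC score matrix.
#' @param model covariate model flag.
#' @return `data.table`: snp_id, target_id, beta, se, tstat, p, n_used,
#'   kind.
#' @export
run_qtl_scan <- function(dosage, target_mat, covars,
                         kind = c("meQTL", "eQTL"), candidates = NULL,
                         pcs = NULL, model = "cell_adjusted") {
  kind <- match.arg(kind)
  assert_aligned_samples(dosage, target_mat, covars$sample_id)
  if (is.null(candidates)) {
    candidates <- data.table::CJ(snp_id = rownames(dosage),
                                 target_id = rownames(target_mat))
  }
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    test_qtl(dosage[candidates$snp_id[i], ],
             target_mat[candidates$target_id[i], ],
             covars, kind, pcs = pcs, model = model)
  })
  cbind(candidates[, .(snp_id, target_id)], data.table::rbindlist(res))[]
}

#' Assemble SNP-CpG-gene trios and flag direction consistency
#'
#' Joins significant meQTLs (SNP-CpG), the eQTM catalogue (CpG-gene) and
#' significant eQTLs (SNP-gene) on the shared CpG and gene. A trio is
#' direction-consistent when the sign of the SNP-gene effect equals the
#' product of the SNP-CpG and CpG-gene effect signs; trios with any
#' exactly-zero effect are flagged inconsistent.
#'
#' @param meqtls QTL table with target_id = cpg_id.
#' @param eqtms eQTM record table.
#' @param eqtls QTL table with target_id = gene_id.
#' @param p_thresh QTL significance threshold (default 1e-7), applied to
#'   both QTL tables before joining.
#' @return `data.table`: snp_id, cpg_id, gene_id, b_meqtl, b_eqtm,
#'   b_eqtl, consistent.
#' @export
build_trios <- function(meqtls, eqtms, eqtls, p_thresh = 1e-7) {
  me <- meqtls[p < p_thresh, .(snp_id, cpg_id = target_id, b_meqtl = beta)]
  eq <- eqtls[p < p_thresh, .(snp_id, gene_id = target_id, b_eqtl = beta)]
  em <- eqtms[, .(cpg_id, gene_id, b_eqtm = beta)]
  trios <- me[em, on = "cpg_id", nomatch = NULL, allow.cartesian = TRUE]
  trios <- trios[eq, on = c("snp_id", "gene_id"), nomatch = NULL]
  trios[, consistent :=
          b_meqtl != 0 & b_eqtm != 0 & b_eqtl != 0 &
          sign(b_meqtl) * sign(b_eqtm) == sign(b_eqtl)]
  data.table::setcolorder(trios, c("snp_id", "cpg_id", "gene_id",
                                   "b_meqtl", "b_eqtm", "b_eqtl",
                                   "consistent"))
  trios[]
}

#' Summary counts of a trio set
#'
#' @param trios `data.table` from [build_trios()].
#' @return named list: consistent/inconsistent trio counts, unique
#'   eQTM/eCpG/eGene/SNP counts, and the median number of trios per eCpG
#'   and per eGene.
#' @export
trio_summary <- function(trios) {
  if (nrow(trios) == 0) {
    return(list(n_trios_consistent = 0L, n_trios_inconsistent = 0L,
                n_unique_eqtms = 0L, n_unique_ecpgs = 0L,
                n_unique_egenes = 0L, n_unique_snps = 0L,
                median_trios_per_ecpg = NA_real_,
                median_trios_per_egene = NA_real_))
  }
  list(
    n_trios_consistent = sum(trios$consistent),
    n_trios_inconsistent = sum(!trios$consistent),
    n_unique_eqtms = nrow(unique(trios[, .(cpg_id, gene_id)])),
    n_unique_ecpgs = data.table::uniqueN(trios$cpg_id),
    n_unique_egenes = data.table::uniqueN(trios$gene_id),
    n_unique_snps = data.table::uniqueN(trios$snp_id),
    median_trios_per_ecpg = stats::median(trios[, .N, by = cpg_id]$N),
    median_trios_per_egene = stats::median(trios[, .N, by = gene_id]$N)
  )
}
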