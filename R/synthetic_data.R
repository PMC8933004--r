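#' Simulate a sample covariate table
#'
#' Generates the covariates the association models adjust for: child sex,
#' age in years, cohort of recruitment, and blood cell-type proportions for
#' six leukocyte populations (NK, B, CD4+ T, CD8+ T, monocytes,
#' granulocytes). Cell proportions are drawn from a Dirichlet distribution
#' whose concentration mirrors typical child whole-blood composition
#' (granulocyte-dominated), so they are non-negative and sum to one.
#'
#' @param n_samples number of children to simulate.
#' @param n_cohorts number of recruitment cohorts (entered as indicator
#'   contrasts in the models).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a `data.table` with columns `sample_id`, `sex` (0/1), `age`
#'   (years), `cohort` (factor) and six `cell_*` proportion columns.
#' @export
generate_covariates <- function(n_samples, n_cohorts = 6, seed = 1) {
  if (n_samples <= 0) stop_("n_samples must be positive")
  set.seed(seed)
  # Dirichlet via independent gammas; concentrations approximate child
  # whole-blood medians (granulocytes ~ 45%).
  conc <- c(nk = 2, b = 11, cd4t = 19, cd8t = 13, mono = 8, gran = 44)
  g <- matrix(stats::rgamma(n_samples * 6, shape = rep(conc, each = n_samples)),
              nrow = n_samples)
  props <- g / rowSums(g)
  colnames(props) <- paste0("cell_", names(conc))
  dt <- data.table::data.table(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    sex = stats::rbinom(n_samples, 1, 0.5),
    age = stats::runif(n_samples, 6, 11),
    cohort = factor(sample(paste0("cohort", seq_len(n_cohorts)),
                           n_samples, replace = TRUE))
  )
  cbind(dt, data.table::as.data.table(props))
}

#' Simulate CpG and gene annotations
#'
#' Places genes and CpGs on autosomes. Gene transcription start sites are
#' uniform over each chromosome (kept at least one cis window away from the
#' ends), strands are random, and gene bodies extend from the TSS in the
#' transcriptional direction. A configurable fraction of CpGs is clustered
#' around gene TSSs (normal offsets) and the rest is uniform background, so
#' every gene acquires cis CpGs at a range of distances.
#'
#' @param n_cpgs,n_genes numbers of CpGs and genes (> 0).
#' @param chrom_lengths named numeric vector of autosome lengths in bp;
#'   names must be in "1".."22" and every length must be at least
#'   `2 * window_bp`.
#' @param seed integer seed.
#' @param window_bp cis half-window used for the sizing check and for TSS
#'   placement margins (default 500 kb).
#' @param frac_clustered fraction of CpGs placed near gene TSSs.
#' @param cluster_sd standard deviation (bp) of clustered CpG offsets.
#' @return list with `cpgs` (cpg_id, chrom, pos) and `genes`
#'   (gene_id, chrom, start, end, strand, symbol). Coordinates are 1-based
#'   and inclusive.
#' @export
generate_annotation <- function(n_cpgs, n_genes,
                                chrom_lengths = c("1" = 25e6, "2" = 25e6),
                                seed = 1, window_bp = 5e5,
                                frac_clustered = 0.3, cluster_sd = 5e4) {
  if (n_cpgs <= 0 || n_genes <= 0) stop_("n_cpgs and n_genes must be positive")
  if (is.null(names(chrom_lengths)) || !all(names(chrom_lengths) %in% AUTOSOMES))
    stop_("chrom_lengths must be named with autosome labels \"1\"..\"22\"")
  if (any(chrom_lengths < 2 * window_bp))
    stop_("chromosome length smaller than 2x the cis window; enlarge chromosomes or shrink the window")
  set.seed(seed)
  chroms <- names(chrom_lengths)
  gw <- chrom_lengths / sum(chrom_lengths)

  g_chrom <- sample(chroms, n_genes, replace = TRUE, prob = gw)
  g_len_chr <- chrom_lengths[g_chrom]
  tss <- floor(stats::runif(n_genes, window_bp, g_len_chr - window_bp))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  body_len <- floor(stats::runif(n_genes, 2e3, 2e5))
  start <- ifelse(strand == "+", tss, pmax(1, tss - body_len))
  end <- ifelse(strand == "+", pmin(g_len_chr, tss + body_len), tss)
  genes <- data.table::data.table(
    gene_id = sprintf("TC%05d", seq_len(n_genes)),
    chrom = g_chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, symbol = sprintf("GENE%05d", seq_len(n_genes))
  )

  n_clust <- round(frac_clustered * n_cpgs)
  anchor <- sample.int(n_genes, n_clust, replace = TRUE)
  c_pos <- round(tss[anchor] + stats::rnorm(n_clust, 0, cluster_sd))
  c_chrom <- g_chrom[anchor]
  c_pos <- pmin(pmax(c_pos, 1), chrom_lengths[c_chrom])
  u_chrom <- sample(chroms, n_cpgs - n_clust, replace = TRUE, prob = gw)
  u_pos <- floor(stats::runif(n_cpgs - n_clust, 1, chrom_lengths[u_chrom]))
  cpgs <- data.table::data.table(
    cpg_id = sprintf("cg%06d", seq_len(n_cpgs)),
    chrom = c(c_chrom, u_chrom),
    pos = as.integer(c(c_pos, u_pos))
  )
  data.table::setorder(cpgs, chrom, pos)
  cpgs[, cpg_id := sprintf("cg%06d", seq_len(n_cpgs))]
  list(cpgs = cpgs[], genes = genes[])
}

default_effect_spec <- function() {
  list(prop_true_cpgs = 0.1,   # fraction of CpGs carrying one true cis effect
       n_true_pairs = NULL,    # absolute count; overrides prop when given
       beta_range = c(1, 2),   # |true beta|, log2 expression per beta-value unit
       sign_mix = 0.5,         # fraction of positive effects
       noise_sd = 0.5,         # residual sd of log2 expression
       meth_sd = 0.8,          # per-CpG latent logit spread
       confound_meth = 0.5,    # cohort/cell effect scale on latent methylation
       confound_expr = 0.5,    # cohort/cell/age/sex effect scale on expression
       plant_weight = "variance")  # "variance": true effects favour variable CpGs
}

#' Simulate methylation and expression matrices with planted cis effects
#'
#' Methylation is logit-normal per CpG: a latent Gaussian with a CpG-specific
#' mean drawn from a bimodal mixture (mimicking the low/high methylation
#' modes of array beta values) plus cohort and cell-composition shifts, then
#' squashed through the logistic so values stay in \[0,1\]. Expression is
#' Gaussian on the log2 scale: gene baseline + covariate effects + the sum of
#' planted linear CpG effects + noise. Each "true" CpG influences exactly one
#' of its cis genes with a coefficient drawn from `beta_range` with sign
#' determined by `sign_mix`.
#'
#' @param cpgs,genes annotation tables from [generate_annotation()].
#' @param covars covariate table from [generate_covariates()].
#' @param effect_spec list overriding elements of the default effect
#'   specification (see `default_effect_spec`): `prop_true_cpgs` or
#'   `n_true_pairs`, `beta_range`, `sign_mix`, `noise_sd`, `meth_sd`,
#'   `confound_meth`, `confound_expr`.
#' @param seed integer seed.
#' @param window_bp cis half-window for planting (true pairs always lie
#'   within it).
#' @return list with `meth` (CpGs x samples beta values), `expr`
#'   (genes x samples log2), and `truth`: every cis candidate pair with
#'   `true_beta` (0 for nulls) and `mechanism` in {direct, null}.
#' @export
generate_omics <- function(cpgs, genes, covars, effect_spec = list(),
                           seed = 1, window_bp = 5e5) {
  spec <- utils::modifyList(default_effect_spec(), effect_spec)
  n <- nrow(covars)
  n_cpg <- nrow(cpgs)
  n_gene <- nrow(genes)
  set.seed(seed)

  pairs <- pair_cis(cpgs, genes, window_bp = window_bp)
  n_true <- if (!is.null(spec$n_true_pairs)) spec$n_true_pairs
            else round(spec$prop_true_cpgs * n_cpg)
  elig <- unique(pairs$cpg_id)
  if (n_true > length(elig))
    stop_("effect_spec requests %d true pairs but only %d CpGs have cis pairs",
          n_true, length(elig))

  cohorts <- levels(covars$cohort)
  k <- length(cohorts)
  cohort_idx <- as.integer(covars$cohort)
  gran_c <- covars$cell_gran - mean(covars$cell_gran)
  age_c <- covars$age - mean(covars$age)

  # methylation: latent logit-normal
  mode <- sample.int(3, n_cpg, replace = TRUE, prob = c(0.35, 0.35, 0.3))
  mu <- c(-2.5, 2.5, 0)[mode] + stats::rnorm(n_cpg, 0, c(0.5, 0.5, 1)[mode])
  coh_m <- matrix(stats::rnorm(n_cpg * k, 0, spec$confound_meth), n_cpg, k)
  gran_m <- stats::rnorm(n_cpg, 0, spec$confound_meth)
  z <- mu +
    coh_m[cbind(rep(seq_len(n_cpg), n), rep(cohort_idx, each = n_cpg))] +
    outer(gran_m, gran_c) +
    matrix(stats::rnorm(n_cpg * n, 0, spec$meth_sd), n_cpg, n)
  dim(z) <- c(n_cpg, n)
  meth <- stats::plogis(z)
  dimnames(meth) <- list(cpgs$cpg_id, covars$sample_id)

  # planted pairs: one gene per selected CpG. By default CpGs are selected
  # with probability proportional to their methylation variance, emulating
  # the preference of real eQTMs for variable, intermediate-methylation
  # CpGs; "uniform" plants without regard to variability.
  truth <- data.table::copy(pairs)[, `:=`(true_beta = 0, mechanism = "null")]
  if (n_true > 0) {
    w <- if (identical(spec$plant_weight, "variance")) {
      v <- apply(meth, 1, stats::var)
      v[match(elig, cpgs$cpg_id)]
    } else rep(1, length(elig))
    true_cpgs <- sample(elig, n_true, prob = w)
    picks <- pairs[cpg_id %in% true_cpgs,
                   .SD[sample.int(.N, 1L)], by = cpg_id]
    b <- stats::runif(n_true, spec$beta_range[1], spec$beta_range[2])
    if (any(b == 0)) stop_("beta_range must exclude 0 for true pairs")
    sgn <- ifelse(stats::runif(n_true) < spec$sign_mix, 1, -1)
    picks[, true_beta := b * sgn]
    truth[picks, on = c("cpg_id", "gene_id"),
          `:=`(true_beta = i.true_beta, mechanism = "direct")]
  }

  # expression: baseline + covariates + planted effects + noise
  base <- stats::rnorm(n_gene, 7, 2)
  coh_e <- matrix(stats::rnorm(n_gene * k, 0, spec$confound_expr), n_gene, k)
  expr <- base +
    coh_e[cbind(rep(seq_len(n_gene), n), rep(cohort_idx, each = n_gene))] +
    outer(stats::rnorm(n_gene, 0, spec$confound_expr), gran_c) +
    outer(stats::rnorm(n_gene, 0, spec$confound_expr * 0.1), age_c) +
    outer(stats::rnorm(n_gene, 0, spec$confound_expr * 0.5), covars$sex - 0.5) +
    matrix(stats::rnorm(n_gene * n, 0, spec$noise_sd), n_gene, n)
  dim(expr) <- c(n_gene, n)
  dimnames(expr) <- list(genes$gene_id, covars$sample_id)

  planted <- truth[mechanism != "null"]
  if (nrow(planted)) {
    ci <- match(planted$cpg_id, cpgs$cpg_id)
    gi <- match(planted$gene_id, genes$gene_id)
    for (r in seq_len(nrow(planted))) {
      expr[gi[r], ] <- expr[gi[r], ] + planted$true_beta[r] * meth[ci[r], ]
    }
  }
  list(meth = meth, expr = expr, truth = truth[])
}

#' Attach SNP genotypes and SNP-to-CpG causal chains to simulated omics
#'
#' Simulates independent biallelic SNPs as dosages in {0,1,2} under
#' Hardy-Weinberg with minor-allele frequencies drawn from `maf_range`.
#' For each requested causal chain a SNP placed near a planted CpG shifts
#' that CpG's methylation additively on the latent logit scale (per allele),
#' and the paired gene's expression is updated through the planted
#' CpG-to-gene coefficient, so the SNP is simultaneously a meQTL and an
#' eQTL with mutually consistent effect signs.
#'
#' @param omics output of [generate_omics()] (`meth`, `expr`, `truth`).
#' @param cpgs CpG annotation table.
#' @param chain_spec list: `n_chains` (number of SNP->CpG->gene chains,
#'   attached to planted pairs), `snp_effect_on_meth` (logit shift per
#'   allele), `maf_range` in (0, 0.5], `n_null_snps` (background SNPs with
#'   no omics effect).
#' @param seed integer seed.
#' @return list with `geno` (`snps` table and `dosage` matrix, SNPs x
#'   samples), updated `meth` and `expr`, and the augmented `truth` table
#'   (chain rows get `mechanism = "snp_driven"`, `snp_id`,
#'   `snp_effect_on_meth`).
#' @export
generate_genotypes <- function(omics, cpgs,
                               chain_spec = list(), seed = 1) {
  spec <- utils::modifyList(
    list(n_chains = 0, snp_effect_on_meth = 0.5,
         maf_range = c(0.1, 0.5), n_null_snps = 20),
    chain_spec)
  if (spec$maf_range[1] <= 0 || spec$maf_range[2] > 0.5)
    stop_("maf_range must lie in (0, 0.5]")
  set.seed(seed)
  n <- ncol(omics$meth)
  truth <- data.table::copy(omics$truth)
  meth <- omics$meth
  expr <- omics$expr

  planted <- truth[mechanism == "direct"]
  if (spec$n_chains > nrow(planted))
    stop_("chain_spec requests %d chains but only %d planted pairs exist",
          spec$n_chains, nrow(planted))

  n_snps <- spec$n_chains + spec$n_null_snps
  snps <- data.table::data.table(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = sample(unique(cpgs$chrom), n_snps, replace = TRUE),
    pos = NA_integer_,
    maf = stats::runif(n_snps, spec$maf_range[1], spec$maf_range[2])
  )
  dosage <- matrix(stats::rbinom(n_snps * n, 2, rep(snps$maf, n)),
                   nrow = n_snps,
                   dimnames = list(snps$snp_id, colnames(meth)))

  truth[, `:=`(snp_id = NA_character_, snp_effect_on_meth = 0)]
  if (spec$n_chains > 0) {
    chain_rows <- planted[sample.int(.N, spec$n_chains)]
    for (i in seq_len(spec$n_chains)) {
      cg <- chain_rows$cpg_id[i]
      ci <- match(cg, rownames(meth))
      gi <- match(chain_rows$gene_id[i], rownames(expr))
      ann <- cpgs[cpg_id == cg]
      snps[i, `:=`(chrom = ann$chrom, pos = ann$pos + 500L)]
      old <- meth[ci, ]
      meth[ci, ] <- stats::plogis(stats::qlogis(old) +
                                  spec$snp_effect_on_meth * dosage[i, ])
      expr[gi, ] <- expr[gi, ] + chain_rows$true_beta[i] * (meth[ci, ] - old)
      truth[cpg_id == cg & gene_id == chain_rows$gene_id[i],
            `:=`(mechanism = "snp_driven", snp_id = snps$snp_id[i],
                 snp_effect_on_meth = spec$snp_effect_on_meth)]
    }
  }
  null_idx <- which(is.na(snps$pos))
  if (length(null_idx)) {
    snps[null_idx, pos := sample.int(1e6, length(null_idx))]
  }
  list(geno = list(snps = snps[], dosage = dosage),
       meth = meth, expr = expr, truth = truth[])
}

#' Simulate per-CpG metadata used by the enrichment analyses
#'
#' Fabricates probe reliability (ICC), total and SNP heritability, CpG-island
#' relative position, a handful of blood chromatin-state flags, and an
#' age-related methylation-change label. When `is_ecpg` is supplied the
#' draws are tilted so that eCpGs are more reliable, more heritable, and
#' enriched for active states — giving the enrichment statistics real signal
#' to detect.
#'
#' @param cpgs CpG annotation table.
#' @param is_ecpg optional logical vector (same order as `cpgs`) marking
#'   CpGs that take part in an eQTM.
#' @param shift strength of the eCpG tilt (0 = no dependence).
#' @param seed integer seed.
#' @return `cpgs` with columns `icc`, `heritability_total`,
#'   `heritability_snp`, `island_rel`, logical `state_*` flags and
#'   `age_change` appended.
#' @export
simulate_cpg_metadata <- function(cpgs, is_ecpg = NULL, shift = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(cpgs)
  e <- if (is.null(is_ecpg)) rep(FALSE, n) else as.logical(is_ecpg)
  tilt <- ifelse(e, shift, 0)
  out <- data.table::copy(cpgs)
  out[, icc := stats::rbeta(n, 2 + 2 * tilt, 3)]
  out[, heritability_total := stats::rbeta(n, 2 + tilt, 4)]
  out[, heritability_snp := heritability_total * stats::rbeta(n, 2, 2)]
  isl <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf", "open_sea")
  base_p <- c(0.30, 0.12, 0.12, 0.05, 0.05, 0.36)
  shore_p <- c(0.15, 0.22, 0.22, 0.07, 0.07, 0.27)  # eCpGs favour shores
  out[, island_rel := ifelse(e,
    sample(isl, n, replace = TRUE, prob = shore_p),
    sample(isl, n, replace = TRUE, prob = base_p))]
  for (st in c("TssA", "Enh", "Tx", "ReprPC", "Quies")) {
    p0 <- c(TssA = 0.10, Enh = 0.15, Tx = 0.20, ReprPC = 0.10, Quies = 0.35)[st]
    p <- stats::plogis(stats::qlogis(p0) +
                       (if (st %in% c("TssA", "Enh", "Tx")) 1 else -1) * tilt)
    out[, paste0("state_", st) := stats::runif(n) < p]
  }
  out[, age_change := sample(c("increase", "decrease", "stable"), n,
                             replace = TRUE, prob = c(0.15, 0.15, 0.7))]
  out[]
}

#' Map CpGs to the gene symbols of nearby genes
#'
#' Emulates array-style CpG-to-gene annotation: a CpG is annotated to every
#' gene whose body, or promoter up to `promoter_bp` upstream of the TSS,
#' contains it. Returns the symbol sets used by the closest-gene concordance
#' analysis.
#'
#' @param cpgs,genes annotation tables.
#' @param promoter_bp promoter extension upstream of the TSS (default 1500).
#' @return named list: for each cpg_id, a character vector of symbols
#'   (possibly empty).
#' @export
cpg_symbol_map <- function(cpgs, genes, promoter_bp = 1500) {
  g_start <- ifelse(genes$strand == "+", genes$start - promoter_bp, genes$start)
  g_end <- ifelse(genes$strand == "+", genes$end, genes$end + promoter_bp)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1, g_start), g_end))
  gr_c <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos, cpgs$pos))
  ov <- GenomicRanges::findOverlaps(gr_c, gr_g)
  res <- split(genes$symbol[S4Vectors::subjectHits(ov)],
               cpgs$cpg_id[S4Vectors::queryHits(ov)])
  out <- stats::setNames(vector("list", nrow(cpgs)), cpgs$cpg_id)
  out[names(res)] <- lapply(res, unique)
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}
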