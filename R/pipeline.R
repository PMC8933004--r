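#' Default pipeline configuration
#'
#' A single configuration object drives a full run; it round-trips through
#' JSON ([write_config()] / [read_config()]) unchanged. The master seed
#' fans out to per-stage seeds through a fixed derivation so stages are
#' individually reproducible.
#'
#' @param seed master seed.
#' @param ... overrides for any configuration field.
#' @return named list of configuration values.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_cpgs = 2000, n_genes = 200, n_samples = 300, n_cohorts = 6,
    chrom_lengths = c("1" = 25e6, "2" = 25e6),
    window_bp = 5e5,
    effect_spec = list(),
    n_perm = 100, alpha = 0.05, model = "cell_adjusted",
    chain_spec = list(n_chains = 20, snp_effect_on_meth = 0.5,
                      maf_range = c(0.1, 0.5), n_null_snps = 20),
    p_thresh_qtl = 1e-7, p_thresh_shared = 1e-5,
    frac_shared_adult = 0.3,
    stages = c("simulate", "pair", "associate", "discover", "classify",
               "enrich", "trios", "compare")
  )
  utils::modifyList(cfg, list(...))
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config configuration list.
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  # named atomic vectors lose their names as JSON arrays; store as objects
  config$chrom_lengths <- as.list(config$chrom_lengths)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  if (!is.null(cfg$effect_spec) && length(cfg$effect_spec) == 0)
    cfg$effect_spec <- list()
  cfg
}

write_table <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Run the full discovery pipeline on synthetic data
#'
#' Orchestrates simulate -> pair -> associate -> discover -> classify ->
#' enrich -> trios -> compare. Each stage consumes only prior-stage
#' outputs; tables are written tab-separated under `run_dir` together with
#' a `manifest.json` recording the configuration, per-stage seeds and MD5
#' digests of every written file, so a rerun with the same configuration
#' reproduces the digests byte for byte.
#'
#' @param config configuration from [default_config()].
#' @param run_dir output directory (created if missing); NULL runs
#'   in-memory only.
#' @return named list with the in-memory stage outputs and the manifest.
#' @export
run_pipeline <- function(config = default_config(), run_dir = NULL) {
  stages <- config$stages
  out <- list(config = config)
  sseed <- function(stage) derive_seed(config$seed, match(stage, c(
    "simulate", "pair", "associate", "discover", "classify", "enrich",
    "trios", "compare")))

  if (!"simulate" %in% stages)
    stop_("the simulate stage is required for a synthetic run")
  ann <- generate_annotation(config$n_cpgs, config$n_genes,
                             config$chrom_lengths, seed = sseed("simulate"),
                             window_bp = config$window_bp)
  covars <- generate_covariates(config$n_samples, config$n_cohorts,
                                seed = sseed("simulate") + 1L)
  omics <- generate_omics(ann$cpgs, ann$genes, covars, config$effect_spec,
                          seed = sseed("simulate") + 2L,
                          window_bp = config$window_bp)
  geno <- NULL
  if ("trios" %in% stages) {
    geno <- generate_genotypes(omics, ann$cpgs, config$chain_spec,
                               seed = sseed("simulate") + 3L)
    omics$meth <- geno$meth; omics$expr <- geno$expr; omics$truth <- geno$truth
  }
  out$annotation <- ann
  out$covars <- covars
  out$omics <- omics

  if (!"pair" %in% stages) return(.finish_run(out, run_dir))
  pairs <- pair_cis(ann$cpgs, ann$genes, window_bp = config$window_bp)
  out$pairs <- pairs

  if (!"discover" %in% stages && !"associate" %in% stages)
    return(.finish_run(out, run_dir))
  disc <- eqtm_discover(pairs, omics$meth, omics$expr, covars,
                        model = config$model, n_perm = config$n_perm,
                        alpha = config$alpha, seed = sseed("discover"))
  out$assoc <- disc$assoc
  out$discovery <- disc
  out$eqtms <- disc$eqtms

  if ("classify" %in% stages) {
    out$ecpg_types <- classify_ecpgs(disc$eqtms)
    out$summary <- summarize_catalogue(disc$eqtms)
  }
  if ("enrich" %in% stages) {
    is_ecpg <- ann$cpgs$cpg_id %in% disc$eqtms$cpg_id
    meta <- simulate_cpg_metadata(ann$cpgs, is_ecpg, seed = sseed("enrich"))
    enr <- data.table::rbindlist(lapply(
      c("state_TssA", "state_Enh", "state_Tx", "state_ReprPC", "state_Quies"),
      function(col) tryCatch(
        suppressWarnings(chisq_enrichment(is_ecpg, meta[[col]], category = col)),
        error = function(e) NULL)))
    out$cpg_metadata <- meta
    out$enrichment <- enr
  }
  if ("trios" %in% stages && !is.null(geno)) {
    cand_me <- omics$truth[mechanism == "snp_driven",
                           .(snp_id, target_id = cpg_id)]
    cand_eq <- omics$truth[mechanism == "snp_driven",
                           .(snp_id, target_id = gene_id)]
    if (nrow(cand_me) > 0) {
      meqtls <- run_qtl_scan(geno$geno$dosage, omics$meth, covars,
                             kind = "meQTL", candidates = cand_me,
                             model = config$model)
      eqtls <- run_qtl_scan(geno$geno$dosage, omics$expr, covars,
                            kind = "eQTL", candidates = cand_eq,
                            model = config$model)
      trios <- build_trios(meqtls, disc$eqtms, eqtls,
                           p_thresh = config$p_thresh_qtl)
      out$meqtls <- meqtls; out$eqtls <- eqtls
      out$trios <- trios
      out$trio_summary <- trio_summary(trios)
    }
  }
  if ("compare" %in% stages && nrow(disc$eqtms) > 0) {
    child <- disc$eqtms[, .(cpg_id, symbol = gene_id, beta, p,
                            source = "CHILD")]
    sim <- simulate_adult_catalogue(child, config$frac_shared_adult,
                                    seed = sseed("compare"))
    child_d <- dedupe_min_p(child)
    adult_d <- dedupe_min_p(sim$adult)
    cls <- classify_shared(child_d, adult_d, config$p_thresh_shared)
    matched <- match_catalogues(child_d, adult_d[p < config$p_thresh_shared])
    out$adult_compare <- list(classified = cls,
                              stats = shared_effect_stats(matched))
  }
  .finish_run(out, run_dir)
}

.finish_run <- function(out, run_dir) {
  if (is.null(run_dir)) return(out)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(obj, name) {
    p <- file.path(run_dir, name)
    write_table(obj, p)
    files <<- c(files, p)
  }
  if (!is.null(out$pairs)) wt(out$pairs, "pairs.tsv")
  if (!is.null(out$assoc)) wt(out$assoc, "associations.tsv")
  if (!is.null(out$eqtms)) wt(out$eqtms, "eqtm_catalogue.tsv")
  if (!is.null(out$ecpg_types)) wt(out$ecpg_types, "ecpg_types.tsv")
  if (!is.null(out$enrichment)) wt(out$enrichment, "enrichment.tsv")
  if (!is.null(out$trios)) wt(out$trios, "trios.tsv")
  if (!is.null(out$adult_compare))
    wt(out$adult_compare$classified, "adult_sharing.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("eqtmr")),
    r_version = as.character(getRversion()),
    config = out$config,
    skipped_stages = setdiff(c("simulate", "pair", "associate", "discover",
                               "classify", "enrich", "trios", "compare"),
                             out$config$stages),
    digests = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  out
}
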