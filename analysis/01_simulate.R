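# Stage 1: simulate the study — annotation, covariates, methylation,
# expression, and genotypes with planted ground truth.

source("analysis/00_config.R")

ann <- generate_annotation(cfg$n_cpgs, cfg$n_genes, cfg$chrom_lengths,
                           seed = stage_seed(1L), window_bp = cfg$window_bp)
covars <- generate_covariates(cfg$n_samples, cfg$n_cohorts,
                              seed = stage_seed(2L))
omics <- generate_omics(ann$cpgs, ann$genes, covars, cfg$effect_spec,
                        seed = stage_seed(3L), window_bp = cfg$window_bp)
geno <- generate_genotypes(omics, ann$cpgs, cfg$chain_spec,
                           seed = stage_seed(4L))

save_table(ann$cpgs, "cpgs.tsv")
save_table(ann$genes, "genes.tsv")
save_table(covars, "covariates.tsv")
save_table(geno$truth, "truth.tsv")

as_dt <- function(m) data.table(id = rownames(m), m, check.names = FALSE)
save_table(as_dt(geno$meth), "methylation.tsv")
save_table(as_dt(geno$expr), "expression.tsv")
save_table(as_dt(geno$geno$dosage), "dosage.tsv")
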