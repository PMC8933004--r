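# Stage 7: meQTL and eQTL scans for chain SNPs, trio assembly, and the
# direction-consistency summary.

source("analysis/00_config.R")

read_mat <- function(name) {
  dt <- fread(file.path(results_dir, name))
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

meth <- read_mat("methylation.tsv")
expr <- read_mat("expression.tsv")
dosage <- read_mat("dosage.tsv")
covars <- fread(file.path(results_dir, "covariates.tsv"))
truth <- fread(file.path(results_dir, "truth.tsv"))
eqtms <- fread(file.path(results_dir, "eqtm_catalogue.tsv"))

chains <- truth[mechanism == "snp_driven"]
meqtls <- run_qtl_scan(dosage, meth, covars, "meQTL",
                       candidates = chains[, .(snp_id, target_id = cpg_id)],
                       model = cfg$model)
eqtls <- run_qtl_scan(dosage, expr, covars, "eQTL",
                      candidates = chains[, .(snp_id, target_id = gene_id)],
                      model = cfg$model)
save_table(meqtls, "meqtls.tsv")
save_table(eqtls, "eqtls.tsv")

trios <- build_trios(meqtls, eqtms, eqtls, p_thresh = cfg$p_thresh_qtl)
save_table(trios, "trios.tsv")
s <- trio_summary(trios)
message(sprintf("%d trios (%d consistent, %d inconsistent) over %d eQTMs",
                nrow(trios), s$n_trios_consistent, s$n_trios_inconsistent,
                s$n_unique_eqtms))
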