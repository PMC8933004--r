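# Stage 6: functional enrichment of eCpGs against simulated CpG metadata
# (chromatin-state flags, island position, variability, reliability).

source("analysis/00_config.R")

cpgs <- fread(file.path(results_dir, "cpgs.tsv"))
eqtms <- fread(file.path(results_dir, "eqtm_catalogue.tsv"))
is_ecpg <- cpgs$cpg_id %in% eqtms$cpg_id

meta <- simulate_cpg_metadata(cpgs, is_ecpg, seed = stage_seed(6L))
save_table(meta, "cpg_metadata.tsv")

state_cols <- grep("^state_", names(meta), value = TRUE)
enr <- rbindlist(lapply(state_cols, function(col)
  chisq_enrichment(is_ecpg, meta[[col]], category = col)))
save_table(enr, "enrichment.tsv")

meth <- fread(file.path(results_dir, "methylation.tsv"))
median_beta <- apply(as.matrix(meth[, -1]), 1, median)
lvl <- methylation_level_category(median_beta)
lvl_enr <- rbindlist(lapply(levels(lvl), function(l)
  chisq_enrichment(is_ecpg, lvl == l, category = paste0("meth_", l))))
save_table(lvl_enr, "enrichment_methylation_level.tsv")

w <- wilcoxon_compare(meta$icc, is_ecpg)
message(sprintf("eCpG vs non-eCpG ICC: median diff %.3f (p = %.3g)",
                w$median_diff, w$p))
reliable <- reliability_filter(meta)
message(sprintf("%d of %d CpGs pass the ICC > 0.4 reliability filter",
                nrow(reliable), nrow(meta)))
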