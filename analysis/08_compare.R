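# Stage 8: compare the child catalogue against a simulated adult catalogue
# and report age sharing and effect concordance.

source("analysis/00_config.R")

eqtms <- fread(file.path(results_dir, "eqtm_catalogue.tsv"))
child <- eqtms[, .(cpg_id, symbol = gene_id, beta, p, source = "CHILD")]

sim <- simulate_adult_catalogue(child, cfg$frac_shared_adult,
                                seed = stage_seed(8L))
child_d <- dedupe_min_p(child)
adult_d <- dedupe_min_p(sim$adult)

cls <- classify_shared(child_d, adult_d, cfg$p_thresh_shared)
save_table(cls, "adult_sharing.tsv")

matched <- match_catalogues(child_d, adult_d[p < cfg$p_thresh_shared])
stats <- shared_effect_stats(matched)
jsonlite::write_json(stats, file.path(results_dir, "adult_effect_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf(
  "%.1f%% of child eQTMs age-shared; direction agreement %.1f%%; r = %.3f",
  100 * mean(cls$sharing == "age_shared"), stats$pct_same_direction,
  stats$pearson_r))
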