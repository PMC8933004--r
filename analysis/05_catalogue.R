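# Stage 5: classify eCpGs and summarize the catalogue.

source("analysis/00_config.R")

eqtms <- fread(file.path(results_dir, "eqtm_catalogue.tsv"))

types <- classify_ecpgs(eqtms)
save_table(types, "ecpg_types.tsv")

s <- summarize_catalogue(eqtms)
jsonlite::write_json(s, file.path(results_dir, "catalogue_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf(
  "%d eQTMs; %.1f%% inverse; median |TSS distance| %.0f bp; %.1f%% within 250 kb",
  s$n_eqtms, s$pct_inverse, s$median_abs_dist, s$pct_within_250kb))

trend <- distance_effect_trend(eqtms)
message(sprintf("effect-vs-distance slope %.4f (p = %.3g, n = %d)",
                trend$slope, trend$p, trend$n))
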