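# data.table non-standard-evaluation columns
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", ".ord",
  "cpg_id", "gene_id", "snp_id", "sample_id", "symbol", "source",
  "chrom", "pos", "start", "end", "strand",
  "beta", "se", "tstat", "p", "log_p", "p_adj", "p_emp", "min_p",
  "min_log_p", "signed_dist", "true_beta", "mechanism", "nominal_p",
  "direction", "log2fc_per_10pct", "n_egenes", "n_inv", "n_pos",
  "multiplicity", "significant", "same_symbol", "is_eqtm", "relpos",
  "icc", "heritability_total", "heritability_snp", "island_rel",
  "age_change", "maf", "snp_effect_on_meth", "b_meqtl", "b_eqtm",
  "b_eqtl", "consistent", "target_id", "beta_child", "beta_adult",
  "p_adult", "sharing", "cohort", "cell_gran", "n_used", "n_genes",
  "n_cpgs", "a", "b", "converged", "i.true_beta", "q25", "q75",
  "sex", "age", "cell_nk", "cell_b", "cell_cd4t", "cell_cd8t",
  "cell_mono"
))
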