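# Shared configuration for the numbered analysis scripts. Each script is a
# thin driver over the eqtmr package: run them in order from the repository
# root; tables land under results/.

suppressPackageStartupMessages(library(eqtmr))
suppressPackageStartupMessages(library(data.table))

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

config_path <- file.path(results_dir, "config.json")
if (!file.exists(config_path)) {
  # stronger-than-default chains so the trio stage is informative at this
  # problem size: the SNP signal must survive attenuation through
  # beta-scale methylation and expression noise to clear the genome-wide
  # QTL cutoff
  write_config(default_config(
    seed = 2024,
    chain_spec = list(n_chains = 20, snp_effect_on_meth = 1.5,
                      maf_range = c(0.1, 0.5), n_null_snps = 20)),
    config_path)
}
cfg <- read_config(config_path)

save_table <- function(dt, name) {
  p <- file.path(results_dir, name)
  fwrite(dt, p, sep = "\t")
  message("wrote ", p, " (", nrow(dt), " rows)")
  invisible(p)
}

stage_seed <- function(stream) derive_seed(cfg$seed, stream)
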