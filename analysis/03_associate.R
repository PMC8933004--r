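# Stage 3: covariate-adjusted linear model for every candidate pair.

source("analysis/00_config.R")

read_mat <- function(name) {
  dt <- fread(file.path(results_dir, name))
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

pairs <- fread(file.path(results_dir, "pairs.tsv"))
meth <- read_mat("methylation.tsv")
expr <- read_mat("expression.tsv")
covars <- fread(file.path(results_dir, "covariates.tsv"))

assoc <- run_model(pairs, meth, expr, covars, model = cfg$model)
save_table(assoc, "associations.tsv")
message(sprintf("%d associations; %d with p < 1e-4; %.1f%% inverse",
                nrow(assoc), sum(assoc$p < 1e-4),
                100 * mean(assoc$beta < 0)))
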