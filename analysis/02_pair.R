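# Stage 2: pair every autosomal CpG with the genes whose TSS lies within
# the cis window.

source("analysis/00_config.R")

cpgs <- fread(file.path(results_dir, "cpgs.tsv"))
genes <- fread(file.path(results_dir, "genes.tsv"))

pairs <- pair_cis(cpgs, genes, window_bp = cfg$window_bp)
save_table(pairs, "pairs.tsv")
counts <- pair_counts(pairs)
save_table(counts$per_cpg, "pair_counts_per_cpg.tsv")
save_table(counts$per_gene, "pair_counts_per_gene.tsv")
message(sprintf("%d candidate pairs; median |distance| %.0f bp",
                nrow(pairs), median(abs(pairs$signed_dist))))
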