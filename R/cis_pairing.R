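#' Transcription start site of a gene, strand-aware
#'
#' The TSS is the annotated start coordinate for genes on the + strand and
#' the annotated end coordinate for genes on the - strand.
#'
#' @param genes gene annotation table with `start`, `end`, `strand`.
#' @return integer vector of TSS positions (bp, 1-based).
#' @export
tss <- function(genes) {
  if (!all(genes$strand %in% c("+", "-")))
    stop_("unknown strand value: %s",
          paste(setdiff(genes$strand, c("+", "-")), collapse = ", "))
  if (any(genes$start > genes$end)) stop_("gene start must be <= end")
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end))
}

#' Signed CpG-to-TSS distance
#'
#' Distance is oriented by the gene's transcriptional direction: positive
#' means the CpG lies downstream of the TSS (inside or beyond the gene in
#' its direction of transcription), negative means upstream.
#'
#' @param cpg_pos CpG position(s), bp.
#' @param genes one-row-per-position gene annotation (recycled rules do not
#'   apply; lengths must match or genes must have one row).
#' @param cpg_chrom optional chromosome labels for the CpGs; when given,
#'   a CpG on a different chromosome than its gene is an error.
#' @return integer vector of signed distances.
#' @export
signed_distance <- function(cpg_pos, genes, cpg_chrom = NULL) {
  t <- tss(genes)
  if (!is.null(cpg_chrom) && any(cpg_chrom != genes$chrom))
    stop_("CpG and gene lie on different chromosomes")
  as.integer(ifelse(genes$strand == "+", cpg_pos - t, t - cpg_pos))
}

#' Enumerate autosomal cis CpG-gene candidate pairs
#'
#' Pairs every autosomal CpG with every gene whose TSS lies within
#' `window_bp` of it (a window of `2 * window_bp` centered at the TSS).
#' Membership is inclusive (`|signed_dist| <= window_bp`) unless
#' `strict = TRUE`. Uses an interval overlap index; a brute-force double
#' loop gives identical results and serves as the test oracle.
#'
#' @param cpgs CpG annotation (`cpg_id`, `chrom`, `pos`).
#' @param genes gene annotation (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param window_bp cis half-window in bp (default 500 kb).
#' @param strict use `<` instead of `<=` at the window boundary.
#' @return `data.table` (cpg_id, gene_id, signed_dist), one row per pair.
#' @export
pair_cis <- function(cpgs, genes, window_bp = 5e5, strict = FALSE) {
  if (window_bp <= 0) stop_("window_bp must be positive")
  cpgs <- cpgs[chrom %in% AUTOSOMES]
  genes <- genes[chrom %in% AUTOSOMES]
  if (nrow(cpgs) == 0 || nrow(genes) == 0) {
    return(data.table::data.table(cpg_id = character(0),
                                  gene_id = character(0),
                                  signed_dist = integer(0)))
  }
  g_tss <- tss(genes)
  gr_win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, g_tss - window_bp), g_tss + window_bp))
  gr_cpg <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos, cpgs$pos))
  ov <- GenomicRanges::findOverlaps(gr_cpg, gr_win)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  d <- ifelse(genes$strand[si] == "+",
              cpgs$pos[qi] - g_tss[si], g_tss[si] - cpgs$pos[qi])
  keep <- if (strict) abs(d) < window_bp else rep(TRUE, length(d))
  out <- data.table::data.table(cpg_id = cpgs$cpg_id[qi][keep],
                                gene_id = genes$gene_id[si][keep],
                                signed_dist = as.integer(d[keep]))
  data.table::setorder(out, cpg_id, gene_id)
  unique(out, by = c("cpg_id", "gene_id"))
}

#' Per-CpG and per-gene pair counts of a candidate pair set
#'
#' @param pairs output of [pair_cis()].
#' @return list with `per_cpg` and `per_gene` count tables and their
#'   medians (the catalogue-overview statistics).
#' @export
pair_counts <- function(pairs) {
  per_cpg <- pairs[, .(n_genes = .N), by = cpg_id]
  per_gene <- pairs[, .(n_cpgs = .N), by = gene_id]
  list(per_cpg = per_cpg, per_gene = per_gene,
       median_genes_per_cpg = stats::median(per_cpg$n_genes),
       median_cpgs_per_gene = stats::median(per_gene$n_cpgs))
}
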