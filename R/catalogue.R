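#' Classify eCpGs by multiplicity and effect direction
#'
#' eCpGs are typed along two axes: `mono` (one eGene) vs `multi` (two or
#' more), and `inverse` / `positive` when all effects share a sign vs
#' `bivalent` when signs mix. Bivalent eCpGs are necessarily multi.
#'
#' @param records eQTM record table from [call_eqtms()].
#' @return `data.table` (cpg_id, n_egenes, multiplicity, direction).
#' @export
classify_ecpgs <- function(records) {
  out <- records[, .(
    n_egenes = data.table::uniqueN(gene_id),
    n_inv = sum(beta < 0), n_pos = sum(beta >= 0)
  ), by = cpg_id]
  out[, multiplicity := ifelse(n_egenes == 1, "mono", "multi")]
  out[, direction := data.table::fcase(
    n_inv > 0 & n_pos > 0, "bivalent",
    n_inv > 0, "inverse",
    default = "positive")]
  out[, c("n_inv", "n_pos") := NULL]
  out[]
}

#' Summary statistics of an eQTM catalogue
#'
#' Computes the catalogue-overview numbers: counts of eQTMs, eCpGs and
#' eGenes; the fraction of inverse associations; the median and IQR of the
#' signed CpG-to-TSS distance (overall and by direction) and of its
#' absolute value; the fraction of eQTMs within 250 kb of the TSS; and the
#' absolute effect-size distribution on the log2-fold-change-per-0.1
#' scale. Quantiles use linear interpolation (R type 7).
#'
#' @param records eQTM record table.
#' @return named list of summary statistics; an empty catalogue yields
#'   zero counts and NA statistics.
#' @export
summarize_catalogue <- function(records) {
  if (nrow(records) == 0) {
    return(list(n_eqtms = 0L, n_ecpgs = 0L, n_egenes = 0L,
                pct_inverse = NA_real_, median_signed_dist = NA_real_,
                iqr_signed_dist = c(NA_real_, NA_real_),
                median_abs_dist = NA_real_,
                median_dist_by_direction = NULL,
                pct_within_250kb = NA_real_,
                median_abs_effect = NA_real_, min_abs_effect = NA_real_,
                max_abs_effect = NA_real_, pct_effect_lt_0.5 = NA_real_))
  }
  eff <- abs(effect_log2fc_per_10pct(records$beta))
  by_dir <- records[, .(median_signed_dist = as.numeric(stats::median(signed_dist)),
                        q25 = as.numeric(stats::quantile(signed_dist, 0.25)),
                        q75 = as.numeric(stats::quantile(signed_dist, 0.75))),
                    by = direction]
  list(
    n_eqtms = nrow(records),
    n_ecpgs = data.table::uniqueN(records$cpg_id),
    n_egenes = data.table::uniqueN(records$gene_id),
    pct_inverse = 100 * mean(records$beta < 0),
    median_signed_dist = stats::median(records$signed_dist),
    iqr_signed_dist = unname(stats::quantile(records$signed_dist, c(0.25, 0.75))),
    median_abs_dist = stats::median(abs(records$signed_dist)),
    median_dist_by_direction = by_dir[],
    pct_within_250kb = 100 * mean(abs(records$signed_dist) < 250e3),
    median_abs_effect = stats::median(eff),
    min_abs_effect = min(eff),
    max_abs_effect = max(eff),
    pct_effect_lt_0.5 = 100 * mean(eff < 0.5)
  )
}

#' Trend of absolute effect size with distance from the TSS
#'
#' Ordinary least squares of the absolute effect size (|log2FC per 0.1
#' methylation|) on log10 of the absolute CpG-to-TSS distance. Records at
#' distance zero are assigned |distance| = 1 bp before the log by default
#' (`drop_zero = TRUE` drops them instead).
#'
#' @param records eQTM record table.
#' @param drop_zero drop zero-distance records instead of clamping to 1 bp.
#' @return list: `slope`, `p`, `n`.
#' @export
distance_effect_trend <- function(records, drop_zero = FALSE) {
  d <- abs(records$signed_dist)
  eff <- abs(effect_log2fc_per_10pct(records$beta))
  if (drop_zero) {
    keep <- d > 0
    d <- d[keep]; eff <- eff[keep]
  } else {
    d <- pmax(d, 1)
  }
  if (length(d) < 3 || all(d == d[1]))
    stop_("need at least 3 records with positive, non-constant distances")
  fit <- stats::lm(eff ~ log10(d))
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), p = unname(sm[2, 4]), n = length(d))
}

#' Concordance between eGenes and CpG-proximity gene annotation
#'
#' Asks how much of the catalogue a closest-gene annotation would capture:
#' a CpG-gene pair is "comparable" when the CpG's annotated symbol set and
#' the gene's symbol set intersect; an eCpG is "concordant" when at least
#' one of its eGenes shares a symbol with it. Same-symbol enrichment of
#' eQTMs is a 2x2 chi-square over the full candidate universe, and the
#' optional relative-position analysis expands comparable pairs to one
#' entry per (pair, relative position) and tests each position's
#' enrichment within the expanded set.
#'
#' @param records eQTM record table.
#' @param cpg_symbols named list cpg_id -> character vector of symbols.
#' @param gene_symbols named list gene_id -> character vector of symbols.
#' @param all_pairs full candidate pair universe from [pair_cis()].
#' @param relpos optional `data.table` (cpg_id, gene_id, relpos) with one
#'   row per annotated relative gene position of a pair.
#' @return list: `n_comparable_pairs`, `n_ecpgs_comparable`,
#'   `n_ecpgs_concordant`, `pct_concordant`, `same_symbol_enrichment`
#'   (an [chisq_enrichment()] result), `n_expanded`, `relpos_enrichment`.
#' @export
closest_gene_concordance <- function(records, cpg_symbols, gene_symbols,
                                     all_pairs, relpos = NULL) {
  shares <- function(cpg, gene) {
    cs <- cpg_symbols[[cpg]]
    length(cs) > 0 && length(intersect(cs, gene_symbols[[gene]])) > 0
  }
  pairs <- data.table::copy(all_pairs)
  pairs[, same_symbol := mapply(shares, cpg_id, gene_id)]
  pairs[, is_eqtm := FALSE]
  pairs[records, on = c("cpg_id", "gene_id"), is_eqtm := TRUE]

  comparable <- pairs[same_symbol == TRUE]
  ecpgs <- unique(records$cpg_id)
  annotated <- ecpgs[vapply(ecpgs, function(cg)
    length(cpg_symbols[[cg]]) > 0, logical(1))]
  # comparable eCpGs: annotated to a symbol that exists on the gene side
  gene_universe <- unique(unlist(gene_symbols))
  comparable_ecpgs <- annotated[vapply(annotated, function(cg)
    length(intersect(cpg_symbols[[cg]], gene_universe)) > 0, logical(1))]
  concordant <- comparable_ecpgs[vapply(comparable_ecpgs, function(cg) {
    any(vapply(records[cpg_id == cg, gene_id], function(g) shares(cg, g),
               logical(1)))
  }, logical(1))]

  # degenerate toy universes (e.g. every pair same-symbol) carry no
  # enrichment information; report NULL rather than fail
  enr <- tryCatch(
    suppressWarnings(chisq_enrichment(pairs$is_eqtm, pairs$same_symbol,
                                      category = "same_symbol",
                                      reference = "all pairs")),
    error = function(e) NULL)

  relpos_enr <- NULL
  n_expanded <- NA_integer_
  if (!is.null(relpos)) {
    expanded <- relpos[comparable, on = c("cpg_id", "gene_id"), nomatch = NULL]
    n_expanded <- nrow(expanded)
    relpos_enr <- data.table::rbindlist(lapply(
      sort(unique(expanded$relpos)), function(rp) tryCatch(
        suppressWarnings(chisq_enrichment(expanded$is_eqtm,
                                          expanded$relpos == rp,
                                          category = rp,
                                          reference = "expanded entries")),
        error = function(e) NULL)))
  }
  list(n_comparable_pairs = nrow(comparable),
       n_ecpgs_comparable = length(comparable_ecpgs),
       n_ecpgs_concordant = length(concordant),
       pct_concordant = 100 * length(concordant) /
         max(1L, length(comparable_ecpgs)),
       same_symbol_enrichment = enr,
       n_expanded = n_expanded,
       relpos_enrichment = relpos_enr)
}
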