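#' Chi-square enrichment of a CpG category among target CpGs
#'
#' Builds the 2x2 table of target status (e.g. eCpG vs non eCpG) against a
#' category flag and tests independence with Pearson's chi-square without
#' continuity correction. The odds ratio is `(a*d)/(b*c)`; when any cell is
#' zero the Haldane correction (adding 0.5 to every cell) is applied to the
#' odds ratio only, never to the test.
#'
#' @param target_flags logical per CpG: in the target set (e.g. eCpG).
#' @param category_flags logical per CpG: in the annotation category.
#' @param category label stored in the result.
#' @param reference label of the reference group (default "non eCpGs").
#' @param correct apply the continuity correction to the chi-square test.
#' @return one-row `data.table`: category, odds_ratio, p, a, b, c, d,
#'   reference. Cell `a` counts target CpGs in the category.
#' @export
chisq_enrichment <- function(target_flags, category_flags,
                             category = "category", reference = "non eCpGs",
                             correct = FALSE) {
  if (length(target_flags) != length(category_flags))
    stop_("flag vectors must be aligned")
  if (length(target_flags) < 2) stop_("need at least 2 CpGs")
  target_flags <- as.logical(target_flags)
  category_flags <- as.logical(category_flags)
  if (length(unique(target_flags)) < 2 || length(unique(category_flags)) < 2)
    stop_("degenerate 2x2 table: a flag vector is constant")
  a <- sum(target_flags & category_flags)
  b <- sum(target_flags & !category_flags)
  c_ <- sum(!target_flags & category_flags)
  d <- sum(!target_flags & !category_flags)
  tab <- matrix(c(a, c_, b, d), 2)
  test <- stats::chisq.test(tab, correct = correct)
  or <- if (min(tab) == 0) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  data.table::data.table(category = category, odds_ratio = or,
                         p = unname(test$p.value),
                         a = a, b = b, c = c_, d = d,
                         reference = reference)
}

#' Categorize CpGs by median methylation level
#'
#' Levels: low (0 to 0.3, inclusive), medium (above 0.3 up to 0.7), high
#' (above 0.7 up to 1).
#'
#' @param median_beta numeric vector of median beta values in \[0,1\].
#' @return factor with levels low, medium, high.
#' @export
methylation_level_category <- function(median_beta) {
  if (any(median_beta < 0 | median_beta > 1, na.rm = TRUE))
    stop_("median beta values must lie in [0,1]")
  cut(median_beta, breaks = c(0, 0.3, 0.7, 1),
      labels = c("low", "medium", "high"),
      include.lowest = TRUE, right = TRUE)
}

#' Wilcoxon rank-sum comparison of a continuous variable between two groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) test, plus the difference of group
#' medians (group TRUE minus group FALSE).
#'
#' @param values numeric vector.
#' @param group logical vector splitting the values into two groups.
#' @return list: `p`, `median_diff`, group sizes.
#' @export
wilcoxon_compare <- function(values, group) {
  group <- as.logical(group)
  if (!any(group) || !any(!group)) stop_("both groups must be non-empty")
  a <- values[group]; b <- values[!group]
  p <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  list(p = unname(p),
       median_diff = stats::median(a) - stats::median(b),
       n_a = length(a), n_b = length(b))
}

#' Linear trend of heritability with the number of eGenes per eCpG
#'
#' OLS of a per-CpG heritability measure (outcome) on the number of eGenes
#' the CpG is associated with.
#'
#' @param heritability numeric per CpG.
#' @param n_egenes integer per CpG.
#' @return list: `slope` (heritability change per additional eGene), `p`,
#'   `n`.
#' @export
heritability_trend <- function(heritability, n_egenes) {
  if (length(unique(n_egenes)) < 3)
    stop_("need at least 3 distinct eGene counts")
  fit <- stats::lm(heritability ~ n_egenes)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), p = unname(sm[2, 4]),
       n = length(heritability))
}

#' Filter CpGs to reliably measured probes
#'
#' Keeps CpGs whose probe intraclass correlation coefficient strictly
#' exceeds the threshold (default 0.4). CpGs with missing ICC are dropped
#' and their count reported as a message.
#'
#' @param cpgs CpG table with an `icc` column.
#' @param icc_threshold reliability cutoff (strict `>`).
#' @return the reliable subset of `cpgs`.
#' @export
reliability_filter <- function(cpgs, icc_threshold = 0.4) {
  if (!"icc" %in% names(cpgs)) stop_("cpgs must carry an 'icc' column")
  n_missing <- sum(is.na(cpgs$icc))
  if (n_missing > 0)
    message(sprintf("dropping %d CpGs without an ICC estimate", n_missing))
  cpgs[!is.na(icc) & icc > icc_threshold]
}
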