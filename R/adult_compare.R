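#' Explode multi-symbol catalogue entries to one row per symbol
#'
#' Entries whose `symbol` field holds several symbols separated by `sep`
#' become one row per symbol; single-symbol rows pass through unchanged.
#'
#' @param entries catalogue table with columns cpg_id, symbol, beta, p,
#'   source.
#' @param sep symbol separator (default ";").
#' @return exploded `data.table`.
#' @export
explode_symbols <- function(entries, sep = ";") {
  out <- entries[, .(symbol = unlist(strsplit(symbol, sep, fixed = TRUE))),
                 by = .(cpg_id, beta, p, source)]
  data.table::setcolorder(out, c("cpg_id", "symbol", "beta", "p", "source"))
  out[]
}

#' Deduplicate catalogue entries by minimum p-value
#'
#' When several rows share a (cpg_id, symbol, source) key — e.g. several
#' probes or transcript clusters mapping to the same gene symbol — only
#' the row with the smallest p-value is kept; ties keep the first row in
#' input order.
#'
#' @param entries catalogue table (cpg_id, symbol, beta, p, source).
#' @return deduplicated `data.table`.
#' @export
dedupe_min_p <- function(entries) {
  dt <- data.table::copy(entries)
  dt[, .ord := .I]
  dt <- dt[order(p, .ord)]
  out <- dt[!duplicated(dt[, .(cpg_id, symbol, source)])]
  out <- out[order(.ord)]
  out[, .ord := NULL]
  out[]
}

#' Classify child catalogue entries as age-shared or cohort-specific
#'
#' A child eQTM is `age_shared` when the same (cpg_id, symbol) appears in
#' any adult source with p-value below `p_thresh`, and `cohort_specific`
#' otherwise. Both tables should be deduplicated first
#' ([dedupe_min_p()]).
#'
#' @param child child catalogue entries.
#' @param adult adult catalogue entries (one or more sources).
#' @param p_thresh adult significance threshold (default 1e-5).
#' @return `child` with a `sharing` column appended.
#' @export
classify_shared <- function(child, adult, p_thresh = 1e-5) {
  hits <- unique(adult[p < p_thresh, .(cpg_id, symbol)])
  out <- data.table::copy(child)
  out[, sharing := "cohort_specific"]
  out[hits, on = c("cpg_id", "symbol"), sharing := "age_shared"]
  out[]
}

#' Match child and adult entries on CpG and symbol
#'
#' @param child,adult deduplicated catalogue tables.
#' @return `data.table` of matched pairs with `beta_child`, `beta_adult`,
#'   `p_adult`, `source`.
#' @export
match_catalogues <- function(child, adult) {
  m <- child[, .(cpg_id, symbol, beta_child = beta)][
    adult[, .(cpg_id, symbol, beta_adult = beta, p_adult = p, source)],
    on = c("cpg_id", "symbol"), nomatch = NULL]
  m[]
}

#' Direction agreement and effect correlation of matched eQTMs
#'
#' @param matched output of [match_catalogues()] (needs `beta_child`,
#'   `beta_adult`).
#' @return list: `pct_same_direction` (percent of matches with equal
#'   effect signs) and `pearson_r` (NA when fewer than 3 matches).
#' @export
shared_effect_stats <- function(matched) {
  if (nrow(matched) == 0)
    return(list(pct_same_direction = NA_real_, pearson_r = NA_real_,
                n = 0L))
  same <- sign(matched$beta_child) == sign(matched$beta_adult)
  r <- if (nrow(matched) >= 3)
    stats::cor(matched$beta_child, matched$beta_adult) else NA_real_
  list(pct_same_direction = 100 * mean(same), pearson_r = r,
       n = nrow(matched))
}

#' Simulate an adult eQTM catalogue from a child catalogue
#'
#' Fabricates an adult-cohort comparison table for testing: a configurable
#' fraction of child entries is "shared" (present in the adult source at a
#' significant p-value, with an effect size correlated with the child one),
#' the rest is absent or present only at non-significant p-values.
#' Clearly synthetic — no real adult catalogue is used.
#'
#' @param child child catalogue entries (cpg_id, symbol, beta, p, source).
#' @param frac_shared fraction of child entries planted as age-shared.
#' @param effect_cor correlation of adult vs child effect sizes among
#'   shared entries.
#' @param source adult source label.
#' @param seed integer seed.
#' @return list: `adult` entry table, `truth` (logical per child row:
#'   planted as shared).
#' @export
simulate_adult_catalogue <- function(child, frac_shared = 0.3,
                                     effect_cor = 0.8, source = "ADULT",
                                     seed = 1) {
  set.seed(seed)
  n <- nrow(child)
  shared <- stats::runif(n) < frac_shared
  sd_b <- stats::sd(child$beta)
  if (!is.finite(sd_b) || sd_b == 0) sd_b <- 1
  beta_adult <- effect_cor * child$beta +
    sqrt(1 - effect_cor^2) * stats::rnorm(n, 0, sd_b)
  adult <- data.table::data.table(
    cpg_id = child$cpg_id, symbol = child$symbol,
    beta = beta_adult,
    p = ifelse(shared, 10^stats::runif(n, -12, -6), 10^stats::runif(n, -4, 0)),
    source = source)
  # keep only a subset of the non-shared rows so some entries are truly absent
  keep <- shared | stats::runif(n) < 0.5
  list(adult = adult[keep], truth = shared)
}
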