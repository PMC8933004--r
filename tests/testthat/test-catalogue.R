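make_records <- function(cpg, gene, beta, dist = 0L, p = 1e-8) {
  data.table::data.table(cpg_id = cpg, gene_id = gene, beta = beta,
                         log2fc_per_10pct = beta * 0.1, se = 0.1, p = p,
                         signed_dist = as.integer(dist),
                         direction = ifelse(beta < 0, "inverse", "positive"),
                         nominal_p = 1e-4)
}

test_that("eCpG classification covers mono/multi and direction types", {
  rec <- make_records(
    cpg = c("m_inv", "m_pos", "multi_inv", "multi_inv",
            "biv", "biv", "biv"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    beta = c(-1, 2, -1, -2, -1, 2, 3))
  cls <- classify_ecpgs(rec)
  expect_equal(cls[cpg_id == "m_inv", multiplicity], "mono")
  expect_equal(cls[cpg_id == "m_inv", direction], "inverse")
  expect_equal(cls[cpg_id == "m_pos", direction], "positive")
  expect_equal(cls[cpg_id == "multi_inv", multiplicity], "multi")
  expect_equal(cls[cpg_id == "multi_inv", direction], "inverse")
  expect_equal(cls[cpg_id == "biv", direction], "bivalent")
  # bivalent implies multi; totals add up
  expect_true(all(cls[direction == "bivalent", multiplicity] == "multi"))
  expect_equal(nrow(cls), data.table::uniqueN(rec$cpg_id))
  expect_equal(sum(cls$multiplicity == "mono") + sum(cls$multiplicity == "multi"),
               nrow(cls))
})

test_that("classification matches a brute-force group-by on random catalogues", {
  set.seed(111)
  rec <- make_records(
    cpg = sample(sprintf("cg%02d", 1:30), 120, replace = TRUE),
    gene = sprintf("g%03d", 1:120),
    beta = rnorm(120))
  cls <- classify_ecpgs(rec)
  for (cg in sample(unique(rec$cpg_id), 10)) {
    sub <- rec[cpg_id == cg]
    expect_equal(cls[cpg_id == cg, n_egenes], length(unique(sub$gene_id)))
    dir <- if (all(sub$beta < 0)) "inverse"
           else if (all(sub$beta >= 0)) "positive" else "bivalent"
    expect_equal(cls[cpg_id == cg, direction], dir)
  }
})

test_that("catalogue summaries match their definitions", {
  one <- make_records("c1", "g1", -0.5, dist = 10000L)
  s <- summarize_catalogue(one)
  expect_equal(s$pct_inverse, 100)
  expect_equal(s$median_signed_dist, 10000)

  sym <- make_records(c("c1", "c2"), c("g1", "g2"), c(-1, 1),
                      dist = c(-5000L, 5000L))
  expect_equal(summarize_catalogue(sym)$pct_inverse, 50)

  set.seed(113)
  rec <- make_records(sprintf("c%03d", 1:200), sprintf("g%03d", 1:200),
                      rnorm(200), dist = as.integer(runif(200, -5e5, 5e5)))
  s <- summarize_catalogue(rec)
  expect_equal(s$n_eqtms, 200)
  expect_equal(s$pct_inverse, 100 * mean(rec$beta < 0))
  expect_equal(s$median_signed_dist, median(rec$signed_dist))
  expect_equal(s$pct_within_250kb, 100 * mean(abs(rec$signed_dist) < 250e3))
  expect_equal(s$median_abs_effect, median(abs(rec$beta * 0.1)))
  expect_equal(s$pct_effect_lt_0.5, 100 * mean(abs(rec$beta * 0.1) < 0.5))

  empty <- summarize_catalogue(make_records(character(0), character(0),
                                            numeric(0)))
  expect_equal(empty$n_eqtms, 0)
})

test_that("distance-effect trend recovers planted decay and hand OLS", {
  # constant effects: slope ~ 0
  rec <- make_records(sprintf("c%d", 1:50), sprintf("g%d", 1:50),
                      rep(1, 50), dist = as.integer(seq(1e3, 4e5, length = 50)))
  tr <- distance_effect_trend(rec)
  expect_lt(abs(tr$slope), 1e-10)

  # planted decay: |effect| declines with log distance
  set.seed(115)
  d <- as.integer(10^runif(200, 3, 5.6))
  eff <- 10 * (2 - log10(d) / 3) + rnorm(200, 0, 0.2)
  rec2 <- make_records(sprintf("c%d", 1:200), sprintf("g%d", 1:200),
                       eff, dist = d)
  tr2 <- distance_effect_trend(rec2)
  expect_lt(tr2$slope, 0)
  expect_lt(tr2$p, 1e-6)

  # 3-point hand example: effects 10,20,30 at log10(d) = 1,2,3 -> slope 1
  rec3 <- make_records(c("a", "b", "c"), c("g1", "g2", "g3"),
                       c(10, 20, 30), dist = c(10L, 100L, 1000L))
  expect_equal(distance_effect_trend(rec3)$slope, 1, tolerance = 1e-10)

  expect_error(distance_effect_trend(rec3[1:2]), "at least 3")
})

test_that("closest-gene concordance counts and 2x2 enrichment match hand values", {
  # toy universe: 6 pairs, 3 eQTMs
  all_pairs <- data.table::data.table(
    cpg_id = c("c1", "c1", "c2", "c3", "c4", "c5"),
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    signed_dist = 0L)
  rec <- make_records(c("c1", "c2", "c3"), c("g1", "g3", "g4"),
                      c(-1, 1, -2))
  cpg_symbols <- list(c1 = "A", c2 = "B", c3 = character(0),
                      c4 = "E", c5 = "ZZZ")
  gene_symbols <- list(g1 = c("A", "X"), g2 = "C", g3 = "D", g4 = "D",
                       g5 = "E", g6 = "F")
  rep_ <- closest_gene_concordance(rec, cpg_symbols, gene_symbols, all_pairs)
  # comparable pairs: c1-g1 (A) and c4-g5 (E)
  expect_equal(rep_$n_comparable_pairs, 2)
  # comparable eCpGs: c1 (A exists on gene side); c2's B and c3's empty do not
  expect_equal(rep_$n_ecpgs_comparable, 1)
  # concordant: c1, whose eGene g1 carries symbol A
  expect_equal(rep_$n_ecpgs_concordant, 1)
  # 2x2 over 6 pairs: eqtm&same=1, eqtm&diff=2, non&same=1, non&diff=2
  enr <- rep_$same_symbol_enrichment
  expect_equal(c(enr$a, enr$b, enr$c, enr$d), c(1, 2, 1, 2))
  expect_equal(enr$odds_ratio, (1 * 2) / (2 * 1))
})

test_that("relative-position expansion yields one entry per annotated position", {
  all_pairs <- data.table::data.table(
    cpg_id = c("c1", "c2", "c3", "c4"),
    gene_id = c("g1", "g2", "g3", "g4"),
    signed_dist = 0L)
  rec <- make_records(c("c1", "c2"), c("g1", "g2"), c(-1, 1))
  cpg_symbols <- list(c1 = "A", c2 = "B", c3 = "C", c4 = "D")
  gene_symbols <- list(g1 = "A", g2 = "B", g3 = "C", g4 = "D")
  relpos <- data.table::data.table(
    cpg_id = c("c1", "c1", "c2", "c3", "c4"),
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    relpos = c("TSS1500", "body", "body", "body", "TSS200"))
  rep_ <- closest_gene_concordance(rec, cpg_symbols, gene_symbols,
                                   all_pairs, relpos = relpos)
  expect_equal(rep_$n_expanded, 5)  # c1 contributes two entries
  expect_true(rep_$n_expanded >= rep_$n_comparable_pairs)
})
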