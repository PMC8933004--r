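---
title: "Methods: cis-eQTM discovery with CpG-level permutation FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-eQTM discovery with CpG-level permutation FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the multiple-testing
procedure, the synthetic-data generator, and the numerical and design
choices behind `eqtmr`. Nothing here is executed at build time; runnable
numbers live in the test suite and in `scripts/acceptance.R`.

## The association model

For a CpG methylation vector $m$ (beta values in $[0,1]$) and a gene's
log2 expression $y$ over $n$ samples, the package fits

$$ y = \beta m + X\gamma + \varepsilon $$

where $X$ contains an intercept, sex, age, cohort indicators, and five
cell-type proportions (granulocytes are the omitted reference so the
compositional constraint does not make $X$ singular). The pair-level
p-value is the two-sided t-test on $\beta$. Cell adjustment is the
default model; `cell_unadjusted` drops the proportions.

A scan over all candidate pairs does not call `lm()` per pair. By the
Frisch–Waugh–Lovell theorem, regressing the covariate-residualized $y$
on the covariate-residualized $m$ gives exactly the full-model $\beta$,
standard error, and t-statistic with degrees of freedom
$n - \mathrm{rank}(X) - 1$. The engine computes the covariate QR once,
residualizes both matrices, and obtains every pair's statistics from
three accumulated cross-products. The test suite proves equality with
per-pair `lm()`-style fits to $10^{-10}$.

Two numerical choices matter at scale: p-values are carried in natural
log space (`pt(..., log.p = TRUE)`) so extreme associations do not
underflow to zero before the permutation machinery compares them, and
the per-pair fallback path locates the methylation column through the
QR pivot rather than assuming column order.

## Cis pairing

Genes are reduced to their TSS (interval start on the + strand, end on
the − strand). A CpG pairs with every gene on the same autosome whose
TSS lies within ±`window_bp` (500 kb default); the boundary is inclusive
by default, with a `strict` flag for an open window. Signed distance is
CpG minus TSS in the gene's reading direction. Pairing uses interval
overlap (`GenomicRanges::findOverlaps`) and is tested against a
brute-force double loop.

## CpG-level multiple testing

The number of genes per CpG window varies, so pair-level BH would favour
CpGs in gene-dense regions. Instead, error is controlled per CpG:

1. **Permutations.** Expression sample labels are permuted `n_perm`
   times (default 100); one permutation is shared across all genes so
   gene–gene correlation survives. Permutation index 0 is reserved for
   the identity, and each permutation's seed derives deterministically
   from the master seed and the index, so permutations are reproducible
   individually and in any order.
2. **Minimum p per CpG.** Each permutation contributes, per CpG, the
   minimum p-value over that CpG's window — the null of "best
   association this CpG could show by chance".
3. **Beta approximation.** With $k$ independent uniform p-values the
   minimum is $\mathrm{Beta}(1, k)$; correlation among tests within the
   window makes the effective $k$ smaller, so both parameters are
   estimated. The MLE runs as a damped Newton iteration on $(a, b)$
   vectorized across all CpGs (moment starts), with a scalar BFGS refit
   on $(\log a, \log b)$ for rows that do not converge; rows that still
   fail fall back to the rank-based estimate $(r+1)/(n_{perm}+1)$. The
   smooth beta tail is the reason to fit at all: it interpolates below
   the $1/(n_{perm}+1)$ resolution of ranks.
4. **Selection.** Benjamini–Hochberg at $\alpha = 0.05$ over the per-CpG
   empirical p-values selects eCpGs. The genome-wide empirical threshold
   is the midpoint between the largest significant and smallest
   non-significant empirical p (an alternative `largest_significant`
   rule is provided); each significant CpG's nominal pair-level cutoff
   is `qbeta(threshold, a, b)`, and its pairs below that cutoff are the
   eQTMs. Calling is hierarchical: a sub-threshold pair of a
   non-significant CpG is never an eQTM.

The acceptance suite measures the realized false discovery proportion of
this whole procedure on synthetic data with known truth at the stated
operating point (2,000 CpGs, 200 genes, $n = 300$, 10% true CpGs, 100
permutations) and checks the beta-based empirical p against the direct
rank-based one at 1,000 permutations.

## The synthetic generator

The generator is designed to stress the procedure the way real blood
methylation/expression data would, while keeping the truth measurable:

- **Methylation** is logit-normal with a bimodal mixture of latent means
  (hypo-, hyper-, and intermediate-methylated CpGs), matching the
  U-shaped beta-value distribution of array data.
- **Cell composition** is Dirichlet with a concentration profile typical
  of child blood, and both omics load on cell proportions and cohort —
  a real confounder structure, so the covariate adjustment is doing
  actual work in every test.
- **Planted effects**: a fraction `prop_true_cpgs` (default 10%) of CpGs
  receive one true cis effect with $|\beta| \in [1, 2]$, mixed signs,
  and expression noise sd 0.5. True CpGs are sampled with probability
  proportional to methylation variance, reflecting that detectable
  eCpGs are the variable, intermediately methylated ones; a CpG whose
  methylation barely varies cannot carry a detectable effect at any
  plausible sample size, and planting there would only measure the
  generator, not the procedure.
- **SNP chains** act additively on the latent logit-methylation scale
  (keeping beta values in $[0,1]$ without clipping) and propagate to
  expression only through the planted methylation→expression effect, so
  a chain's three effect signs are mutually consistent by construction.

What the generator deliberately does **not** emulate: probe technical
artifacts (cross-reactivity, SNPs under probes), trans effects, spatial
correlation of methylation beyond shared confounders, count-level
expression noise (expression is Gaussian on the log2 scale), and linkage
disequilibrium between SNPs.

## Determinism

Every stochastic component takes an explicit seed. A master seed fans
out to stages and replicates through a fixed integer derivation
(`derive_seed`), so stages are individually reproducible and two
pipeline runs with the same configuration produce byte-identical output
files (verified by MD5 digests recorded in each run's manifest).

## Limitations

- The beta fit assumes the per-CpG minimum-p null is well approximated
  by a beta law; with very few permutations (tens) or pathological
  windows the rank fallback is coarser, and empirical p-values are then
  bounded below by $1/(n_{perm}+1)$.
- The FDR guarantee is about the CpG-level selection; the per-CpG
  nominal cutoffs inherit Monte-Carlo error from both the permutations
  and the beta fit.
- OLS on beta values treats a 0.1 change the same everywhere in
  $[0,1]$; no M-value transform is provided.
- Enrichment tests are marginal 2×2 chi-squares; they do not adjust for
  covariates such as probe density or methylation level, which real
  annotation enrichment would need.
- The adult-comparison module matches on (CpG, symbol) only; it does not
  model platform differences between catalogues beyond a per-entry
  minimum-p dedup.
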