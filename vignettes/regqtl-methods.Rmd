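---
title: "Methods: Bayesian window QTL mapping, eQTL scanning, and their integration"
author: "regqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian window QTL mapping, eQTL scanning, and their integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`regqtl` implements one analysis end to end: map trait-associated 1-Mb QTL
windows with mixture-prior whole-genome regression, map cis/trans eQTL with
per-pair linear regression, intersect the two, prune to tag-SNPs, and emit
signed SNP→gene regulation networks. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design decisions
that were genuinely open.

## The association model

Both GWAS stages fit

$$y = Xb + \sum_{j=1}^{k} a_j \beta_j \delta_j + e,$$

with $y$ the phenotype, $X$ the fixed-effect/covariate design, $a_j$ the
additive genotype code at SNP $j$ (centred at twice the allele frequency),
$\delta_j \sim \mathrm{Bernoulli}(1-\pi)$ the inclusion indicator, and
$e \sim N(0, \sigma^2_e I)$. Under Bayes C all included effects share one
variance $\sigma^2_\beta$; under Bayes B each locus has its own
$\sigma^2_{\beta j} \sim \nu_\beta S^2_\beta / \chi^2_{\nu_\beta}$. The
recommended workflow — and what `run_pipeline()` does — runs Bayes C first
to estimate the genetic and residual variances, then hands those to Bayes B
as priors for the association pass.

Sampling choices that matter:

* **Collapsed inclusion updates.** $\delta_j$ is drawn from its marginal
  odds with $\beta_j$ integrated out of the likelihood, then $\beta_j$ is
  drawn only if included. Joint naive updates of $(\delta_j, \beta_j)$ mix
  poorly at high $\pi$; the collapsed form is exact and cheap (one dot
  product per locus per iteration, implemented in RcppArmadillo).
* **Effect-variance prior scale.** $S^2_\beta = \tilde\sigma^2_g(\nu_\beta -
  2) / \big(\nu_\beta (1-\pi) \sum_j 2p_j(1-p_j)\big)$ with $\nu_\beta = 4$,
  where $\tilde\sigma^2_g$ comes from the Bayes C stage. This spreads the
  expected genetic variance over the expected number of included loci.
* **Genotype centring** at $2p_j$ decouples SNP effects from the intercept;
  fixed effects use full-rank dummy coding with the intercept absorbed, and
  covariates are standardized.
* **Degenerate inputs** (constant phenotype, fewer samples than fixed-effect
  levels + 2) are rejected with errors rather than produce a collapsing
  $\sigma^2_e$ chain. $\pi = 1$ is allowed with a warning (the model
  empties; all inclusion probabilities go to 0).
* **Variance components** use scaled-inverse-χ² updates with $\nu_e = 4$;
  both can be fixed (`fix_sigma2_e`, `fix_sigma2_beta`) which, together with
  `intercept = FALSE`, makes the posterior exactly enumerable on tiny
  instances — the test suite exploits this to compare inclusion
  probabilities against brute force over all $2^p$ inclusion patterns
  (agreement within 0.03 at 30,000 iterations).

Defaults follow study-scale practice: `pi = 0.9997`, `n_iter = 41000`,
`burn_in = 1000`. On the simulated fixtures in the tests we use smaller
chains (5,000 iterations, 1,000 burn-in at 2,000 SNPs / 500 samples;
800–3,000 iterations on smaller fixtures); at those sizes the h² posterior
mean lands within ±0.08 of truth in ≥ 8/10 seeds, which is the regime the
acceptance checks probe. π is an input, never estimated.

## Window variance decomposition

SNPs are binned into non-overlapping 1-Mb windows by
`floor((pos − 1)/1e6)`, labelled `chrom_index`; only windows containing at
least one SNP count. Per kept iteration $t$ and window $w$ the share is
$\mathrm{Var}_i\big(\sum_{j \in w} a_{ij}\beta_j^{(t)}\delta_j^{(t)}\big) /
\mathrm{Var}_i(g_i^{(t)})$ — the variance across individuals of the
window's genomic values relative to the total — and the posterior mean
× 100 is reported. Iterations with zero total genetic variance are skipped.
Because windows covary, shares need not sum to exactly 100; the suite
asserts the sum stays within [50, 150] on fixtures. A window is *relevant*
when its share is at least `multiplier` (default 5) times the infinitesimal
expectation 100/n_windows percent, boundary inclusive — the boundary
reading is ours; the convention that 2,502 windows give an expected 0.04%
and a 0.20% threshold is preserved exactly (to printed precision) by
`call_relevant_windows()`.

Memory: the sampler stores per-window variance samples
(kept-iterations × windows), not the full β chain; `save_beta_chain = TRUE`
is available for small fixtures.

## eQTL scan

Expression (log2-CPM) and genotypes are residualized against the covariate
design (intercept + contemporary group by default) once, and all SNP × gene
pairs are tested from the cross-product matrix: $t = r\sqrt{df}/\sqrt{1 -
r^2}$ with $df = n - 1 - q$, two-sided p from the t distribution. This is
algebraically identical to per-pair OLS including the covariates
(Frisch–Waugh), and the tests assert $|\Delta p| < 10^{-10}$ against an
`lm()` oracle. Missing genotypes are mean-imputed per SNP before
residualization; SNPs/genes left with zero variance are skipped and counted.

Cis/trans labelling measures distance to the nearest gene-body boundary
(0 inside the body; gene intervals are 1-based inclusive), cis iff
distance ≤ 1 Mb *inclusive*, trans otherwise; cross-chromosome pairs are
trans with infinite distance. We deliberately use the gene body rather than
the TSS — the boundary convention is stated nowhere we could anchor it, and
the gene-body rule is symmetric in upstream/downstream. BH FDR is applied
separately within the cis and the trans class (each class has its own test
count), and `significant` marks FDR < 0.05.

## Expression preparation

CPM is plain per-million scaling (via edgeR; no TMM re-weighting — the
simplest reading of "counts per million"), log2 with a pseudo-count of
1 CPM so zeros map to 0 exactly. The gene filter keeps a gene iff it is
expressed (log2-CPM ≥ 0) in at least 50% of samples — the two published
filter clauses (low expression; expressed in < 50% of samples) are
subsumed by this single rule, which matches common practice. Batch
adjustment is per-gene, per-batch mean-centering with the grand mean
restored: a location-only correction, documented as such, standing in for
ANOVA-based simultaneous component removal which is out of scope. PCA-style
diagnostics can be done on the returned matrix directly.

## Variant QC and the positional merge

The QC keep-rule is: QUAL ≥ 30 and total (site-level INFO) DP > 10 when the
VCF carries call-set annotations, then call rate ≥ 0.95, MAF ≥ 0.05,
autosomal chromosome, biallelic. DP is read site-level because "total depth
of coverage" describes the site, not the sample. The published panel filter
("≤ 95% excluded") and RNA-seq filter ("< 95% removed") differ by the
boundary; we harmonize to keep-iff-call-rate ≥ 0.95, the stricter reading
within rounding. The removal tally attributes each record to the first
criterion it fails, in the order above.

Merging a genotyping panel with transcribed variants keys on (chrom, pos)
only — "same genomic position" — keeping the panel record at overlaps.
Genotype concordance at overlap positions is computed before removal over
pairs where both calls are non-missing, after harmonizing alleles by direct
REF/ALT match or swap (genotype flipped 2 − g); incompatible allele pairs
are excluded from the denominator and counted. Strand flips are not
attempted since both call sets come from one reference build. Whether a
published concordance of this kind counts half-matches is unknowable from
text alone; we define it as exact-genotype match.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the fixtures emulate: ~200 individuals, LD-blocked biallelic
genotypes with MAF ≥ 0.05, a trait with a handful of QTL at h² ≈ 0.2–0.35
plus contemporary-group effects and a covariate, and an RNA-seq count
matrix with planted cis/trans effects and batch structure.

* **Genotypes**: within an LD block, allele draws share a latent Gaussian
  factor (correlation `within_block_r`), thresholded at the
  Hardy–Weinberg quantile of the SNP's allele frequency; two gamete draws
  sum to the genotype, so margins are Binomial(2, p). SNPs in one block
  share a base allele frequency (±0.05 jitter) — with dissimilar
  frequencies a binary pair cannot reach high r² no matter the latent
  correlation. Blocks are independent and never span chromosomes; blocks
  whose realized MAF dips below 0.05 are rejection-resampled, so fixtures
  pass the QC filter untouched. LD decay in any real population is not
  calibrated here: `within_block_r` is a free parameter, and passing tests
  say nothing about a specific population's LD structure.
* **Phenotype**: QTL effects are Gaussian by default; with
  `qtl_equal_effects = TRUE` they have equal magnitude and random sign, so
  each planted window carries an equal share of genetic variance *by
  construction* — the end-to-end fixtures use this so that "a planted
  regulatory SNP inside a relevant QTL window" is actually realized in
  every replicate rather than left to the luck of a Gaussian draw.
  Realized genetic and residual components are rescaled to exact variances
  h² and 1 − h²; true h² is genetic/(genetic + residual), fixed-effect
  variance excluded, matching what the model reports.
* **Expression**: latent log2 expression = baseline + batch shift + planted
  additive effects + Gaussian noise; counts are Poisson with exposure
  libsize × 2^latent / normalizer, so CPM → log2 recovers the latent signal
  through a monotone link. Planted effects have fixed magnitude
  (`cis_effect_sd` / `trans_effect_sd`) with random sign — a planted pair
  is a detectable effect, not a draw that may be indistinguishable from
  zero. Planted cis pairs satisfy the ≤ 1 Mb rule against the emitted gene
  map (validated in-suite by re-deriving labels with the scan's own
  classifier); `n_cis_at_qtl` optionally forces some cis pairs onto
  trait-QTL SNPs for end-to-end fixtures.

What the generator does **not** emulate: read-level noise, alignment
artifacts, genotyping error, overdispersion beyond Poisson (a
negative-binomial option was considered and dropped as irrelevant to the
tested pipeline's behaviour), population structure, and relatedness.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated generative model, not robustness to those realities.

## Integration, pruning, networks

Significant eQTL are kept iff the SNP lies in a relevant window's span
`[index·1e6 + 1, (index+1)·1e6]`; per-SNP roll-ups report cis-only /
trans-only / both. LD pruning slides a window of 100 SNPs (step 10,
per chromosome, SNPs position-sorted); while any retained pair in the
window has r² ≥ 0.5, the lower-MAF member is removed (tie: the later
position), and removal is sticky. PLINK's exact internal ordering is not
published; this greedy rule is our contract, pinned by an exhaustive
enumeration oracle in the tests (50 random fixtures, identical survivor
sets). Pruning is applied jointly per chromosome across all candidate
eQTL, not per QTL window — the less arbitrary of the two readings.
Networks are igraph objects: SNP and gene nodes (genes carry `is_tf` from a
user-supplied list), one directed edge per tag-SNP/gene association signed
by the regression beta; GraphML round-trips preserve all attributes. BED
export of windows converts the 1-based inclusive span to 0-based half-open,
and the conversion is tested on both boundaries.

## Pipeline and reproducibility

`run_pipeline()` fans one global seed out to stages via fixed offsets
(`seed·131 + stage`), so any stage can be rerun independently yet
reproducibly; rerunning a config byte-reproduces the window and eQTL
tables (asserted on checksums in the tests). Every stage writes a manifest
entry with outputs, md5 hashes, counts, and wall clock. The generators are
pure functions of (config, seed). All problem sizes used in the tests and
in `scripts/acceptance.R` (e.g. 2,000 SNPs × 500 samples × 5,000
iterations for recovery; 5,000 SNPs × 200 samples end to end; 20,000
null pairs for calibration) are the package's choices, balancing
Monte-Carlo error of the checked quantities against routine-run times.

## Known limitations

* The sampler is single-trait, additive-only; no dominance, epistasis, or
  multi-trait extensions, and no REML/GBLUP alternative.
* Window shares use the variance of window genomic values (not sums of
  squared effects); with strong between-window LD the shares of linked
  windows are not additive.
* The eQTL scan imposes no p-value emission threshold and materializes all
  pairs; at biobank scale you would chunk over SNP blocks (the scan is
  already block-structured internally via the cross-product).
* Batch centering removes location shifts only; scale or multivariate batch
  structure passes through.
* The LD-prune tie-break (later position) can differ from other tools on
  exact-tie fixtures; the in-package oracle defines the contract.
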