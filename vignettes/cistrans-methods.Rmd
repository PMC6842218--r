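---
title: "Quantifying cis- and trans-regulatory divergence in F1 hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cis- and trans-regulatory divergence in F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement idea

When two species are crossed, the F1 hybrid carries one allele from each
parent inside a single nucleus. Any diffusible (trans-acting) regulator
acts on both alleles equally, so an expression imbalance *between the two
alleles within the hybrid* can only come from linked, allele-specific
(cis-acting) differences. Comparing that allelic imbalance with the
expression difference *between the parents* decomposes regulatory
divergence per gene:

* `parental_div = log2(P1 / P2)` — total expression divergence between
  the parents,
* `cis = log2(F1A1 / F1A2)` — the hybrid allelic log ratio,
* `trans = parental_div - cis` — the remainder, attributed to diffusible
  factors,
* `%cis = |cis| / (|cis| + |trans|) * 100` — the cis share of total
  regulatory divergence.

The identity `cis + trans = parental_div` holds exactly by construction;
the test suite checks it to machine precision.

All four inputs are read counts at species-diagnostic SNP sites,
aggregated per gene and pooled across biological replicates (mean of
normalized counts, rescaled to the mean effective library size and rounded
half-to-even, so the exact tests receive integers). Three exact tests are
run per gene, each family FDR-adjusted separately (Benjamini–Hochberg,
5%):

* **A — parental difference**: two-sided exact binomial on `(P1, P2)`,
  null probability one half;
* **B — allelic imbalance (cis)**: two-sided exact binomial on
  `(F1A1, F1A2)`;
* **C — trans effect**: two-sided Fisher exact test on the table
  `[[P1, P2], [F1A1, F1A2]]`, null: the parental ratio equals the allelic
  ratio.

Two-sidedness is the method of small p-values throughout (sum the
probabilities of all outcomes no more likely than the observed one), the
same convention as `binom.test` and `fisher.test`, which serve as
independent oracles in the tests.

The three significance flags map onto seven regulatory categories:
conserved (no flag), cis only (A, B), trans only (A, C), compensatory
(B, C), cis + trans / cis × trans (all three, split by the sign of
`cis * trans`), and ambiguous for the remaining single-flag combinations
and for a zero sign product. The map is total and deterministic: every
one of the eight flag combinations lands in exactly one category.

## Inheritance of expression level

Separately from the allelic analysis, each gene's *total* hybrid
expression is compared with each parent using an in-package conditional
negative-binomial exact test (`nb_exact_test`). Replicate counts in each
group are assumed NB with a common dispersion `phi`
(`variance = mu + phi * mu^2`); conditioning on the pooled total makes the
group-A sum follow a negative hypergeometric law free of the unknown mean,
and `phi = 0` degenerates to the exact binomial (Poisson limit). The
common dispersion is estimated by a pooled method-of-moments ratio,
`max(0, sum(v - m) / sum(m^2))` over (gene, class) cells — the ratio form
avoids the downward bias of per-gene moment estimates at three
replicates. A gene is differentially expressed when FDR < 0.05 *and* the
point fold change (with a 0.5 pseudocount on group means) reaches
1.25-fold.

The two hybrid-versus-parent contrasts classify each gene into the eight
classical inheritance clusters: additivity (significant in opposite
directions; subtype by whether the female parent out-expresses the male),
expression-level dominance toward the parent the hybrid matches (exactly
one contrast significant; direction from the significant contrast's
sign), and transgressivity (over-/underdominance; both contrasts
significant in the same direction). Swapping which parent is called
female applies a fixed permutation to the clusters (female and male
dominance exchange, additivity subtypes flip, transgressive calls are
unchanged), which the tests verify by enumeration.

## From SNP-site counts to gene tables

Inputs are TSV tables with one row per diagnostic SNP site and one count
column per library–allele combination. Upstream read processing
(trimming, alignment to parental pseudo-genomes, SNP calling) is out of
scope; the package starts at count tables. Three stages prepare them:

1. **Dual-mapping merge.** When each F1 allele was counted against both
   parental pseudo-genomes, the merged count is the maximum of the two —
   the convention that counteracts allele-mapping bias, since the
   non-matching pseudo-genome can only lose reads. The site's F1 total is
   the sum of the two merged allele counts. The merge is idempotent and
   order-invariant.
2. **Quality filters.** A site is kept when the hybrid's minor parental
   allele has at least 2 reads and the site total at least 20. The
   thresholds are applied to counts pooled across F1 replicates by
   default, because the downstream allelic tests pool replicates too; a
   `per_replicate` flag applies them within each library instead.
   Parental homozygosity and F1 biallelism are enforced structurally by
   the column grammar (parents carry only their own allele; every F1
   library carries exactly the two parental alleles).
3. **Gene aggregation.** Counts are summed over a gene's retained sites;
   genes with no surviving site are dropped and logged. Aggregation
   precedes normalization (a `normalize`-then-aggregate order is
   deliberately not offered: per-site normalization would weight sites by
   sequencing depth twice).

Library scaling uses TMM (trimmed mean of M-values) on per-library gene
totals, with the standard trim fractions (30% on log ratios, 5% on log
abundance), precision weighting, automatic upper-quartile reference
selection, and factors rescaled to geometric mean one. The computation is
delegated to the edgeR implementation of the published definition; the
test suite recomputes factors from the definition directly as an
independent check. TMM assumes most genes are not differentially
expressed between libraries, so simulated architectures keep a conserved
majority.

**Replicate quality control.** Each library's median squared Pearson
correlation (on `log2(x + 1)` normalized values) with its same-class
replicates is reported, with 0.90 as the pass threshold (pass is `>=`).
For exclusion the fit is stricter than the raw flag: a library is dropped
only when its class retains a *coherent core* — at least two classmates
whose pairwise R-squared reaches the threshold — because a single
wrecked replicate also drags its good peers' medians down, and a class
that is incoherent wholesale gives QC no outlier to point at. Exclusion
refits normalization without the dropped libraries.

## The synthetic cross

`simulate_cross()` generates both the input tables and a truth table so
every stage is verifiable without external data. Per gene with cis effect
`c` and trans effect `t` (log2 units):

* parent 1 libraries draw NB counts with mean `mu * 2^((c + t) / 2) * s_j`
  and parent 2 with mean `mu * 2^(-(c + t) / 2) * s_j` (`s_j` a library
  size factor) — the symmetric placement decouples expression magnitude
  from divergence;
* F1 libraries draw a gene total with mean `mu * 2^shift * s_j` (the
  additive, mid-parent baseline is `shift = 0`; dominance and
  transgressive scenarios set per-gene shifts) and split it binomially
  between alleles with allele-1 share `2^c / (1 + 2^c)`.

So the expected parental log2 ratio is `c + t` and the expected allelic
log2 ratio is `c`, exactly the quantities the estimator targets. Gene
counts are then partitioned over the gene's SNP sites multinomially with
equal weights (site sums reproduce the gene draw exactly), and an
optional mapping bias emits two per-pseudo-genome copies per F1 allele
with the non-matching copy binomially thinned — the situation the
max-merge rule corrects.

Defaults, chosen once as plausible bulk RNA-seq flower-bud conditions and
stated rather than inferred (the source data report none): 500 expected
reads per gene per library, NB dispersion 0.05, three replicates per
class, five SNP sites per gene (the observed SNP-per-gene ratio in
comparable data is about five), effect magnitudes uniform on [0.5, 2.5]
log2 with random signs subject to the category constraints, and a
category mix with a 70% conserved majority. The seed fully determines the
output.

What the simulator does *not* emulate: between-gene variation in
expression level (a scalar `base_mean` keeps moment checks simple; pass a
vector for realistic spread — replicate QC is only informative in that
regime), within-gene regulatory heterogeneity across SNP sites, isoform
structure, GC or positional bias, and genuinely correlated library
effects. Passing recovery tests therefore demonstrate estimator
correctness under the stated generative model, not robustness to every
artefact of real libraries.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 inside log ratios only — never in test counts — so
  estimates stay finite at zero counts without biasing the exact tests.
* Replicate pooling rounds half-to-even (base `round`), stated for
  determinism.
* Zero totals give p = 1 in every exact test; a gene with all four pooled
  quantities zero is excluded and logged.
* An all-zero library is an error for TMM; a single-gene matrix yields
  factors 1 with a warning.
* Floating-point ties in the small-p sums use the customary `1 + 1e-7`
  relative tolerance.
* `%cis` is undefined (NA) when both components are exactly zero.

## Benchmark conditions used by the test suite

The acceptance-style checks run at sizes chosen to finish quickly while
leaving clear statistical margins: 10,000 random quadruples for the
decomposition identity; exhaustive enumeration of binomial outcomes and
2×2 tables to grand total 60 for the exact tests; 200 null runs of 500
conserved genes (depth 200, dispersion 0.1) for calibration; 1,500 genes
(depth 1,000, dispersion 0.05, effects on [1, 2.5] log2) for category
recovery; 800 genes for inheritance recovery; and two 2,000-gene crosses
(depth 500, dispersion 0.05) for the between-cross contrast.

The inheritance benchmark fixes dispersion at 0.01. That value comes from
a power calculation, not from the data: with three replicates at depth
1,000 and a 2-fold parental divergence, the two additivity contrasts are
only 1.41-fold each, and the sampling standard deviation of the log2 fold
change is about `sqrt(2 * (1/3000 + phi/3)) / ln 2`. At `phi = 0.05` that
is ~0.27 log2 — the 1.25-fold gate can then never be passed reliably —
while at `phi = 0.01` it is ~0.12 log2 and additive genes are recovered
with high probability. Biological dispersions in real plant tissue are
often larger; the benchmark measures classifier correctness, not field
power.

## Known limitations

The regulatory tests follow the classical recipe: replicate-pooled counts
and count-level exact tests. The allelic (cis) test is conditionally
binomial given the totals — allele splitting within a library really is
binomial, and averaging replicates only shrinks its variance — so the
cis family is calibrated, in fact conservative, under the null. The
parental binomial and the Fisher trans test are different: their pooled
counts carry biological replicate-to-replicate variance that the count-
level null cannot see, so at appreciable NB dispersion both families are
anticonservative, and under a global null a visible share of genes can be
labelled `trans_only` (flags A and C both fire off the same parental
wobble). This is the recognised weakness of pooled exact tests for
allele-specific expression and the motivation for overdispersion-aware
(beta-binomial / NB GLM) alternatives, which are deliberately out of
scope here; conclusions about trans divergence from this pipeline lean on
the assumption that biological replicate variability is small relative to
counting noise.

Other limitations: the DE engine uses a single common dispersion (no
per-gene shrinkage, no covariates); the fold-change gate applies to the
raw point estimate; SNP sites within a gene are assumed to share one
allelic ratio; and the category map treats the trans test as the
operational "same ratio" criterion for cis-only, so borderline genes near
the FDR boundary migrate between adjacent categories rather than failing
loudly.

## Choosing between interfaces

`cistrans_fit()` is the primary surface: one call from a SNP-site table
to a fitted object with `print`, `summary`, `coef` and `plot` methods
(the plot is the classic parental-versus-allelic scatter: cis-only genes
on the diagonal, trans-only on the horizontal axis, compensatory on the
vertical). Every stage is also exported on its own
(`merge_dual_mappings`, `filter_snp_sites`, `aggregate_to_genes`,
`tmm_factors`, `de_contrasts`, `classify_inheritance`,
`regulatory_calls`, the summary operations, `compare_crosses`), and
`run_all()` drives the identical computation from a YAML/JSON
configuration, writing all tables, a run manifest and a report — the
`exec/cistrans` script wraps it for shell use.
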