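---
title: "Methods: ensemble integration of tissue eQTLs with GWAS"
author: "eqtlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble integration of tissue eQTLs with GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlens)
```

## The analysis in one paragraph

Genome-wide association studies of complex diseases such as chronic
obstructive pulmonary disease leave many variants stranded below genome-wide
significance. `eqtlens` implements an ensemble strategy that recovers signal
from these sub-threshold variants by anchoring them in the genetic control of
gene expression: map expression quantitative trait loci (eQTLs) in a
case-control tissue cohort; intersect the significant eQTL SNPs (eSNPs) with
suggestive GWAS variants and quantify the enrichment; aggregate per-eSNP GWAS
evidence into per-gene log Bayes factor (LBF) scores with permutation-based
empirical p-values; organize all nominally significant eQTLs into a bipartite
eSNP-eGene network, partition it into communities by bipartite-modularity
maximization; and validate communities against independent differential
expression and DNA methylation evidence via Fisher meta-analysis.

## The eQTL scan

Every SNP-probe pair is tested by ordinary least squares of expression on
genotype dosage plus covariates (age, sex, pack-years of smoking, ancestry
principal components, and expression principal components), with a two-sided
t-test on the dosage coefficient at the residual degrees of freedom. The
implementation residualizes both dosage and expression on the covariate
design once and tests each pair on the residuals (the Frisch-Waugh-Lovell
decomposition), which is algebraically identical to per-pair OLS but runs as
two QR decompositions and one cross-product for the whole scan.

Pairs are *cis* when the SNP lies on the gene's chromosome within a window of
the annotated gene interval — 500 kb on each side by default, a 1 Mb total
window, boundary inclusive, 1-based inclusive coordinates throughout — and
*trans* otherwise (the trans family is genome-wide). The window anchors at
the annotated gene start and end rather than the TSS alone; this is
configurable. Benjamini-Hochberg FDR is applied separately within the cis and
trans families, which are reported as separate analyses with separate counts;
whether one joint adjustment would be preferable is a genuinely open choice,
and the per-family form is recorded in the output provenance.

Expression principal components (default `k = 13`, a config parameter; the
iterative PC-selection procedures some studies use are out of scope here)
absorb broad technical structure. Two numerical details matter. First, a PC
sign convention (largest-magnitude loading positive) makes scans
reproducible. Second, at synthetic scale the PCs can absorb genuine genetic
signal: with only a few hundred probes, a strong planted eQTL is a visible
variance direction, something that essentially cannot happen with tens of
thousands of probes. Tests that measure raw statistical power therefore run
with few or zero expression PCs, while the default pipeline keeps the
field-standard 13.

Monomorphic SNPs and zero-variance probes are dropped with counts logged in
provenance. Perfect fits (zero residual with nonzero slope) report the
smallest representable double rather than erroring; constant responses report
a null fit (slope 0, p = 1).

## GWAS intersection and enrichment

The intersection keeps GWAS SNPs below a suggestive threshold (default
p < 1e-4) that are also eSNPs at the eQTL FDR (default 5%), each with its
best (minimum-p) eGene; ties break by p then lexicographic probe id. Fold
enrichment is (k/n)/(K/N) with an upper-tail hypergeometric p-value, where
the universe N is explicitly the SNPs tested in *both* analyses — printed
enrichment folds are meaningless without a stated universe, so it is recorded
in provenance.

## LBF gene scores and permutation nulls

For each gene, eQTL records passing nominal thresholds (cis p < 1e-3, trans
p < 1e-6) whose eSNP appears in the GWAS summary contribute a Wakefield-style
approximate Bayes factor evaluated at the eSNP's GWAS z-score
(z = the inverse-normal transform of the two-sided p, computed in log space
so p-values near double underflow stay finite):

$$\mathrm{LBF} = \log_{10}\!\left[\sqrt{\frac{V}{V+W}}\;
  \exp\!\left(\frac{z^2 W}{2(V+W)}\right)\right]$$

with sampling variance normalized to V = 1 and prior effect variance
W = 0.21 by default. The kernel is deliberately pluggable: the contract the
ensemble relies on is that GWAS-supported eSNPs contribute positively,
unsupported eSNPs contribute a small penalty, and the gene score is the sum
of contributions. A total of 4.0 or more conventionally marks an individually
significant gene on this log10 scale. Because p-only summaries carry no
effect signs, z is non-negative; the LBF depends only on z squared, so no
information is lost.

eSNPs are pruned greedily by distance before summing (sort by eQTL p, keep a
record iff no kept record within 1 Mb on the same chromosome, deterministic
ties by p then rsID). This is a stand-in for LD-aware pruning when no LD
matrix is supplied; both pruned and unpruned modes are available because
either convention is defensible.

Empirical p-values come from GWAS summaries recomputed under case-control
label permutations (default 50) of the cohort itself, with the same
association test as the observed summary so observed and null scores are
exchangeable under the null. The default *pooled* null pools scores across
genes and permutations: 50 permutations of a few thousand genes resolve
empirical p-values far below 1/50, which per-gene nulls cannot. The add-one
estimator p = (1 + #{null >= obs}) / (1 + N) keeps p in (0, 1]. Within one
run, selecting genes at an empirical p cutoff is equivalent to a monotone
LBF cutoff; the LBF value that corresponds to p < 1e-3 is run-dependent and
is reported, not fixed.

## The bipartite network and its communities

Edges connect eSNPs to eGenes only — never eSNP to eSNP or eGene to eGene.
Construction keeps cis edges at p < 1e-3 and trans edges at p < 1e-6, drops
eSNPs absent from the GWAS summary, collapses probes to gene symbols (an
edge exists if any probe of the gene qualifies; supporting-probe counts are
kept as edge metadata, the network itself is unweighted), and removes
isolated SNP-gene pairs — edges whose two endpoints both have degree 1 —
because they create no additional connections. Removal iterates to a fixed
point; for the pair rule one pass already is the fixed point, since removing
a pair cannot change any other node's degree. The stricter alternative
(remove any edge with a degree-1 endpoint) is available behind a flag.

Communities maximize Barber's bipartite modularity

$$Q = \frac{1}{m}\sum_{i \in \mathrm{SNPs}}\ \sum_{j \in \mathrm{genes}}
 \left(A_{ij} - \frac{k_i d_j}{m}\right)\delta(c_i, c_j)$$

computed sparsely (within-community edge fraction minus per-community degree
products over m squared). The all-in-one partition scores exactly zero, a
useful built-in check. Fitting follows BRIM: given gene labels, every SNP
independently moves to its gain-maximizing community (so the SNP side updates
en bloc), then the gene side updates symmetrically; Q is non-decreasing and
iteration stops when the improvement drops below 1e-10 or after 100 sweeps
(non-convergence returns best-so-far with a warning). Determinism comes from
sweeping nodes in sorted order and breaking gain ties toward the lowest
community id. BRIM cannot create more communities than its initialization
provides, so initialization matters: the default builds the gene-side
one-mode projection (genes weighted by shared eSNP counts), runs seeded label
propagation on it, and assigns each SNP to the majority community of its gene
neighbours (ties to the lowest id). An `extra_singletons` option seeds
additional labels when finer structure is expected. The iteration caps and
initialization are this package's documented defaults, not values inherited
from any particular prior implementation.

## Community validation

Differential expression and differential methylation are tested per feature
by the same covariate-adjusted linear model machinery (ordinary t on the
status coefficient). For each community, Fisher's method combines the
p-values of all probes annotated to member genes, and separately the p-values
of member CpGs whose *raw* case-control mean beta-value difference exceeds
5% in absolute value (strict inequality; the filter intentionally uses the
unadjusted difference, since "effect greater than 5%" is a raw-scale
statement). A community is `validated_both` when both meta p-values fall
below 0.05, `validated_one` when exactly one does. Communities with no
qualifying features on a side get an absent meta p-value there, which counts
as not significant.

Fisher's method assumes independent inputs; probes within a community are
correlated, so these are reported as meta-analysis p-values with that caveat
rather than silently corrected — matching how such community p-values are
conventionally used. Correlation-adjusted variants (Brown's method) could be
slotted in but are not the default.

## The synthetic cohort generator

The generator exists so every stage above can be exercised against planted
truth. Its defaults describe one fixed study design, chosen once:

* **Cohort**: 86 cases, 31 controls (117 subjects), the scale of a severe
  COPD lung-tissue study; an independent GWAS cohort of 5000 with balanced
  case-control split.
* **Genotypes**: 2000 SNPs on 2 chromosomes at 10 kb spacing, MAF drawn once
  per plan from U(0.1, 0.5) (all above the 5% panel filter). LD follows a
  haplotype-copying model: within blocks of 10 SNPs, each haplotype allele
  copies its left neighbour with probability 0.8, else draws fresh at the
  SNP's MAF. Copying a Bernoulli(maf) value preserves marginal frequencies
  exactly, and block r-squared is tunable through the copy probability. Two
  haplotypes sum to a dosage in {0, 1, 2}.
* **Expression**: 200 genes, one probe each; expression = planted effects x
  dosage + optional covariate terms + N(0, 1) noise. 30 cis effects of 0.8
  expression units per allele (t around 5-6 at n = 117, comfortably
  detectable, as real significant cis eQTLs in such a cohort must be);
  5 trans effects of 1.2. The trans size is deliberately large: clearing the
  trans threshold of p < 1e-6 at n = 117 requires |t| above ~5.3, so any
  trans eQTL a cohort of this size can report is a large effect — planting
  smaller ones would emulate nothing observable.
* **Disease**: logistic liability on 10 of the cis eSNPs at log-odds 0.4 per
  allele, making their genes "shared" between expression and disease — the
  planted analogue of genes discoverable by signature matching. The intercept
  is tuned by bisection to the expected case count, then the exact 86/31
  quota is enforced by random demotion of surplus cases / odds-weighted
  promotion of controls.
* **Methylation**: 500 CpGs annotated round-robin to genes; beta values are
  the logistic transform of a Gaussian latent (SD 0.5), with the latent mean
  solved numerically so the *expected beta* equals the target — 25 CpGs get a
  +0.10 case-control difference, the scale of a reportable methylation shift.
* **GWAS summaries and permutations** use an allelic trend test (the
  dosage-status correlation on a t distribution with n - 2 df). The t form
  was chosen over the asymptotic chi-square after checking calibration at
  n near 120: rejection rates are nominal at 5% and 1% under the null.

What the generator does *not* emulate: realistic genome-wide LD maps,
imputation dosage uncertainty, population structure (ancestry PCs are
injected as independent covariates, not simulated admixture), probe-level
measurement artifacts, or cell-type heterogeneity of tissue. Passing tests on
this generator therefore demonstrates correctness of the statistical
machinery and recoverability of planted signal under idealized conditions —
not robustness to the full messiness of real cohorts.

## Problem sizes and numerical choices

The test-suite simulations use the default 117-subject design with panels of
20-2000 SNPs and 20-200 genes, 50-replicate calibration loops, and 50
permutations; the full pipeline at the default plan runs in well under a
minute on one core. Small, fixed seeds make every run reproducible;
seed-sensitive steps (label propagation, permutation, quota sampling) all
accept explicit seeds. Tolerances: modularity identities hold to 1e-10;
scan-vs-oracle agreement to 1e-8 relative; BRIM stops at Q improvements
below 1e-10. Degenerate inputs (monomorphic SNPs, constant probes, empty
networks, genes without qualifying eSNPs, communities without CpGs) are
handled as flagged results or logged drops, never silent errors.

## Known limitations

* The LBF kernel is a reconstruction of a signature-matching score, not a
  re-implementation of any specific hierarchical Bayesian method; absolute
  score values depend on W and on the pruning convention.
* Distance pruning only approximates LD pruning; with long-range LD it will
  under- or over-prune.
* Fisher meta p-values inherit the independence assumption discussed above.
* BRIM finds local optima; the exhaustive-search tests bound the gap on
  small graphs (at least 95 of 100 random instances reach the global
  optimum), but no guarantee exists at scale.
* Headline counts from any real cohort (numbers of significant eQTLs,
  communities, validated communities) are functions of cohort size, array
  content and LD structure, and are not reproducible from synthetic data;
  the package's claims are therefore property-based.

## A minimal run

```{r example, eval = FALSE}
plan <- default_plan()
res <- run_ensemble_pipeline(plan, out_dir = tempfile("run_"), seed = 1)
head(res$scores)
res$network
res$communities
table(res$validation$status)
```
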