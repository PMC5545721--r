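---
title: "From a seed-gene co-expression module to a polygenic co-expression index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a seed-gene co-expression module to a polygenic co-expression index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`coexpci` implements a four-step chain for studying the genetic control of a
gene set's co-expression. (1) From a preprocessed expression matrix it
builds a weighted co-expression network, detects modules, and keeps the
module containing a seed gene of interest (the motivating application is
the dopamine receptor gene *DRD2* in post-mortem prefrontal cortex). The
module's shared variation is summarized by its **module eigengene (ME)**,
the first principal component of the gene-standardized member submatrix.
(2) SNPs within ±100 kb of module genes are screened for association with
the ME by per-SNP additive regression; such variants are **co-eQTLs** — they
track the co-expression of a whole gene set rather than a single
transcript. (3) Independent associated SNPs are combined into a
**Polygenic Co-expression Index (PCI)**: each genotype of each SNP receives
a weight equal to the mean training ME in that genotype group minus the
grand mean, and an individual's PCI is the sum of the weights of their
genotypes. Greater PCI predicts greater module co-expression from genotype
alone, so the index can be carried to cohorts with no expression data.
(4) The PCI is validated by k-fold cross-validation and frozen-weight
replication, and associated with phenotypes: ROI-level imaging signal,
working-memory load-by-PCI interactions, clinical improvement (Spearman),
and treatment-response classification (ROC/AUC), with Bonferroni or
Benjamini–Hochberg control where families of tests arise.

Because the motivating data (post-mortem brain expression with genotypes,
fMRI, clinical trials) cannot be redistributed, the package ships a
synthetic-cohort generator with the generative structure the analysis
assumes. Every pipeline stage is exercised and tested against that
generator; the published cohort-specific estimates serve as *design
anchors* for the generator's defaults, not as values the tests reproduce.

## The generative model

For sample $i$, a latent module factor
$$L_i = \sum_s \beta_s\, d_{is} + \varepsilon_i,$$
where $d_{is} \in \{0,1,2\}$ counts minor alleles at causal SNP $s$ (drawn
from Hardy–Weinberg proportions at the SNP's minor allele frequency) and
$\varepsilon_i$ is Gaussian noise scaled so that $\mathrm{var}(L) = 1$ in
the population. Module gene $g$ is
$$x_{ig} = \lambda_g L_i + \sum_c \gamma_{gc} z_{ic} + s\,\eta_{ig},$$
with loadings $\lambda_g$ uniform on `loading_range`, linear confound
effects $\gamma_{gc}$ (age and sex by default), and a common noise scale
$s$. Background genes carry confounds and independent noise only.

**PC1 targeting.** The noise scale $s$ is solved numerically (by
`uniroot` on the top eigenvalue of the implied population correlation
matrix of the module, after confound adjustment) so the expected
explained-variance fraction of the module's first principal component
equals `pc1_target` (default 0.325). An unattainable target fails with a
message naming the attainable range; the lower bound is $1/m$ for an
$m$-gene module. Finite-sample PCA inflates the realized fraction by
roughly $+0.005$ at $n = 200$, $m = 85$, which is well inside the
generator's ±0.02 calibration tolerance (the test suite verifies a
multi-seed average within ±0.05).

**Default conditions.** The discovery preset is $n = 200$ samples, an
85-gene module (seed gene `DRD2` plus the eight SNP-host genes and three
risk-anchor genes, filler ids for the rest), 915 background genes, and
eight causal SNPs whose ids, host genes and minor allele frequencies come
from the reference SNP panel (`reference_snp_panel()`). Base-pair
coordinates for the panel and for all gene windows are synthetic — only
the chromosome of each locus is anchored — and are documented as such.
The default per-allele effect `causal_beta = 0.38` puts about 45% of the
latent variance under genetic control; after screening, weight fitting
and in-sample attenuation this lands the training PCI–ME $R^2$ near the
0.38 design anchor. The replication preset is $n = 50$, five module
probes removed (never the seed gene), a broader RNA-quality range
(4.5–9, versus 7–9.5 in discovery), and `causal_beta = 0.24`, sizing the
designed PCI–ME $R^2$ near 0.15 — a deliberately degraded, smaller
cohort. The clinical preset is $n = 87$ with a latent–improvement
correlation of 0.4 and a median-split responder label; the responder
operationalization in the source study is not public, so the median
split is a placeholder choice, not an inference.

**What the generator does not emulate.** Realistic transcriptome-wide
covariance (background genes are independent), linkage disequilibrium
(genotypes are in linkage equilibrium by default; a block-LD mode exists
only to exercise pruning), non-Gaussian noise, probe-level artifacts, and
population structure. Passing tests therefore demonstrate that the
pipeline recovers the structure it models — not that it is robust to every
failure mode of real expression data.

## Network construction choices

The network is **unsigned** by default ($a_{ij} = |r_{ij}|^\beta$;
a signed variant is available), built on Pearson correlation. The soft
power $\beta$ is the smallest grid value whose scale-free fit $R^2$
(log-frequency on log-connectivity over ten bins, requiring a negative
slope) reaches 0.8, falling back to the best-fitting power with a logged
warning. The topological overlap matrix is
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
and modules come from average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$ with a **static cut** at `cut_height` times the maximum
merge height (default 0.997), relabeling clusters smaller than
`min_module_size` (default 20) as unassigned. A static cut replaces the
dynamic tree cut used by canonical WGCNA because it is deterministic and
fully specifiable; the high default reflects that soft-thresholded TOM
dissimilarities concentrate near 1, so informative merges sit in a thin
band below the maximum height (the default was fixed by a planted-module
recovery sweep, at which it achieves mean truth-Jaccard ≈ 0.95 with pure
modules under the default generator). Ties in cluster labeling are broken
by module size, then smallest member index. The eigengene is
sign-oriented so it correlates positively with the seed gene (or with the
average member when the seed gene is absent), and its scores are scaled
to unit variance.

## Screening, selection and the PCI

The co-eQTL scan regresses the ME on additive dosage per SNP; covariates
are not included by default because the ME is computed from expression
already residualized on them (they can be added). Monomorphic or
under-sampled SNPs are flagged `untestable`, never silently dropped.
Independence is enforced by greedy LD pruning (accept in ascending-p
order while all pairwise dosage $r^2 < 0.2$; the criterion is a
convention, stated nowhere in the source). Selection is either the fixed
threshold $p < 0.005$ (default) or a plateau rule that adds pruned SNPs
in ascending-p order and stops when the incremental fit gain falls below
`plateau_eps` twice in a row. The plateau trace is judged on **adjusted**
$R^2$: each SNP's weights consume roughly two genotype-group means, so
raw in-sample $R^2$ grows by about $2/n$ per SNP even for pure-noise
markers and cannot plateau at moderate $n$; adjusting for the consumed
parameters restores the intended "variance plateaus" behavior. Both raw
and adjusted traces are returned.

PCI weights are centered genotype-group means of the training ME.
Genotype groups smaller than `min_group = 5` are merged toward the
heterozygote before averaging, because tiny-group means are unstable. A
missing genotype contributes 0 — the grand-mean (null) contribution —
rather than dropping the sample; samples missing more than half the model
SNPs are flagged. These weights guarantee non-negative training
correlation with the ME, and they are invariant to centering and
equivariant to scaling of the ME. The weighting is an explicit
reconstruction (the source delegates its formula to earlier work); it is
isolated behind `fit_pci()` so alternative weightings can be swapped.

Cross-validation re-runs screening, pruning and selection inside every
training fold by default (the stricter protocol; `reselect = FALSE`
re-fits weights on a fixed panel instead). Replication freezes the
trained weights entirely: the replication cohort contributes a fresh ME
(PCA re-run on the module genes present there, sign re-oriented) and
genotypes, nothing else; the report includes a high-quality stratum
(quality > 6) mirroring the RIN-stratified replication of the motivating
study, and the test is one-tailed for $r > 0$, matching the directional
claim.

## Phenotype associations

ROI-level associations use OLS or a Huber robust fit (tuning constant
1.345, IRLS to 1e-8 or 50 iterations, via `MASS::rlm`). The two-level
repeated-measures LOAD×PCI interaction is tested as a regression of the
within-subject difference on the PCI plus covariates — exactly the
repeated-measures ANCOVA interaction ($F = t^2$) for a two-level within
factor, verified in the tests against a full multivariate repeated-
measures fit; the behavioral family threshold $\alpha = 0.025$ is
reported as metadata, never hard-coded. Enrichment is an exact
upper-tail hypergeometric test whose background is a required explicit
input (the motivating background, protein-coding risk loci, has no
published count). Spearman association uses midranks and the
$t$-approximation; ROC/AUC uses the midrank Mann–Whitney identity with a
tie-corrected one-tailed normal $p$ (exact permutation enumeration is
available for $n \le 12$). BH q-values come from the standard step-up
rule. Sidedness is always recorded; one-tailed tests are used only where
the underlying claim is directional.

## Numerical and degenerate-input conventions

Zero-variance genes fail adjacency construction by name; zero-variance
eigengene members are dropped with a logged count. Dosages outside
{0, 1, 2, NA} are rejected naming the offending cell. Chromosome names
are normalized across the `chr1`/`1` conventions; genomic intervals are
1-based and closed, with the ±100 kb window boundary inclusive. All
randomness descends from one integer seed through a documented
stage-offset scheme (`split_seed`), so every stage is independently
reproducible and two runs of the same configuration are bit-identical.
TSV output of expression values uses 17 significant digits so a
write–read round trip is exact.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full chain at the
default discovery size (1,000 genes × 200 samples) over 20 seeds for
module recovery, 100 replication cohorts (n = 50), 200 clinical cohorts
(n = 87), a 1,000-SNP null screen, and 1,000-replicate power
simulations — sizes chosen so the whole battery completes in a few
minutes while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

The static tree cut trades the adaptivity of dynamic cutting for
determinism and will fragment modules whose internal correlation varies
strongly. The plateau selection needs $n$ large relative to the number of
candidate parameters to be meaningful. The hypergeometric enrichment
treats genes as exchangeable (no length or LD correction). The exact
repeated-measures shortcut applies only to two-level within factors. The
generator's independence assumptions (background genes, SNPs) make
recovery easier than in real tissue; treat the shipped numbers as
internal-consistency checks, not field benchmarks.
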