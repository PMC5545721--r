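# coexpci

Gene co-expression modules and the **Polygenic Co-expression Index
(PCI)** — an R package for asking whether common genetic variants jointly
control the co-expression of a gene set, and whether that genetic signal
carries to cohorts where no expression was measured.

## The problem

Risk variants for complex brain disorders cluster in molecular pathways,
and pathway genes tend to be co-expressed. For a seed gene of interest
(the motivating application is the dopamine D2 receptor gene *DRD2* in
prefrontal cortex), one can ask: which genes share its expression
variation, which SNPs track that shared variation, and can those SNPs —
summed into a single per-person index — predict the pathway's expression
state in people for whom only genotypes exist (imaging cohorts, clinical
trials)?

The package implements that chain end to end:

1. **Module detection.** A weighted co-expression network
   (soft-thresholded correlation, topological overlap, average-linkage
   clustering with a static tree cut) yields modules; the module
   containing the seed gene is summarized by its **module eigengene
   (ME)** — the first principal component of the gene-standardized
   member submatrix, sign-oriented to the seed gene:
   `ME = PC1(X_module)`, with explained variance `λ₁ / Σλ`.
2. **co-eQTL screen.** SNPs within ±100 kb of module genes are tested by
   per-SNP regression `ME ~ dosage`; associated, LD-independent SNPs
   (greedy pruning at r² < 0.2, selection at p < 0.005 or by a
   variance-plateau rule) are the module's *co-eQTLs*.
3. **PCI.** Each genotype g of each selected SNP s gets a weight
   `w(s,g) = mean(ME | g at s) − mean(ME)`; an individual's index is
   `PCI_i = Σ_s w(s, g_is)`. Greater PCI ⇒ greater predicted module
   co-expression. Weights are cross-validated (per-fold re-selection)
   and replicated with frozen weights in independent cohorts.
4. **Phenotype association.** Linear / Huber-robust models for ROI
   signals, exact two-level repeated-measures interaction tests for
   load-dependent behavior, hypergeometric risk-gene enrichment,
   Spearman correlation with clinical improvement, ROC/AUC prediction of
   treatment response, Bonferroni and Benjamini–Hochberg control.

Restricted post-mortem, imaging and clinical data cannot ship with the
package, so it includes a fully specified synthetic-cohort generator
(Hardy–Weinberg genotypes, latent-factor module with a calibrated PC1
fraction, demographic confounds, degraded replication cohorts, clinical
outcomes) against which every stage is tested. See the methods vignette
(`vignettes/coexpci-methods.Rmd`) for the model and design choices.

## Worked example

```r
library(coexpci)

co   <- simulate_cohort(default_cohort_config("discovery", seed = 42))
prep <- residualize(co$expression, co$covariates[c("age", "sex")])

net     <- network_config()
power   <- select_soft_power(prep, net)
tom     <- topological_overlap(adjacency(prep, power$power))
modules <- detect_modules(tom, net)
mod     <- seed_module(modules, "DRD2")
me      <- module_eigengene(prep, mod$members, "DRD2")
me
#> <eigengene> 85 members, 200 samples, PC1 explains 35.7%

scan <- coeqtl_scan(me, co$genotypes)
sel  <- select_snps(scan, co$genotypes, me)   # prune, keep p < 0.005
fit  <- fit_pci(me, co$genotypes, sel$snps)
fit
#> <pci_model> 6 SNPs, trained on 200 samples, training R^2 = 0.404
#> SNPs: rs1805453, rs11213916, rs1037791, rs851436, rs6902039, rs2486064

crossvalidate_pci(me, co$genotypes, k_folds = 5, seed = 1)
#> <pci_cv> 5 folds (0 failed), pooled out-of-fold r = 0.524

rep_co <- simulate_cohort(default_cohort_config("replication", seed = 7))
replicate_pci(fit, rep_co$expression, rep_co$genotypes,
              co$truth$module_gene_ids, "DRD2")
#> <pci_replication> r = 0.323 (one-tailed p = 0.0111, n = 50, 80/85 probes)
#>   quality > 6 stratum: r = 0.552 (n = 30, p = 0.000786)

clin <- simulate_cohort(default_cohort_config("clinical", seed = 7))
pci  <- score_pci(fit, clin$genotypes)
roc_auc(pci, clin$phenotypes$responder)
#> <roc_result> AUC = 0.567 (n1 = 43, n0 = 44), one-tailed p = 0.142
```

Reading the output: the detected seed module recovered all 85 planted
genes and its eigengene explains 35.7% of module variance; six
LD-independent SNPs passed the p < 0.005 screen, and their genotype
weights predict the eigengene with in-sample R² = 0.40 and out-of-fold
r = 0.52. The frozen weights replicate in a smaller, lower-quality
cohort missing five probes (r = 0.32, stronger in the high-quality
stratum, as expected when RNA degradation attenuates the module signal),
and in a genotype-only clinical cohort the index classifies treatment
responders modestly above chance — a single n = 87 draw; the average
over many clinical cohorts sits near AUC 0.62.

`run_pipeline()` chains all stages with per-stage outputs and a checksum
manifest; a thin command-line wrapper lives at `inst/cli/coexpci.R`
(`simulate`, `run` subcommands).

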