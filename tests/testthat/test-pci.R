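test_that("gene windows use closed +/- 100 kb intervals", {
  genes <- data.frame(gene = "G1", chrom = "chr2", start = 500000,
                      end = 520000)
  snps <- data.frame(id = c("in_edge", "out_edge", "inside", "other_chr"),
                     chrom = c("2", "2", "2", "3"),
                     pos = c(400000, 399999, 510000, 510000))
  res <- suppressMessages(snps_in_gene_windows(snps, genes))
  expect_setequal(res$snp_ids, c("in_edge", "inside"))
  expect_true(all(res$map$gene == "G1"))
})

test_that("window filtering equals a brute-force interval scan", {
  set.seed(30)
  genes <- data.frame(gene = sprintf("G%02d", 1:10),
                      chrom = sample(1:3, 10, TRUE),
                      start = sample.int(5e6, 10))
  genes$end <- genes$start + sample.int(50000, 10)
  snps <- data.frame(id = sprintf("s%04d", 1:1000),
                     chrom = as.character(sample(1:3, 1000, TRUE)),
                     pos = sample.int(5.2e6, 1000))
  w <- 100000
  keep <- vapply(seq_len(1000), function(i) {
    any(genes$chrom == snps$chrom[i] &
          snps$pos[i] >= genes$start - w & snps$pos[i] <= genes$end + w)
  }, logical(1))
  res <- snps_in_gene_windows(snps, genes, w)
  expect_setequal(res$snp_ids, snps$id[keep])
})

test_that("co-eQTL scan matches the closed-form OLS oracle", {
  ch <- get_discovery_chain()
  geno <- ch$cohort$genotypes
  # perfect fit: ME equal to a dosage
  d <- geno$dosage[, 1]
  me_fake <- stats::setNames(as.numeric(d), rownames(geno$dosage))
  scan <- coeqtl_scan(me_fake, geno)
  expect_lt(scan$p[1], 1e-12)
  expect_equal(scan$slope[1], 1, tolerance = 1e-10)
  # n = 20 fixture: compare slope/t/p against stats::lm / summary
  set.seed(31)
  d20 <- matrix(rbinom(20 * 3, 2, 0.4), 20,
                dimnames = list(sprintf("x%02d", 1:20), c("a", "b", "c")))
  y <- stats::setNames(rnorm(20), rownames(d20))
  s20 <- coeqtl_scan(y, geno_matrix(d20))
  for (j in 1:3) {
    cf <- summary(stats::lm(y ~ d20[, j]))$coefficients
    expect_equal(s20$slope[j], cf[2, 1], tolerance = 1e-10)
    expect_equal(s20$t[j], cf[2, 3], tolerance = 1e-10)
    expect_equal(s20$p[j], cf[2, 4], tolerance = 1e-10)
  }
  # monomorphic SNP flagged, not dropped
  dm <- cbind(d20, mono = 1)
  sm <- coeqtl_scan(y, geno_matrix(dm))
  expect_equal(sm$status[sm$snp == "mono"], "untestable")
  expect_equal(nrow(sm), 4)
  # covariate-adjusted route agrees with lm
  cv <- data.frame(age = rnorm(20))
  rownames(cv) <- rownames(d20)
  sc <- coeqtl_scan(y, geno_matrix(d20), covars = cv)
  cf <- summary(stats::lm(y ~ cv$age + d20[, 1]))$coefficients
  expect_equal(sc$slope[1], cf[3, 1], tolerance = 1e-10)
  expect_equal(sc$p[1], cf[3, 4], tolerance = 1e-10)
})

test_that("Bonferroni correction caps at one", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.01, 10), 0.1)
  # the top screen hit: corrected p = p * family size
  expect_equal(bonferroni(5.0e-6, 660), 0.0033, tolerance = 1e-12)
})

test_that("LD pruning is greedy by p with deterministic ties", {
  set.seed(32)
  base <- rbinom(80, 2, 0.3)
  dosage <- cbind(dupA = base, dupB = base,
                  free = rbinom(80, 2, 0.3))
  rownames(dosage) <- sprintf("i%02d", 1:80)
  g <- geno_matrix(dosage)
  # duplicated column: smaller p wins
  kept <- ld_prune(g, c(dupA = 0.5, dupB = 0.01, free = 0.9), 0.2)
  expect_setequal(kept, c("dupB", "free"))
  # tie: lexicographic
  kept2 <- ld_prune(g, c(dupA = 0.5, dupB = 0.5, free = 0.9), 0.2)
  expect_true("dupA" %in% kept2 && !"dupB" %in% kept2)
  # uncorrelated SNPs all retained
  set.seed(33)
  ind <- matrix(rbinom(400 * 6, 2, 0.5), 400,
                dimnames = list(sprintf("i%03d", 1:400), letters[1:6]))
  p6 <- stats::setNames(runif(6), letters[1:6])
  expect_length(ld_prune(geno_matrix(ind), p6, 0.2), 6)
  # 50-SNP LD-block fixture vs reference greedy oracle
  set.seed(34)
  nblock <- 10
  cols <- list()
  for (b in seq_len(nblock)) {
    anchor <- rbinom(150, 2, 0.4)
    for (k in 1:5) {
      flip <- rbinom(150, 1, 0.12)
      v <- ifelse(flip == 1, rbinom(150, 2, 0.4), anchor)
      cols[[paste0("b", b, "_", k)]] <- v
    }
  }
  D <- do.call(cbind, cols)
  rownames(D) <- sprintf("i%03d", 1:150)
  gB <- geno_matrix(D)
  pB <- stats::setNames(runif(ncol(D)), colnames(D))
  expect_identical(ld_prune(gB, pB, 0.2), ld_prune_oracle(D, pB, 0.2))
})

test_that("fixed-threshold selection keeps the reported eight SNPs", {
  # the screen's eight uncorrected p-values plus a ninth just above 0.005,
  # all mutually independent
  p9 <- c(5.0e-6, 4.6e-4, 1.0e-3, 1.0e-3, 1.7e-3, 2.8e-3, 3.0e-3,
          3.2e-3, 5.1e-3)
  ids <- c("rs2486064", "rs6902039", "rs851436", "rs9297283",
           "rs12940715", "rs1805453", "rs11213916", "rs1037791",
           "extra9")
  set.seed(35)
  D <- matrix(rbinom(500 * 9, 2, 0.3), 500,
              dimnames = list(sprintf("i%03d", 1:500), ids))
  tab <- data.frame(snp = ids, p = p9)
  class(tab) <- c("coeqtl_table", "data.frame")
  sel <- select_snps(tab, geno_matrix(D), alpha = 0.005)
  expect_setequal(sel$snps, ids[1:8])
  # nothing significant: explicit empty-model failure
  tab$p <- rep(0.5, 9)
  expect_error(select_snps(tab, geno_matrix(D)), "empty model")
})

test_that("plateau selection keeps roughly the planted SNP count", {
  # a cohort large enough that per-SNP group-mean noise (~2/n) sits well
  # below the plateau increment
  counts <- vapply(1:20, function(sd) {
    set.seed(sd)
    n <- 1000
    D <- matrix(rbinom(n * 23, 2, 0.3), n,
                dimnames = list(sprintf("i%04d", 1:n),
                                sprintf("s%02d", 1:23)))
    # 3 strong SNPs, 20 null
    y <- stats::setNames(
      0.45 * (D[, 1] + D[, 2] + D[, 3]) + rnorm(n), rownames(D))
    g <- geno_matrix(D)
    scan <- coeqtl_scan(y, g)
    sel <- select_snps(scan, g, me = y, method = "plateau")
    length(sel$snps)
  }, numeric(1))
  expect_true(all(counts >= 3 & counts <= 5))
})

test_that("PCI weights are centered genotype-group eigengene means", {
  # one SNP with group means (-1, 0, +1), grand mean 0
  d <- rep(c(0, 1, 2), each = 10)
  me <- stats::setNames(rep(c(-1, 0, 1), each = 10),
                        sprintf("i%02d", 1:30))
  g <- geno_matrix(matrix(d, dimnames = list(names(me), "s1")))
  fit <- fit_pci(me, g, "s1")
  expect_equal(unname(coef(fit)[, "s1"]), c(-1, 0, 1))
  expect_equal(unname(score_pci(fit, g)), as.numeric(d - 1),
               ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1)
  # constant eigengene: all weights zero, R^2 = 0
  me0 <- stats::setNames(rep(2, 30), names(me))
  fit0 <- fit_pci(me0, g, "s1")
  expect_true(all(coef(fit0) == 0))
  expect_equal(fit0$r_squared, 0)
})

test_that("PCI weights satisfy the weighted zero-sum constraint", {
  ch <- get_discovery_chain()
  fit <- fit_pci(ch$me, ch$cohort$genotypes, reference_snp_panel()$id)
  common <- intersect(names(ch$me$scores),
                      rownames(ch$cohort$genotypes$dosage))
  for (s in fit$snps) {
    g <- ch$cohort$genotypes$dosage[common, s]
    w <- coef(fit)[as.character(g), s]
    expect_lt(abs(sum(w)), 1e-10)
  }
  expect_gte(cor(fit$train_pci, fit$train_me), 0)
})

test_that("training R^2 equals an independent group-mean recomputation", {
  ch <- get_discovery_chain()
  geno <- ch$cohort$genotypes
  fit <- fit_pci(ch$me, geno, reference_snp_panel()$id, min_group = 5)
  y <- ch$me$scores
  pci_oracle <- rep(0, length(y))
  for (s in fit$snps) {
    g <- geno$dosage[names(y), s]
    counts <- table(g)
    map <- as.character(0:2)
    if (!is.na(counts["2"]) && counts["2"] < 5) map[3] <- "1"
    if (!is.na(counts["0"]) && counts["0"] < 5) map[1] <- "1"
    gm <- map[g + 1]
    mns <- tapply(y, gm, mean)
    pci_oracle <- pci_oracle + (mns[gm] - mean(y))
  }
  expect_equal(unname(fit$train_pci), as.numeric(pci_oracle),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, cor(pci_oracle, y)^2, tolerance = 1e-10)
  # design anchor: training fit in the tuned regime
  expect_gt(fit$r_squared, 0.25)
})

test_that("PCI weights are centering invariant and scale equivariant", {
  ch <- get_discovery_chain()
  g <- ch$cohort$genotypes
  ids <- reference_snp_panel()$id[1:4]
  f1 <- fit_pci(ch$me$scores, g, ids)
  f2 <- fit_pci(ch$me$scores + 100, g, ids)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  f3 <- fit_pci(3 * ch$me$scores, g, ids)
  expect_equal(coef(f3), 3 * coef(f1), tolerance = 1e-10)
})

test_that("scoring handles missingness, ordering and absent SNPs", {
  w <- c(-1, 0, 1)
  d <- matrix(c(0, 1, 2, NA), 4, 1,
              dimnames = list(sprintf("i%d", 1:4), "s1"))
  me <- stats::setNames(c(-1, -1, 0, 0, 0, 0, 1, 1), sprintf("j%d", 1:8))
  gtrain <- geno_matrix(matrix(c(0, 0, 1, 1, 1, 1, 2, 2), 8, 1,
                               dimnames = list(names(me), "s1")))
  fit <- fit_pci(me, gtrain, "s1", min_group = 2)
  sc <- suppressMessages(score_pci(fit, geno_matrix(d)))
  expect_equal(unname(sc), c(-1, 0, 1, 0),   # missing contributes 0
               ignore_attr = TRUE)
  expect_error(score_pci(fit, geno_matrix(
    matrix(0:1, 2, 1, dimnames = list(c("a", "b"), "other")))), "s1")
  # order invariance on a multi-SNP model
  ch <- get_discovery_chain()
  g <- ch$cohort$genotypes
  fit8 <- fit_pci(ch$me, g, reference_snp_panel()$id)
  s1 <- score_pci(fit8, g)
  perm_s <- sample(ncol(g$dosage))
  perm_i <- sample(nrow(g$dosage))
  g_perm <- geno_matrix(g$dosage[perm_i, perm_s], g$meta[perm_s, ])
  s2 <- score_pci(fit8, g_perm)
  expect_equal(s2[names(s1)], s1, tolerance = 1e-12, ignore_attr = TRUE)
  # brute-force per-sample summation oracle
  oracle <- vapply(rownames(g$dosage)[1:100], function(i) {
    tot <- 0
    for (s in fit8$snps) {
      gi <- g$dosage[i, s]
      if (!is.na(gi)) tot <- tot + coef(fit8)[as.character(gi), s]
    }
    tot
  }, numeric(1))
  expect_equal(s1[1:100], oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dosages are flipped when the minor allele is swapped", {
  me <- stats::setNames(c(rep(-1, 6), rep(0, 6), rep(1, 6)),
                        sprintf("i%02d", 1:18))
  d <- rep(c(0, 1, 2), each = 6)
  meta <- data.frame(id = "s1", minor = "A", major = "G")
  fit <- fit_pci(me, geno_matrix(matrix(d, dimnames = list(names(me), "s1")),
                                 meta), "s1")
  meta_fl <- data.frame(id = "s1", minor = "G", major = "A")
  g_fl <- geno_matrix(matrix(2 - d, dimnames = list(names(me), "s1")),
                      meta_fl)
  expect_warning(sc <- score_pci(fit, g_fl), "flipping")
  expect_equal(unname(sc), unname(score_pci(
    fit, geno_matrix(matrix(d, dimnames = list(names(me), "s1")), meta))))
})

test_that("cross-validation recovers a noiseless genotype-driven ME", {
  set.seed(36)
  n <- 60
  D <- matrix(rbinom(n * 5, 2, 0.5), n,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("s%d", 1:5)))
  me <- stats::setNames(as.numeric(D[, 1]) - 1, rownames(D))
  cv <- crossvalidate_pci(me, geno_matrix(D), k_folds = 5, seed = 1)
  expect_gt(cv$r, 0.99)
})

test_that("cross-validation on a null cohort finds nothing", {
  set.seed(37)
  n <- 200
  D <- matrix(rbinom(n * 50, 2, 0.3), n,
              dimnames = list(sprintf("i%03d", 1:n), sprintf("s%02d", 1:50)))
  me <- stats::setNames(rnorm(n), rownames(D))
  # a permissive threshold keeps every fold non-empty so the pooled
  # out-of-fold correlation is computed on the full n = 200
  cv <- suppressMessages(
    crossvalidate_pci(me, geno_matrix(D), selection = list(alpha = 0.5),
                      k_folds = 5, seed = 2))
  expect_lt(abs(cv$r), 0.2)
})

test_that("self-replication reproduces the training correlation", {
  ch <- get_discovery_chain()
  fit <- fit_pci(ch$me, ch$cohort$genotypes, reference_snp_panel()$id)
  rep_same <- replicate_pci(fit, ch$prep, ch$cohort$genotypes,
                            ch$cohort$truth$module_gene_ids, "DRD2")
  expect_equal(rep_same$r, sqrt(fit$r_squared), tolerance = 1e-10)
})

test_that("replication uses frozen weights only", {
  ch <- get_discovery_chain()
  fit <- fit_pci(ch$me, ch$cohort$genotypes, reference_snp_panel()$id)
  rep_co <- simulate_cohort(default_cohort_config(
    "replication", seed = 901, n_background_genes = 5))
  r1 <- replicate_pci(fit, rep_co$expression, rep_co$genotypes,
                      ch$cohort$truth$module_gene_ids, "DRD2")
  # corrupting replication expression changes r only through the ME:
  # the PCI scores must be bit-identical
  corrupted <- expr_matrix(rep_co$expression$values +
                             matrix(rnorm(length(rep_co$expression$values)),
                                    nrow(rep_co$expression$values)),
                           rep_co$expression$quality)
  r2 <- replicate_pci(fit, corrupted, rep_co$genotypes,
                      ch$cohort$truth$module_gene_ids, "DRD2")
  expect_identical(r1$scores, r2$scores)
  expect_false(isTRUE(all.equal(r1$r, r2$r)))
  # permuted genotype labels break the association
  perm <- sample(rownames(rep_co$genotypes$dosage))
  gp <- rep_co$genotypes$dosage
  rownames(gp) <- perm
  r3 <- replicate_pci(fit, rep_co$expression,
                      geno_matrix(gp, rep_co$genotypes$meta),
                      ch$cohort$truth$module_gene_ids, "DRD2")
  expect_lt(abs(r3$r), 0.35)
  # excessive probe loss is refused
  few <- expr_matrix(rep_co$expression$values[1:30, , drop = FALSE],
                     rep_co$expression$quality)
  expect_error(replicate_pci(fit, few, rep_co$genotypes,
                             ch$cohort$truth$module_gene_ids, "DRD2"),
               "floor")
})
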