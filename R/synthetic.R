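#' Reported co-eQTL SNP panel (synthetic coordinates)
#'
#' The eight-SNP panel used as the default causal set of the cohort
#' generator: marker ids, host genes, minor allele frequencies and the
#' chromosome implied by each cytogenetic locus. Base-pair coordinates are
#' NOT published for these markers, so the `pos` column (and the derived
#' gene coordinates) are synthetic placements on the correct chromosome,
#' constructed so each SNP lies inside the +/- 100 kb window of its host
#' gene.
#'
#' @return data.frame with columns `id`, `chrom`, `pos`, `gene`, `maf`,
#'   `minor`, `major`.
#' @export
reference_snp_panel <- function() {
  data.frame(
    id = c("rs2486064", "rs6902039", "rs851436", "rs9297283",
           "rs12940715", "rs1805453", "rs11213916", "rs1037791"),
    chrom = c("1", "6", "2", "8", "17", "17", "11", "7"),
    pos = c(203185000, 24426000, 19550000, 98280000,
            71400000, 5360000, 111170000, 16830000),
    gene = c("CHIT1", "GPLD1", "OSR1", "POP1",
             "SDK2", "DHX33", "BTG4", "AGR2"),
    maf = c(0.22, 0.23, 0.48, 0.20, 0.20, 0.34, 0.30, 0.31),
    minor = "A", major = "G",
    stringsAsFactors = FALSE)
}

#' Cohort generator configuration
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' Defaults encode the discovery regime: 200 post-mortem-like samples, an
#' 85-gene module whose first principal component is tuned to explain 32.5%
#' of module variance, 915 unrelated background genes, and eight causal SNPs
#' (the [reference_snp_panel()] markers) whose additive effects jointly
#' account for ~45% of latent-factor variance, sized so the fitted index's
#' training R^2 lands near 0.38.
#'
#' @param n_samples number of samples.
#' @param n_module_genes module size (default 85).
#' @param n_background_genes genes outside the module.
#' @param n_snps total SNPs simulated (causal + null).
#' @param n_causal_snps number of causal SNPs (taken from the reference
#'   panel, recycled/truncated as needed).
#' @param maf_range MAF range for null SNPs, within (0, 0.5].
#' @param causal_beta effect of one minor-allele dose on the latent factor,
#'   in latent-SD units.
#' @param loading_range range of module-gene loadings on the latent factor.
#' @param pc1_target intended explained-variance fraction of the module's
#'   first principal component, in (0, 1).
#' @param confound_spec list of confound descriptors, each a list with
#'   `name`, `sampler` (function(n) -> numeric), `effect_range` (per-gene
#'   effect size range on standardized confound).
#' @param probe_dropout number of module genes absent from the generated
#'   expression matrix (replication-cohort probe loss; the seed gene is
#'   never dropped).
#' @param clinical_effect correlation between the latent factor and the
#'   clinical improvement score (0 disables the phenotype table's clinical
#'   link).
#' @param wm_load_effect effect of the latent factor on the 2-back minus
#'   1-back reaction-time difference, in within-subject SD units.
#' @param quality_range range of per-sample RNA quality scores (RIN-like).
#' @param responder_quantile improvement quantile above which a sample is
#'   labeled a treatment responder (default median split).
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200, n_module_genes = 85,
                          n_background_genes = 915, n_snps = 100,
                          n_causal_snps = 8, maf_range = c(0.05, 0.5),
                          causal_beta = 0.38, loading_range = c(0.4, 0.9),
                          pc1_target = 0.325, confound_spec = NULL,
                          probe_dropout = 0, clinical_effect = 0,
                          wm_load_effect = 0.25,
                          quality_range = c(7, 9.5),
                          responder_quantile = 0.5, seed = 1) {
  if (is.null(confound_spec)) {
    confound_spec <- list(
      list(name = "age", sampler = function(n) stats::runif(n, 18, 78),
           effect_range = c(-0.3, 0.3)),
      list(name = "sex", sampler = function(n) stats::rbinom(n, 1, 0.5),
           effect_range = c(-0.3, 0.3)))
  }
  cfg <- list(n_samples = n_samples, n_module_genes = n_module_genes,
              n_background_genes = n_background_genes, n_snps = n_snps,
              n_causal_snps = n_causal_snps, maf_range = maf_range,
              causal_beta = causal_beta, loading_range = loading_range,
              pc1_target = pc1_target, confound_spec = confound_spec,
              probe_dropout = probe_dropout,
              clinical_effect = clinical_effect,
              wm_load_effect = wm_load_effect,
              quality_range = quality_range,
              responder_quantile = responder_quantile, seed = seed)
  stopifnot(is_count(n_samples), n_samples >= 1,
            is_count(n_module_genes), n_module_genes >= 2,
            is_count(n_background_genes),
            is_count(n_snps), is_count(n_causal_snps),
            is_count(probe_dropout))
  if (n_causal_snps > n_snps) stop2("n_causal_snps exceeds n_snps")
  if (!(pc1_target > 0 && pc1_target < 1))
    stop2("pc1_target must lie in (0, 1)")
  if (!(all(maf_range > 0) && all(maf_range <= 0.5) &&
        maf_range[1] <= maf_range[2]))
    stop2("maf_range must lie within (0, 0.5]")
  if (abs(clinical_effect) > 1) stop2("|clinical_effect| must be <= 1")
  if (probe_dropout >= n_module_genes)
    stop2("probe_dropout must leave at least one module gene")
  structure(cfg, class = "cohort_config")
}

#' Preset cohort configurations
#'
#' `"discovery"` is the default Braincloud-like regime (n = 200, high RNA
#' quality). `"replication"` emulates a BrainEAC-like cohort: n = 50, five
#' module probes missing, broader (partly degraded) RNA quality, and an
#' attenuated genetic effect sized for a designed index-vs-eigengene
#' R^2 of about 0.15. `"clinical"` is the pooled treatment cohort: n = 87
#' with latent-improvement correlation 0.4.
#'
#' @param cohort one of "discovery", "replication", "clinical".
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(cohort = c("discovery", "replication",
                                             "clinical"),
                                  seed = 1, ...) {
  cohort <- match.arg(cohort)
  args <- switch(cohort,
    discovery = list(),
    replication = list(n_samples = 50, probe_dropout = 5,
                       causal_beta = 0.24, quality_range = c(4.5, 9)),
    clinical = list(n_samples = 87, clinical_effect = 0.4,
                    n_module_genes = 10, n_background_genes = 0))
  args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws each SNP i.i.d. per sample from Hardy-Weinberg proportions
#' ((1-p)^2, 2p(1-p), p^2) for minor-allele dose 0/1/2 at minor allele
#' frequency p.
#'
#' @param n_samples number of samples.
#' @param snp_meta data.frame with columns `id` and `maf` (optionally
#'   `chrom`, `pos`, `minor`, `major`); all MAFs in (0, 0.5].
#' @param seed integer seed.
#' @return a [geno_matrix].
#' @export
simulate_genotypes <- function(n_samples, snp_meta, seed = 1) {
  stopifnot(is_count(n_samples), n_samples >= 1,
            all(c("id", "maf") %in% names(snp_meta)))
  bad <- which(!(snp_meta$maf > 0 & snp_meta$maf <= 0.5))
  if (length(bad))
    stop2("MAF outside (0, 0.5] for SNP(s): ",
          paste(snp_meta$id[bad], collapse = ", "))
  set.seed(seed)
  dose <- vapply(snp_meta$maf,
                 function(p) stats::rbinom(n_samples, 2L, p),
                 numeric(n_samples))
  dimnames(dose) <- list(sprintf("S%04d", seq_len(n_samples)), snp_meta$id)
  geno_matrix(dose, snp_meta)
}

# Solve the common noise SD so the population first-eigenvalue fraction of
# the module correlation matrix (confound-adjusted part) equals pc1_target.
# Correlations are lambda_g lambda_h / sqrt((lambda_g^2+s^2)(lambda_h^2+s^2)).
solve_noise_scale <- function(loadings, pc1_target) {
  m <- length(loadings)
  frac <- function(s) {
    a <- loadings / sqrt(loadings^2 + s^2)
    R <- tcrossprod(a)
    diag(R) <- 1
    eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / m
  }
  lo <- 1e-4; hi <- 100
  if (pc1_target >= frac(lo) || pc1_target <= frac(hi))
    stop2(sprintf(paste0("pc1_target %.3f infeasible for this loading_range:",
                         " attainable range is (%.4f, %.4f)"),
                  pc1_target, frac(hi), frac(lo)))
  stats::uniroot(function(s) frac(s) - pc1_target, c(lo, hi),
                 tol = 1e-6)$root
}

#' Simulate clinical improvement outcomes
#'
#' Generates an improvement score correlated with the latent module factor,
#' `improvement = r * L + sqrt(1 - r^2) * eta`, and a binary responder label
#' for samples whose improvement exceeds the configured quantile.
#'
#' @param latent numeric vector of latent factor values (named by sample).
#' @param clinical_effect target correlation r, with |r| <= 1.
#' @param responder_quantile quantile threshold for the responder label
#'   (default 0.5, a median split).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `improvement`, `responder`.
#' @export
simulate_clinical_outcomes <- function(latent, clinical_effect,
                                       responder_quantile = 0.5, seed = 1) {
  if (abs(clinical_effect) > 1) stop2("|clinical_effect| must be <= 1")
  set.seed(seed)
  eta <- stats::rnorm(length(latent))
  imp <- clinical_effect * latent + sqrt(1 - clinical_effect^2) * eta
  thr <- stats::quantile(imp, responder_quantile)
  data.frame(sample = names(latent) %||% seq_along(latent),
             improvement = imp,
             responder = as.integer(imp > thr),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Generates a cohort with the generative structure the downstream analysis
#' assumes: Hardy-Weinberg genotypes; a latent module factor
#' `L = sum_s beta * dose_s + eps` scaled to unit population variance;
#' module genes loading on the latent factor with a common noise scale
#' solved numerically so the module's expected first-PC explained-variance
#' fraction equals `pc1_target`; linear demographic confounds on all genes;
#' independent background genes; and optional clinical/behavioral
#' phenotypes tied to the latent factor.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   ([expr_matrix]), `genotypes` ([geno_matrix]), `covariates`
#'   (data.frame), `phenotypes` (data.frame or NULL), `gene_coords`
#'   (data.frame), `risk_genes` (character), and `truth` (latent factor,
#'   module gene ids, loadings, causal SNP ids and betas, seed gene id).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m <- cfg$n_module_genes
  samples <- sprintf("S%04d", seq_len(n))

  ## --- gene ids and synthetic coordinates -------------------------------
  panel <- reference_snp_panel()
  # three module members carry known risk-gene names; they anchor the
  # enrichment test (risk hits inside the module) and the hub-rank check
  risk_anchors <- c("GATAD2A", "GALNT10", "ZSCAN23")
  module_genes <- c("DRD2", panel$gene, risk_anchors,
                    sprintf("MOD%03d",
                            seq_len(max(0, m - 1 - nrow(panel) -
                                          length(risk_anchors)))))
  module_genes <- module_genes[seq_len(m)]
  seed_gene <- "DRD2"
  bg_genes <- if (cfg$n_background_genes > 0)
    sprintf("BG%04d", seq_len(cfg$n_background_genes)) else character()

  # module genes: panel genes keep their panel chromosome; the rest (and all
  # background genes) are spread over chromosomes 1-22 at 1 Mb spacing
  all_genes <- c(module_genes, bg_genes)
  chrom <- rep(as.character(rep(1:22, length.out = 40)),
               length.out = length(all_genes))
  start <- 1e6 + 3e6 * (seq_along(all_genes) %/% 22)
  gene_coords <- data.frame(gene = all_genes, chrom = chrom,
                            start = round(start),
                            end = round(start) + 20000,
                            stringsAsFactors = FALSE)
  in_panel <- match(panel$gene, gene_coords$gene)
  gene_coords$chrom[in_panel] <- panel$chrom
  gene_coords$start[in_panel] <- panel$pos - 30000
  gene_coords$end[in_panel] <- panel$pos + 30000
  drd2 <- match("DRD2", gene_coords$gene)
  gene_coords$chrom[drd2] <- "11"
  gene_coords$start[drd2] <- 113409000
  gene_coords$end[drd2] <- 113475000

  ## --- SNP metadata ------------------------------------------------------
  k <- cfg$n_causal_snps
  causal_meta <- if (k > 0) {
    idx <- rep_len(seq_len(nrow(panel)), k)
    cm <- panel[idx, c("id", "chrom", "pos", "maf", "minor", "major")]
    if (k > nrow(panel)) cm$id <- make.unique(cm$id, sep = "_x")
    cm
  } else panel[0, c("id", "chrom", "pos", "maf", "minor", "major")]
  n_null <- cfg$n_snps - k
  null_meta <- NULL
  if (n_null > 0) {
    # half the null SNPs inside module-gene windows (screen candidates),
    # half far outside every window (exercise the window filter)
    host <- gene_coords[rep_len(seq_len(m), n_null), ]
    inside <- seq_len(n_null) %% 2 == 0
    pos <- ifelse(inside, host$start + 5000, host$end + 250000)
    null_meta <- data.frame(
      id = sprintf("snp%04d", seq_len(n_null)),
      chrom = host$chrom, pos = pos,
      maf = stats::runif(n_null, cfg$maf_range[1], cfg$maf_range[2]),
      minor = "A", major = "G", stringsAsFactors = FALSE)
  }
  snp_meta <- rbind(causal_meta, null_meta)
  rownames(snp_meta) <- NULL

  ## --- genotypes and latent factor --------------------------------------
  geno <- simulate_genotypes(n, snp_meta, seed = split_seed(cfg$seed, "geno"))
  betas <- rep(cfg$causal_beta, k)
  h2 <- sum(betas^2 * 2 * causal_meta$maf * (1 - causal_meta$maf))
  if (h2 >= 1)
    stop2("causal_beta too large: genetic variance of latent factor >= 1")
  set.seed(split_seed(cfg$seed, "latent"))
  genetic <- if (k > 0)
    drop(geno$dosage[, causal_meta$id, drop = FALSE] %*% betas) else
    numeric(n)
  latent <- genetic + stats::rnorm(n, sd = sqrt(1 - h2))
  names(latent) <- samples

  ## --- confounds ---------------------------------------------------------
  set.seed(split_seed(cfg$seed, "confound"))
  n_genes <- length(all_genes)
  conf_vals <- list(); conf_eff <- list()
  for (cs in cfg$confound_spec) {
    v <- cs$sampler(n)
    conf_vals[[cs$name]] <- v
    conf_eff[[cs$name]] <- stats::runif(n_genes, cs$effect_range[1],
                                        cs$effect_range[2])
  }
  covariates <- data.frame(sample = samples, conf_vals,
                           stringsAsFactors = FALSE)  # quality added below
  conf_term <- matrix(0, n_genes, n)
  for (nm in names(conf_vals)) {
    z <- as.numeric(scale(conf_vals[[nm]]))
    conf_term <- conf_term + tcrossprod(conf_eff[[nm]], z)
  }

  ## --- expression --------------------------------------------------------
  set.seed(split_seed(cfg$seed, "expr"))
  loadings <- stats::runif(m, cfg$loading_range[1], cfg$loading_range[2])
  loadings[1] <- cfg$loading_range[2]       # seed gene: strongest loading
  names(loadings) <- module_genes
  # GATAD2A sits among the hubs: swap it the fourth-largest loading
  if ("GATAD2A" %in% module_genes && m >= 4) {
    i4 <- order(loadings, decreasing = TRUE)[4]
    ig <- match("GATAD2A", module_genes)
    tmp <- loadings[ig]
    loadings[ig] <- loadings[i4]
    loadings[i4] <- tmp
  }
  s <- solve_noise_scale(loadings, cfg$pc1_target)
  X <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  X[seq_len(m), ] <- s * X[seq_len(m), ] +
    tcrossprod(loadings, latent)
  X <- X + conf_term
  dimnames(X) <- list(all_genes, samples)
  quality <- stats::runif(n, cfg$quality_range[1], cfg$quality_range[2])
  covariates$quality <- quality   # RIN analogue; carried for QC, not a confound

  dropped <- character()
  if (cfg$probe_dropout > 0) {
    set.seed(split_seed(cfg$seed, "dropout"))
    dropped <- sample(setdiff(module_genes, seed_gene), cfg$probe_dropout)
    X <- X[setdiff(rownames(X), dropped), , drop = FALSE]
  }
  expression <- expr_matrix(X, quality)

  ## --- phenotypes --------------------------------------------------------
  phenotypes <- NULL
  set.seed(split_seed(cfg$seed, "pheno"))
  clin <- simulate_clinical_outcomes(latent, cfg$clinical_effect,
                                     cfg$responder_quantile,
                                     seed = split_seed(cfg$seed, "clinical"))
  set.seed(split_seed(cfg$seed, "behav"))
  rt1 <- 500 + 50 * stats::rnorm(n)
  rt2 <- 600 + 50 * (cfg$wm_load_effect * latent +
                       sqrt(max(0, 1 - cfg$wm_load_effect^2)) *
                       stats::rnorm(n))
  phenotypes <- data.frame(
    sample = samples,
    rt_1back = rt1, rt_2back = rt2,
    improvement = clin$improvement, responder = clin$responder,
    stringsAsFactors = FALSE)

  ## --- risk genes: module anchors + background decoys --------------------
  risk_genes <- c(intersect(risk_anchors, module_genes),
                  utils::head(bg_genes, 5))

  structure(list(
    expression = expression, genotypes = geno, covariates = covariates,
    phenotypes = phenotypes, gene_coords = gene_coords,
    risk_genes = risk_genes,
    truth = list(latent = latent, module_gene_ids = module_genes,
                 loadings = loadings, dropped_probes = dropped,
                 causal_snp_ids = causal_meta$id, causal_betas = betas,
                 noise_scale = s, seed_gene = seed_gene,
                 genetic_component = genetic),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> n=%d; %d genes (%d module, %d ",
                     "dropped); %d SNPs (%d causal)\n"),
              x$config$n_samples, nrow(x$expression$values),
              x$config$n_module_genes, length(x$truth$dropped_probes),
              ncol(x$genotypes$dosage), length(x$truth$causal_snp_ids)))
  invisible(x)
}
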