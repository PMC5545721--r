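#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene ids and whose
#' header row holds sample ids; values are numeric, `NA` for missing. An
#' optional companion row is not used — quality scores travel in the
#' covariate table and can be attached with the `quality` argument.
#'
#' @param path TSV file path.
#' @param quality optional named numeric vector of per-sample quality
#'   scores.
#' @return an [expr_matrix].
#' @export
read_expression <- function(path, quality = NULL) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop2("malformed expression TSV: ", path)
  genes <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop2("non-numeric expression values in ", path)
  rownames(m) <- genes
  if (!is.null(quality)) quality <- quality[colnames(m)]
  expr_matrix(m, quality)
}

#' Write an expression matrix to TSV
#' @param expr an [expr_matrix].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  # full precision so a write -> read round trip is bit-identical
  vals <- format(expr$values, digits = 17, trim = TRUE,
                 scientific = TRUE)
  d <- data.frame(gene = gene_ids(expr), vals,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix from TSV
#'
#' Samples x SNPs dosage matrix: first column sample ids, header row SNP
#' ids, values in \{0, 1, 2, NA\}. An invalid dosage is rejected naming the
#' offending row and column.
#'
#' @param path TSV file path.
#' @param meta optional SNP metadata data.frame (`id`, `chrom`, `pos`,
#'   `minor`, `major`, `maf`) or path to its TSV.
#' @return a [geno_matrix].
#' @export
read_genotypes <- function(path, meta = NULL) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop2("malformed genotype TSV: ", path)
  samples <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- samples
  if (is.character(meta)) meta <- utils::read.delim(
    meta, stringsAsFactors = FALSE)
  bad <- which(!(m %in% c(0, 1, 2) | is.na(m)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(m))
    stop2(sprintf("invalid dosage '%s' at line %d (sample '%s'), column '%s'",
                  m[bad[1]], idx[1] + 1L, samples[idx[1]],
                  colnames(m)[idx[2]]))
  }
  storage.mode(m) <- "numeric"
  geno_matrix(m, meta)
}

#' Write a genotype matrix (dosages + metadata) to TSV
#' @param geno a [geno_matrix].
#' @param path dosage TSV output path.
#' @param meta_path optional metadata TSV output path.
#' @export
write_genotypes <- function(geno, path, meta_path = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- data.frame(sample = rownames(geno$dosage), geno$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(geno$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read biallelic genotypes from a minimal VCF
#'
#' Loads GT fields from a VCF (plain text or bgzipped), converting to
#' minor-allele dosage. Multi-allelic sites are skipped with a logged
#' count. The ALT allele is taken as the counted allele; if its sample
#' frequency exceeds 0.5 the dosage is flipped so dosage counts the minor
#' allele, and the metadata records which allele is minor.
#'
#' @param path VCF file path.
#' @return a [geno_matrix].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("vcfR is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) log_note("multiallelic_sites_skipped", count = sum(multi))
  keep <- which(!multi)
  if (!length(keep)) stop2("no biallelic site in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  dose <- t(apply(gt, c(1, 2), count_alt))   # samples x SNPs
  ids <- ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]),
                fix[keep, "ID"])
  colnames(dose) <- ids
  ref <- fix[keep, "REF"]; alt <- fix[keep, "ALT"]
  af <- colMeans(dose, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  dose[, flip] <- 2 - dose[, flip, drop = FALSE]
  meta <- data.frame(id = ids,
                     chrom = normalize_chrom(fix[keep, "CHROM"]),
                     pos = as.integer(fix[keep, "POS"]),
                     minor = ifelse(flip, ref, alt),
                     major = ifelse(flip, alt, ref),
                     maf = pmin(af, 1 - af),
                     stringsAsFactors = FALSE)
  geno_matrix(dose, meta)
}

#' Read a generic sample table (covariates or phenotypes)
#'
#' Tab-delimited with a `sample` id column; duplicate sample ids are
#' rejected.
#'
#' @param path TSV path.
#' @return data.frame with rownames set to sample ids.
#' @export
read_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  idcol <- if ("sample" %in% names(d)) "sample" else names(d)[1]
  if (anyDuplicated(d[[idcol]]))
    stop2("duplicate sample ids in ", path)
  rownames(d) <- d[[idcol]]
  d
}

#' Write a simulated cohort to a directory
#'
#' Writes `expression.tsv`, `genotypes.tsv`, `snp_meta.tsv`,
#' `covariates.tsv`, `phenotypes.tsv`, `gene_coords.tsv`,
#' `risk_genes.txt` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"),
                  file.path(dir, "snp_meta.tsv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_coords, file.path(dir, "gene_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$risk_genes, file.path(dir, "risk_genes.txt"))
  truth <- cohort$truth
  truth$latent <- unname(truth$latent)
  truth$loadings <- unname(truth$loadings)
  truth$genetic_component <- unname(truth$genetic_component)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing -> network construction -> seed-module detection
#' -> risk-gene enrichment -> co-eQTL scan -> SNP selection -> PCI fit and
#' cross-validation -> optional frozen-weight replication -> optional
#' clinical associations, writing each stage's outputs before the next
#' begins and recording everything in a run manifest.
#'
#' @param expr discovery [expr_matrix].
#' @param geno discovery [geno_matrix].
#' @param covars covariate data.frame.
#' @param gene_coords gene coordinate table (for the SNP window filter).
#' @param seed_gene seed gene id (e.g. `"DRD2"`).
#' @param out_dir output directory.
#' @param risk_genes optional character vector of risk-gene ids for the
#'   enrichment test (background = all genes in `expr`).
#' @param phenotypes optional phenotype data.frame with `improvement` and
#'   `responder` columns for the clinical associations.
#' @param replication optional list with elements `expr` and `geno` for
#'   frozen-weight replication.
#' @param net_config a [network_config()].
#' @param selection selection settings list (see [crossvalidate_pci()]).
#' @param min_quality sample QC threshold (strict `>`; `NULL` skips QC).
#' @param window_bp SNP-to-gene window half width.
#' @param k_folds cross-validation folds.
#' @param seed master seed.
#' @return list of class `run_manifest` (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(expr, geno, covars, gene_coords, seed_gene,
                         out_dir, risk_genes = NULL, phenotypes = NULL,
                         replication = NULL,
                         net_config = network_config(),
                         selection = list(), min_quality = NULL,
                         window_bp = 100000, k_folds = 5, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(); t0 <- Sys.time()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    stages[[name]] <<- TRUE
    res
  }

  prep <- run_stage("prep", function() {
    e <- expr
    if (!is.null(min_quality)) e <- filter_by_quality(e, min_quality)
    residualize(e, covars[setdiff(names(covars), c("sample", "quality"))])
  })
  write_expression(prep, file.path(out_dir, "expression_residualized.tsv"))

  net <- run_stage("network", function() {
    pw <- select_soft_power(prep, net_config)
    adj <- adjacency(prep, pw$power, net_config$signed)
    tom <- topological_overlap(adj)
    part <- detect_modules(tom, net_config)
    list(power = pw, adj = adj, partition = part)
  })
  mod <- run_stage("seed_module", function()
    seed_module(net$partition, seed_gene))
  me <- run_stage("eigengene", function()
    module_eigengene(prep, mod$members, seed_gene))
  kin <- intramodular_connectivity(net$adj, mod$members)
  kme <- stats::cor(t(prep$values), me$scores)[, 1]
  modules_tab <- data.frame(
    gene = names(net$partition$labels),
    module = as.integer(net$partition$labels),
    kME = kme[names(net$partition$labels)],
    kIN = kin$kIN[match(names(net$partition$labels), kin$gene)],
    stringsAsFactors = FALSE)
  utils::write.table(modules_tab, file.path(out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(me$scores), ME = unname(me$scores)),
    file.path(out_dir, "eigengene.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  enrichment <- NULL
  if (!is.null(risk_genes)) {
    enrichment <- run_stage("enrichment", function() {
      bg <- gene_ids(prep)
      hits_bg <- intersect(risk_genes, bg)
      hits_mod <- intersect(risk_genes, mod$members)
      list(p = hypergeom_enrichment(length(mod$members),
                                    length(hits_mod), length(bg),
                                    length(hits_bg)),
           module_hits = length(hits_mod),
           background_hits = length(hits_bg))
    })
  }

  candidates <- run_stage("snp_windows", function() {
    mg <- gene_coords[gene_coords$gene %in% mod$members, , drop = FALSE]
    snps_in_gene_windows(geno$meta, mg, window_bp)
  })
  geno_cand <- geno_matrix(
    geno$dosage[, candidates$snp_ids, drop = FALSE],
    geno$meta[geno$meta$id %in% candidates$snp_ids, , drop = FALSE])

  scan <- run_stage("coeqtl_scan", function() coeqtl_scan(me, geno_cand))
  utils::write.table(scan, file.path(out_dir, "coeqtl_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sel_cfg <- utils::modifyList(list(method = "fixed", alpha = 0.005,
                                    r2_max = 0.2, plateau_eps = 0.005,
                                    min_group = 5), selection)
  sel <- run_stage("selection", function()
    select_snps(scan, geno_cand, me = me, method = sel_cfg$method,
                alpha = sel_cfg$alpha, r2_max = sel_cfg$r2_max,
                plateau_eps = sel_cfg$plateau_eps,
                min_group = sel_cfg$min_group))
  model <- run_stage("pci_fit", function()
    fit_pci(me, geno_cand, sel$snps, min_group = sel_cfg$min_group))
  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("coexpci")),
         snps = model$snps, weights = as.data.frame(model$weights),
         grand_mean = model$grand_mean, r_squared = model$r_squared,
         selection = sel_cfg),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  scores <- score_pci(model, geno)
  utils::write.table(
    data.frame(sample = names(scores), pci = unname(scores)),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  cv <- run_stage("pci_cv", function()
    crossvalidate_pci(me, geno_cand, selection = sel_cfg,
                      k_folds = k_folds,
                      seed = split_seed(seed, "cv")))

  repl <- NULL
  if (!is.null(replication)) {
    repl <- run_stage("replication", function()
      replicate_pci(model, replication$expr, replication$geno,
                    mod$members, seed_gene))
  }

  clinical <- NULL
  if (!is.null(phenotypes) &&
      all(c("improvement", "responder") %in% names(phenotypes))) {
    clinical <- run_stage("clinical", function() {
      ph <- phenotypes
      ids <- intersect(ph$sample %||% rownames(ph), names(scores))
      ph <- ph[match(ids, ph$sample %||% rownames(ph)), , drop = FALSE]
      sp <- spearman_assoc(ph$improvement, scores[ids],
                           sidedness = "greater")
      roc <- roc_auc(scores[ids], ph$responder)
      list(spearman = sp, roc = roc)
    })
  }

  out_files <- list.files(out_dir, full.names = TRUE)
  manifest <- structure(list(
    version = as.character(utils::packageVersion("coexpci")),
    seed = seed,
    started = format(t0), finished = format(Sys.time()),
    stages = names(stages),
    power = net$power$power, scale_free_r2 = net$power$r2,
    module_label = mod$label, module_size = length(mod$members),
    explained_variance = me$explained_variance,
    enrichment_p = if (is.null(enrichment)) NULL else enrichment$p,
    n_candidate_snps = length(candidates$snp_ids),
    selected_snps = model$snps,
    training_r2 = model$r_squared,
    cv_r = cv$r,
    replication_r = if (is.null(repl)) NULL else repl$r,
    replication_p = if (is.null(repl)) NULL else repl$p_one_tailed,
    clinical_rho = if (is.null(clinical)) NULL else
      clinical$spearman$estimate,
    clinical_auc = if (is.null(clinical)) NULL else clinical$roc$auc,
    checksums = as.list(tools::md5sum(out_files))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  module size %d, ME explained variance %.3f\n",
              x$module_size, x$explained_variance))
  cat(sprintf("  %d SNPs selected, training R^2 = %.3f, CV r = %.3f\n",
              length(x$selected_snps), x$training_r2, x$cv_r))
  if (!is.null(x$replication_r))
    cat(sprintf("  replication r = %.3f (one-tailed p = %.3g)\n",
                x$replication_r, x$replication_p))
  invisible(x)
}
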