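#' Screen SNPs for association with the module eigengene (co-eQTL scan)
#'
#' Per SNP, ordinary least squares of the eigengene on additive minor-allele
#' dosage (plus optional covariates), with a two-sided t-test on the dosage
#' slope. SNPs failing the testability preconditions (monomorphic after
#' missing-genotype removal, or fewer than 10 usable samples) are flagged
#' `"untestable"` rather than dropped.
#'
#' @param me an `eigengene` (or named numeric vector of eigengene scores).
#' @param geno a [geno_matrix] with samples matching the eigengene.
#' @param covars optional data.frame of covariates (not included by default
#'   because the eigengene is computed from residualized expression).
#' @return data.frame of class `coeqtl_table`: per SNP `slope`, `t`, `p`,
#'   `n`, genotype-group counts `n0`, `n1`, `n2`, and `status`.
#' @export
coeqtl_scan <- function(me, geno, covars = NULL) {
  scores <- if (inherits(me, "eigengene")) me$scores else me
  stopifnot(inherits(geno, "geno_matrix"))
  common <- intersect(names(scores), rownames(geno$dosage))
  if (length(common) < 10) stop2("fewer than 10 samples shared by ME and genotypes")
  y_all <- scores[common]
  D <- geno$dosage[common, , drop = FALSE]
  Z <- NULL
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    if (!is.null(rownames(covars)) && all(common %in% rownames(covars)))
      covars <- covars[common, , drop = FALSE]
    Z <- covariate_design(covars)
  }
  snps <- colnames(D)
  out <- data.frame(snp = snps, slope = NA_real_, t = NA_real_,
                    p = NA_real_, n = NA_integer_, n0 = NA_integer_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  for (j in seq_along(snps)) {
    x <- D[, j]
    ok <- !is.na(x)
    n <- sum(ok)
    out$n[j] <- n
    out$n0[j] <- sum(x[ok] == 0); out$n1[j] <- sum(x[ok] == 1)
    out$n2[j] <- sum(x[ok] == 2)
    if (n < 10 || length(unique(x[ok])) < 2) {
      out$status[j] <- "untestable"
      next
    }
    y <- y_all[ok]; xv <- x[ok]
    if (is.null(Z)) {
      sxx <- sum((xv - mean(xv))^2)
      b <- sum((xv - mean(xv)) * (y - mean(y))) / sxx
      res <- y - mean(y) - b * (xv - mean(xv))
      df <- n - 2
      se <- sqrt(sum(res^2) / df / sxx)
    } else {
      X <- cbind(Z[ok, , drop = FALSE], dose = xv)
      fit <- stats::lm.fit(X, y)
      b <- fit$coefficients[["dose"]]
      df <- n - fit$rank
      XtXinv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(sum(fit$residuals^2) / df * XtXinv[ncol(X), ncol(X)])
    }
    tval <- b / se
    out$slope[j] <- b
    out$t[j] <- tval
    out$p[j] <- 2 * stats::pt(-abs(tval), df)
  }
  class(out) <- c("coeqtl_table", "data.frame")
  out
}

#' Bonferroni correction
#'
#' `min(1, p * n_tests)` with an explicit family size (the screening family
#' may exceed the number of reported SNPs).
#'
#' @param pvalues numeric p-values.
#' @param n_tests family size (>= 1).
#' @return corrected p-values.
#' @export
bonferroni <- function(pvalues, n_tests) {
  stopifnot(n_tests >= 1, all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  pmin(1, pvalues * n_tests)
}

#' Greedy LD pruning
#'
#' Sorts SNPs by ascending p-value (ties broken by SNP id) and accepts a
#' SNP iff its squared dosage correlation with every previously accepted
#' SNP is below `r2_max`.
#'
#' @param geno a [geno_matrix].
#' @param pvalues named numeric vector of p-values covering all SNPs (or a
#'   `coeqtl_table`).
#' @param r2_max maximum allowed squared correlation (default 0.2).
#' @return character vector of retained ("independent") SNP ids.
#' @export
ld_prune <- function(geno, pvalues, r2_max = 0.2) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (inherits(pvalues, "coeqtl_table"))
    pvalues <- stats::setNames(pvalues$p, pvalues$snp)
  snps <- colnames(geno$dosage)
  if (!all(snps %in% names(pvalues)))
    stop2("pvalues must cover every SNP")
  p <- pvalues[snps]
  testable <- snps[!is.na(p)]
  ord <- testable[order(p[testable], testable)]
  accepted <- character()
  for (s in ord) {
    if (length(accepted)) {
      r <- suppressWarnings(
        stats::cor(geno$dosage[, s], geno$dosage[, accepted, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      if (any(r^2 >= r2_max)) next
    }
    accepted <- c(accepted, s)
  }
  accepted
}

#' Select SNPs for the polygenic co-expression index
#'
#' Two strategies over LD-pruned SNPs: `"fixed"` keeps pruned SNPs with
#' `p < alpha` (strict, default alpha 0.005); `"plateau"` adds pruned SNPs
#' in ascending-p order, refitting the index on the training data at each
#' step, and stops once the incremental training R^2 falls below
#' `plateau_eps` for two consecutive additions.
#'
#' @param coeqtl a `coeqtl_table` from [coeqtl_scan()].
#' @param geno the training [geno_matrix].
#' @param me training eigengene (needed for the plateau method).
#' @param method `"fixed"` or `"plateau"`.
#' @param alpha fixed-threshold p-value cutoff (default 0.005).
#' @param r2_max LD pruning threshold (default 0.2).
#' @param plateau_eps minimum incremental R^2 (default 0.005).
#' @param min_group smallest genotype group kept unmerged when refitting.
#' @return list with `snps` (selected ids), `method`, and for the plateau
#'   method a `trace` data.frame of R^2 versus model size.
#' @export
select_snps <- function(coeqtl, geno, me = NULL,
                        method = c("fixed", "plateau"), alpha = 0.005,
                        r2_max = 0.2, plateau_eps = 0.005, min_group = 5) {
  method <- match.arg(method)
  pruned <- ld_prune(geno, coeqtl, r2_max)
  p <- stats::setNames(coeqtl$p, coeqtl$snp)[pruned]
  if (method == "fixed") {
    sel <- pruned[p < alpha]
    if (!length(sel))
      stop2("empty model: no pruned SNP reaches p < ", alpha)
    return(list(snps = sel, method = "fixed", alpha = alpha,
                r2_max = r2_max))
  }
  if (is.null(me)) stop2("plateau selection needs the training eigengene")
  ord <- pruned[order(p, pruned)]
  scores <- if (inherits(me, "eigengene")) me$scores else me
  trace <- data.frame(k = seq_along(ord), snp = ord, r2 = NA_real_,
                      adj_r2 = NA_real_)
  # the plateau is judged on adjusted R^2: the raw training R^2 grows by
  # about (groups - 1)/n for every SNP added, informative or not
  below <- 0L; last_r2 <- 0; stop_k <- length(ord)
  for (k in seq_along(ord)) {
    fit <- suppressWarnings(
      fit_pci(scores, geno, ord[seq_len(k)], min_group = min_group))
    trace$r2[k] <- fit$r_squared
    trace$adj_r2[k] <- fit$adj_r_squared
    if (k > 1) {
      below <- if (trace$adj_r2[k] - last_r2 < plateau_eps) below + 1L
      else 0L
      if (below >= 2L) break
    }
    last_r2 <- trace$adj_r2[k]
  }
  # keep SNPs up to the last addition that still cleared the increment
  done <- which(!is.na(trace$adj_r2))
  gains <- c(trace$adj_r2[done[1]], diff(trace$adj_r2[done]))
  informative <- which(gains >= plateau_eps)
  stop_k <- if (length(informative)) max(informative) else 1L
  sel <- ord[seq_len(stop_k)]
  if (!length(sel)) stop2("empty model: plateau selection kept no SNP")
  list(snps = sel, method = "plateau", plateau_eps = plateau_eps,
       r2_max = r2_max, trace = trace[!is.na(trace$r2), ])
}

#' Fit the polygenic co-expression index (PCI)
#'
#' For each selected SNP, the weight of genotype g is the mean training
#' eigengene within that genotype group minus the grand mean of the
#' training eigengene. Genotype groups smaller than `min_group` are merged
#' into the adjacent dosage group toward the heterozygote (2 -> 1, 0 -> 1)
#' before computing group means. An individual's index is the sum of the
#' weights of their genotypes across SNPs, so greater PCI predicts greater
#' module co-expression.
#'
#' @param me training eigengene (an `eigengene` or named numeric vector).
#' @param geno training [geno_matrix].
#' @param selected_ids SNP ids entering the model.
#' @param min_group smallest genotype group kept unmerged (default 5).
#' @return an object of class `pci_model` with per-SNP weight vectors,
#'   the training grand mean, training R^2 and selection metadata.
#' @seealso [score_pci()], [crossvalidate_pci()], [replicate_pci()]
#' @export
fit_pci <- function(me, geno, selected_ids, min_group = 5) {
  scores <- if (inherits(me, "eigengene")) me$scores else me
  stopifnot(inherits(geno, "geno_matrix"))
  if (!length(selected_ids)) stop2("refusing to fit PCI on an empty SNP set")
  missing_ids <- setdiff(selected_ids, colnames(geno$dosage))
  if (length(missing_ids))
    stop2("SNP(s) absent from genotypes: ",
          paste(missing_ids, collapse = ", "))
  common <- intersect(names(scores), rownames(geno$dosage))
  y <- scores[common]
  grand <- mean(y)
  weights <- matrix(NA_real_, nrow = 3, ncol = 0,
                    dimnames = list(c("0", "1", "2"), NULL))
  kept <- character()
  n_params <- 0L
  for (s in selected_ids) {
    g <- geno$dosage[common, s]
    ok <- !is.na(g)
    counts <- vapply(0:2, function(d) sum(g[ok] == d), numeric(1))
    # merge small homozygote groups toward the heterozygote
    grp <- c("0", "1", "2")
    if (counts[3] > 0 && counts[3] < min_group) grp[3] <- "1"
    if (counts[1] > 0 && counts[1] < min_group) grp[1] <- "1"
    gm <- grp[g[ok] + 1]
    if (length(unique(gm)) < 2) {
      warning("SNP ", s, " collapses to one genotype group; dropped",
              call. = FALSE)
      next
    }
    means <- tapply(y[ok], gm, mean)
    w <- means[grp] - grand
    w[is.na(w)] <- 0                        # genotype never observed
    weights <- cbind(weights, stats::setNames(as.numeric(w), NULL))
    colnames(weights)[ncol(weights)] <- s
    kept <- c(kept, s)
    n_params <- n_params + length(unique(gm)) - 1L
  }
  if (!length(kept)) stop2("refusing to fit PCI: all SNPs dropped")
  model <- structure(list(
    snps = kept, weights = weights, grand_mean = grand,
    min_group = min_group, n_train = length(common), n_params = n_params,
    alleles = if (all(c("minor", "major") %in% names(geno$meta)))
      geno$meta[match(kept, geno$meta$id), c("id", "minor", "major")]
    else NULL,
    train_me = y, r_squared = NA_real_), class = "pci_model")
  pci <- score_pci(model, geno)
  model$train_pci <- stats::setNames(as.numeric(pci[common]), common)
  model$r_squared <- if (stats::sd(model$train_pci) == 0) 0 else
    stats::cor(model$train_pci, y)^2
  # adjusted for the genotype-group means the weights consume, so adding
  # uninformative SNPs does not inflate the in-sample fit
  model$adj_r_squared <- max(0, 1 - (1 - model$r_squared) *
                               (model$n_train - 1) /
                               max(1, model$n_train - n_params - 1))
  model
}

#' Score individuals with a fitted PCI model
#'
#' `PCI_i = sum_s w(s, g_is)`; a missing genotype contributes 0 (the
#' centered null contribution). Samples missing more than half of the model
#' SNPs are flagged. If a cohort's recorded minor allele disagrees with the
#' model's, the dosage is flipped (2 - g) with a warning.
#'
#' @param model a `pci_model`.
#' @param geno a [geno_matrix] containing every model SNP.
#' @return named numeric vector of scores, with attribute
#'   `flagged_samples`.
#' @export
score_pci <- function(model, geno) {
  stopifnot(inherits(model, "pci_model"), inherits(geno, "geno_matrix"))
  absent <- setdiff(model$snps, colnames(geno$dosage))
  if (length(absent))
    stop2("cohort lacks model SNP(s): ", paste(absent, collapse = ", "))
  D <- geno$dosage[, model$snps, drop = FALSE]
  if (!is.null(model$alleles) &&
      all(c("minor", "major") %in% names(geno$meta))) {
    cm <- geno$meta[match(model$snps, geno$meta$id), ]
    flip <- which(!is.na(cm$minor) & cm$minor == model$alleles$major &
                    cm$major == model$alleles$minor)
    if (length(flip)) {
      warning("flipping dosage for SNP(s) with swapped minor allele: ",
              paste(model$snps[flip], collapse = ", "), call. = FALSE)
      D[, flip] <- 2 - D[, flip]
    }
  }
  scores <- numeric(nrow(D))
  for (s in model$snps) {
    g <- D[, s]
    w <- model$weights[, s]
    contrib <- w[as.character(g)]
    contrib[is.na(contrib)] <- 0
    scores <- scores + contrib
  }
  names(scores) <- rownames(D)
  flagged <- rownames(D)[rowMeans(is.na(D)) > 0.5]
  if (length(flagged))
    log_note("samples_with_majority_missing_genotypes", n = length(flagged))
  attr(scores, "flagged_samples") <- flagged
  scores
}

#' @export
print.pci_model <- function(x, ...) {
  cat(sprintf("<pci_model> %d SNPs, trained on %d samples, training R^2 = %.3f\n",
              length(x$snps), x$n_train, x$r_squared))
  cat("SNPs:", paste(x$snps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pci_model <- function(object, ...) object$weights

#' @export
predict.pci_model <- function(object, geno, ...) score_pci(object, geno)

#' @export
fitted.pci_model <- function(object, ...) object$grand_mean + object$train_pci

#' @export
residuals.pci_model <- function(object, ...) object$train_me - fitted(object)

#' @export
summary.pci_model <- function(object, ...) {
  structure(list(n_snps = length(object$snps), n_train = object$n_train,
                 r_squared = object$r_squared,
                 weights = object$weights,
                 weight_range = range(object$weights)),
            class = "summary.pci_model")
}

#' @export
print.summary.pci_model <- function(x, ...) {
  cat(sprintf("PCI model: %d SNPs, n_train = %d, training R^2 = %.3f\n",
              x$n_snps, x$n_train, x$r_squared))
  cat("Genotype weights (rows = dosage 0/1/2):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
plot.pci_model <- function(x, ...) {
  graphics::plot(x$train_pci, x$train_me,
                 xlab = "PCI", ylab = "module eigengene",
                 main = sprintf("training fit, R^2 = %.2f", x$r_squared),
                 ...)
  graphics::abline(stats::lm(x$train_me ~ x$train_pci), col = 2)
  invisible(x)
}

#' Cross-validate the PCI
#'
#' k-fold cross-validation; within each fold the SNP screen, LD pruning,
#' selection and weight fitting all use the training portion only, and the
#' held-out samples are scored with those frozen weights. By default SNP
#' selection is repeated per fold (the stricter choice); `reselect = FALSE`
#' re-fits weights only, on a fixed SNP set.
#'
#' @param me eigengene (or named numeric vector) for the full cohort.
#' @param geno [geno_matrix] for the full cohort.
#' @param selection list of selection settings: `method`, `alpha`,
#'   `r2_max`, `plateau_eps`, `min_group`.
#' @param k_folds number of folds (>= 2; `n >= 2 * k_folds`).
#' @param seed integer seed for the fold split.
#' @param reselect logical; repeat SNP selection inside each fold.
#' @param snps fixed SNP set used when `reselect = FALSE`.
#' @return list of class `pci_cv`: pooled out-of-fold Pearson `r`,
#'   `fold_r`, `failed_folds`, and the pooled out-of-fold scores.
#' @export
crossvalidate_pci <- function(me, geno, selection = list(), k_folds = 5,
                              seed = 1, reselect = TRUE, snps = NULL) {
  scores <- if (inherits(me, "eigengene")) me$scores else me
  stopifnot(inherits(geno, "geno_matrix"), k_folds >= 2)
  sel <- utils::modifyList(list(method = "fixed", alpha = 0.005,
                                r2_max = 0.2, plateau_eps = 0.005,
                                min_group = 5), selection)
  common <- intersect(names(scores), rownames(geno$dosage))
  n <- length(common)
  if (n < 2 * k_folds) stop2("need n >= 2 * k_folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  oof <- stats::setNames(rep(NA_real_, n), common)
  fold_r <- rep(NA_real_, k_folds)
  failed <- integer()
  for (f in seq_len(k_folds)) {
    tr <- common[fold != f]; te <- common[fold == f]
    g_tr <- geno_matrix(geno$dosage[tr, , drop = FALSE], geno$meta)
    res <- tryCatch({
      ids <- if (reselect || is.null(snps)) {
        scan <- coeqtl_scan(scores[tr], g_tr)
        select_snps(scan, g_tr, me = scores[tr], method = sel$method,
                    alpha = sel$alpha, r2_max = sel$r2_max,
                    plateau_eps = sel$plateau_eps,
                    min_group = sel$min_group)$snps
      } else snps
      fit <- fit_pci(scores[tr], g_tr, ids, min_group = sel$min_group)
      score_pci(fit, geno_matrix(geno$dosage[te, , drop = FALSE],
                                 geno$meta))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, f)
      log_note("cv_fold_failed", fold = f, reason = conditionMessage(res))
      next
    }
    oof[te] <- res[te]
    if (stats::sd(res[te]) > 0)
      fold_r[f] <- stats::cor(res[te], scores[te])
  }
  ok <- !is.na(oof)
  pooled_r <- if (sum(ok) > 2 && stats::sd(oof[ok]) > 0)
    stats::cor(oof[ok], scores[common][ok]) else NA_real_
  structure(list(r = pooled_r, fold_r = fold_r, failed_folds = failed,
                 oof_scores = oof, k_folds = k_folds,
                 selection = sel), class = "pci_cv")
}

#' @export
print.pci_cv <- function(x, ...) {
  cat(sprintf("<pci_cv> %d folds (%d failed), pooled out-of-fold r = %.3f\n",
              x$k_folds, length(x$failed_folds), x$r))
  invisible(x)
}

#' Replicate a fitted PCI in an independent cohort
#'
#' Recomputes the module eigengene on the module genes present in the
#' replication expression matrix (fresh PCA, sign re-oriented by the seed
#' gene or mean-member rule), scores the replication genotypes with the
#' frozen training weights, and reports the one-tailed (r > 0) Pearson
#' correlation — overall and within the high-quality stratum.
#'
#' @param model a fitted `pci_model` (weights are frozen).
#' @param expr_rep replication [expr_matrix].
#' @param geno_rep replication [geno_matrix] (must carry all model SNPs).
#' @param module_ids training module member gene ids.
#' @param seed_gene_id seed gene id for eigengene orientation.
#' @param min_overlap minimum fraction of module genes that must be present
#'   (default 0.5).
#' @param quality_threshold quality cut for the stratified report
#'   (default 6; stratum uses quality strictly greater).
#' @return list of class `pci_replication`: `r`, `p_one_tailed`, `n`,
#'   `n_probes_used`, and a `high_quality` stratum report.
#' @export
replicate_pci <- function(model, expr_rep, geno_rep, module_ids,
                          seed_gene_id = NULL, min_overlap = 0.5,
                          quality_threshold = 6) {
  stopifnot(inherits(model, "pci_model"), inherits(expr_rep, "expr_matrix"))
  present <- intersect(module_ids, gene_ids(expr_rep))
  if (length(present) < min_overlap * length(module_ids))
    stop2(sprintf("only %d of %d module genes present (< %.0f%% floor)",
                  length(present), length(module_ids), 100 * min_overlap))
  me_rep <- module_eigengene(expr_rep, present, seed_gene_id)
  pci <- score_pci(model, geno_rep)
  common <- intersect(names(me_rep$scores), names(pci))
  r <- stats::cor(pci[common], me_rep$scores[common])
  n <- length(common)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p1 <- stats::pt(tval, n - 2, lower.tail = FALSE)
  hq <- NULL
  if (!is.null(expr_rep$quality)) {
    keep <- names(expr_rep$quality)[expr_rep$quality > quality_threshold]
    keep <- intersect(keep, common)
    if (length(keep) >= 5) {
      r_hq <- stats::cor(pci[keep], me_rep$scores[keep])
      t_hq <- r_hq * sqrt((length(keep) - 2) / (1 - r_hq^2))
      hq <- list(r = r_hq, n = length(keep),
                 p_one_tailed = stats::pt(t_hq, length(keep) - 2,
                                          lower.tail = FALSE),
                 threshold = quality_threshold)
    }
  }
  structure(list(r = r, p_one_tailed = p1, n = n,
                 n_probes_used = length(present),
                 n_probes_module = length(module_ids),
                 explained_variance = me_rep$explained_variance,
                 high_quality = hq, scores = pci[common],
                 me = me_rep$scores[common]),
            class = "pci_replication")
}

#' @export
print.pci_replication <- function(x, ...) {
  cat(sprintf(paste0("<pci_replication> r = %.3f (one-tailed p = %.3g, ",
                     "n = %d, %d/%d probes)\n"),
              x$r, x$p_one_tailed, x$n, x$n_probes_used, x$n_probes_module))
  if (!is.null(x$high_quality))
    cat(sprintf("  quality > %g stratum: r = %.3f (n = %d, p = %.3g)\n",
                x$high_quality$threshold, x$high_quality$r,
                x$high_quality$n, x$high_quality$p_one_tailed))
  invisible(x)
}
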