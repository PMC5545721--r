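new_assoc_result <- function(test, estimate, stat, stat_name, p, sidedness,
                             n, df = NA_real_, covariates = character(),
                             correction = "none", q = NA_real_,
                             extra = list()) {
  structure(c(list(test = test, estimate = estimate, stat = stat,
                   stat_name = stat_name, p = p, sidedness = sidedness,
                   n = n, df = df, covariates = covariates,
                   correction = correction, q = q), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s: estimate = %.4g, %s = %.3f, p = %.3g (%s-sided), n = %d\n",
              x$test, x$estimate, x$stat_name, x$stat, x$p, x$sidedness,
              x$n))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(test = x$test, estimate = x$estimate, stat = x$stat,
             p = x$p, sidedness = x$sidedness, n = x$n, df = x$df,
             correction = x$correction, q = x$q,
             stringsAsFactors = FALSE)
}

sided_p <- function(tval, df, sidedness) {
  switch(sidedness,
         two = 2 * stats::pt(-abs(tval), df),
         greater = stats::pt(tval, df, lower.tail = FALSE),
         less = stats::pt(tval, df),
         stop2("sidedness must be 'two', 'greater' or 'less'"))
}

#' Linear association of a phenotype with the PCI
#'
#' OLS (default) or Huber M-estimation (robust linear model, tuning
#' constant 1.345, iterated to convergence 1e-8 or 50 iterations) of the
#' phenotype on intercept + PCI + covariates, with a t-test of requested
#' sidedness on the PCI coefficient.
#'
#' @param y numeric phenotype (e.g. ROI percent signal change).
#' @param pci numeric PCI scores aligned with `y`.
#' @param covars optional covariate data.frame (e.g. age, gender,
#'   handedness).
#' @param robust logical; use a Huber robust fit.
#' @param sidedness `"two"` (default), `"greater"` or `"less"`.
#' @return an `assoc_result`.
#' @export
linear_assoc <- function(y, pci, covars = NULL, robust = FALSE,
                         sidedness = "two") {
  stopifnot(length(y) == length(pci))
  dat <- data.frame(y = y, pci = pci)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    stopifnot(nrow(covars) == length(y))
    X <- covariate_design(covars)          # validates rank
    dat <- cbind(dat, as.data.frame(X[, -1, drop = FALSE]))
  }
  ok <- stats::complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  n <- nrow(dat)
  form <- stats::as.formula(paste("y ~", paste(setdiff(names(dat), "y"),
                                               collapse = " + ")))
  if (robust) {
    fit <- MASS::rlm(form, data = dat, psi = MASS::psi.huber, k = 1.345,
                     maxit = 50, acc = 1e-8)
    cf <- summary(fit)$coefficients
  } else {
    fit <- stats::lm(form, data = dat)
    cf <- summary(fit)$coefficients
  }
  df <- n - nrow(cf)
  est <- cf["pci", 1]; tval <- cf["pci", 1] / cf["pci", 2]
  new_assoc_result(if (robust) "robust_linear" else "linear",
                   est, tval, "t", sided_p(tval, df, sidedness),
                   sidedness, n, df,
                   covariates = if (is.null(covars)) character() else
                     names(covars))
}

#' Two-level repeated-measures LOAD x PCI interaction test
#'
#' Tests the interaction between a two-level within-subject factor (e.g.
#' working-memory LOAD, 1-back vs 2-back) and the PCI by regressing the
#' within-subject difference `y_load2 - y_load1` on intercept + PCI +
#' covariates. For a two-level within factor this difference regression is
#' exactly the repeated-measures ANCOVA interaction test (F = t^2).
#' Per-load post-hoc regressions are returned alongside; the family
#' threshold alpha = 0.025 (two measures, Bonferroni) is reported as
#' metadata, not enforced.
#'
#' @param y_load1,y_load2 phenotype under the two load levels, aligned per
#'   sample. Samples with a missing value in either are dropped with a
#'   logged count.
#' @param pci PCI scores.
#' @param covars optional covariates.
#' @return list of class `rm_interaction`: `interaction` (an
#'   `assoc_result` carrying F = t^2), `posthoc` (per-load
#'   `assoc_result`s), `alpha_family`, `n_dropped`.
#' @export
rm_interaction_test <- function(y_load1, y_load2, pci, covars = NULL) {
  stopifnot(length(y_load1) == length(y_load2),
            length(y_load1) == length(pci))
  ok <- !is.na(y_load1) & !is.na(y_load2)
  n_dropped <- sum(!ok)
  if (n_dropped) log_note("dropped_incomplete_pairs", count = n_dropped)
  d <- y_load2[ok] - y_load1[ok]
  cv <- if (is.null(covars)) NULL else
    as.data.frame(covars)[ok, , drop = FALSE]
  inter <- linear_assoc(d, pci[ok], cv, sidedness = "two")
  inter$test <- "load_x_pci_interaction"
  inter$F <- inter$stat^2
  posthoc <- list(
    load1 = linear_assoc(y_load1[ok], pci[ok], cv, sidedness = "two"),
    load2 = linear_assoc(y_load2[ok], pci[ok], cv, sidedness = "two"))
  posthoc$load1$test <- "posthoc_load1"
  posthoc$load2$test <- "posthoc_load2"
  structure(list(interaction = inter, posthoc = posthoc,
                 alpha_family = 0.025, n_dropped = n_dropped),
            class = "rm_interaction")
}

#' @export
print.rm_interaction <- function(x, ...) {
  cat(sprintf("<rm_interaction> F(1, %d) = %.3f, p = %.3g (family alpha = %.3f)\n",
              x$interaction$df, x$interaction$F, x$interaction$p,
              x$alpha_family))
  invisible(x)
}

#' Hypergeometric gene-set enrichment (upper tail)
#'
#' Probability of observing at least `module_hits` risk genes in a module
#' of `module_size` genes drawn from `background_size` genes of which
#' `background_hits` are risk genes:
#' P(X >= module_hits), X ~ Hypergeom(background_size, background_hits,
#' module_size). Exact log-space tail via [stats::phyper()]. The background
#' is a required explicit input.
#'
#' @param module_size number of genes in the module.
#' @param module_hits risk genes in the module.
#' @param background_size genes in the background universe.
#' @param background_hits risk genes in the background universe.
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(module_size, module_hits, background_size,
                                 background_hits) {
  stopifnot(is_count(module_size), is_count(module_hits),
            is_count(background_size), is_count(background_hits))
  if (module_hits > min(module_size, background_hits) ||
      background_size < module_size || background_hits > background_size)
    stop2("impossible enrichment counts")
  stats::phyper(module_hits - 1, background_hits,
                background_size - background_hits, module_size,
                lower.tail = FALSE)
}

#' Spearman rank correlation of improvement with the PCI
#'
#' Rank correlation with mid-ranks for ties; the p-value uses the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom, with the requested sidedness.
#'
#' @param improvement numeric clinical improvement scores.
#' @param pci numeric PCI scores.
#' @param sidedness `"two"`, `"greater"` or `"less"`.
#' @return an `assoc_result` with `estimate` = rho.
#' @export
spearman_assoc <- function(improvement, pci, sidedness = "two") {
  ok <- !is.na(improvement) & !is.na(pci)
  x <- improvement[ok]; y <- pci[ok]
  n <- length(x)
  if (n < 5) stop2("need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    if (sidedness == "two" || (sidedness == "greater" && rho > 0) ||
        (sidedness == "less" && rho < 0)) 0 else 1
  } else {
    sided_p(rho * sqrt((n - 2) / (1 - rho^2)), n - 2, sidedness)
  }
  new_assoc_result("spearman", rho, rho, "rho", p, sidedness, n,
                   df = n - 2)
}

#' ROC curve, AUC and Mann-Whitney p-value
#'
#' `AUC = (concordant + 0.5 * tied) / (n1 * n0)` over all case-control
#' pairs, computed via midranks; the curve gives TPR/FPR at every
#' threshold. The p-value is a one-tailed (AUC > 0.5) tie-corrected normal
#' approximation to the Mann-Whitney U test; for total n <= 12,
#' `exact = TRUE` enumerates the permutation distribution of U instead.
#'
#' @param score numeric predictor (e.g. PCI).
#' @param labels binary labels (0/1 or logical), both classes present.
#' @param exact logical; exact permutation p for n <= 12.
#' @return list of class `roc_result`: `auc`, `p`, `n1`, `n0`, and `curve`
#'   (data.frame of threshold, tpr, fpr).
#' @export
roc_auc <- function(score, labels, exact = FALSE) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  r <- rank(score)                           # midranks handle ties
  U <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  thr <- sort(unique(score), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(score[labels == 1] >= t),
                      numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(score[labels == 0] >= t),
                      numeric(1))))
  N <- n1 + n0
  if (exact && N <= 12) {
    combos <- utils::combn(N, n1)
    Us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(Us >= U)
  } else {
    ties <- table(score)
    sigma2 <- n1 * n0 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (sigma2 == 0) 1 else
      stats::pnorm((U - n1 * n0 / 2) / sqrt(sigma2), lower.tail = FALSE)
  }
  structure(list(auc = auc, p = p, n1 = n1, n0 = n0, curve = curve,
                 sidedness = "greater"), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (n1 = %d, n0 = %d), one-tailed p = %.3g\n",
              x$auc, x$n1, x$n0, x$p))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control:
#' `q_i = min_{j >= i} p_(j) * m / j`, mapped back to input order.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
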