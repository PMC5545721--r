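#' Network construction configuration
#'
#' @param signed logical; `FALSE` (default) builds an unsigned network
#'   (`|cor|^power`), `TRUE` a signed one (`((1+cor)/2)^power`).
#' @param power_grid candidate soft-thresholding powers.
#' @param scale_free_r2_min minimum scale-free model fit R^2 for picking a
#'   power (default 0.8).
#' @param cut_height static tree-cut height as a fraction of the maximum
#'   merge height, in (0, 1).
#' @param min_module_size smallest cluster kept as a module; smaller
#'   clusters are relabeled 0 (unassigned).
#' @return list of class `network_config`.
#' @export
network_config <- function(signed = FALSE, power_grid = 1:12,
                           scale_free_r2_min = 0.8, cut_height = 0.997,
                           min_module_size = 20) {
  stopifnot(all(power_grid >= 1), cut_height > 0, cut_height < 1,
            is_count(min_module_size))
  structure(list(signed = signed, power_grid = power_grid,
                 scale_free_r2_min = scale_free_r2_min,
                 cut_height = cut_height,
                 min_module_size = min_module_size),
            class = "network_config")
}

gene_cor <- function(expr) {
  v <- apply(expr$values, 1, stats::var)
  if (any(v == 0))
    stop2("zero-variance gene(s): ",
          paste(utils::head(gene_ids(expr)[v == 0], 5), collapse = ", "))
  stats::cor(t(expr$values))
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^power`; signed:
#' `a_ij = ((1 + cor)/2)^power`. The diagonal is set to 0.
#'
#' @param expr an [expr_matrix].
#' @param power soft-thresholding power (>= 1).
#' @param signed logical network variant flag.
#' @return symmetric gene x gene adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency <- function(expr, power, signed = FALSE) {
  stopifnot(power >= 1)
  r <- if (inherits(expr, "expr_matrix")) gene_cor(expr) else as.matrix(expr)
  a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
  diag(a) <- 0
  a
}

# Scale-free topology fit: R^2 of log10 p(k) on log10 k over >= 10
# connectivity bins, zeroed when the slope is non-negative.
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2 ||
      diff(range(k)) < 1e-8 * max(1, max(k)))
    return(list(r2 = 0, slope = 0))
  brk <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  cent <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(freq[ok]) ~ log10(cent[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = if (slope < 0) r2 else 0, slope = slope)
}

#' Choose a soft-thresholding power by the scale-free criterion
#'
#' Returns the smallest power in the grid whose scale-free fit R^2 reaches
#' `scale_free_r2_min`; if none does, the power maximizing R^2 is returned
#' with a logged warning.
#'
#' @param expr an [expr_matrix] with at least 20 genes.
#' @param config a [network_config()].
#' @return list with `power`, `r2` at that power, and the full `trace`
#'   (power, r2, slope per grid element).
#' @export
select_soft_power <- function(expr, config = network_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (nrow(expr$values) < 20) stop2("need at least 20 genes")
  r <- gene_cor(expr)
  trace <- data.frame(power = config$power_grid, r2 = NA_real_,
                      slope = NA_real_)
  for (i in seq_along(config$power_grid)) {
    a <- if (config$signed) ((1 + r) / 2)^config$power_grid[i] else
      abs(r)^config$power_grid[i]
    diag(a) <- 0
    sf <- scale_free_fit(rowSums(a))
    trace$r2[i] <- sf$r2
    trace$slope[i] <- sf$slope
  }
  hit <- which(trace$r2 >= config$scale_free_r2_min)
  if (length(hit)) {
    i <- hit[1]
  } else {
    i <- which.max(trace$r2)
    log_note("no_power_reaches_r2_min", best_power = trace$power[i],
             best_r2 = trace$r2[i])
  }
  list(power = trace$power[i], r2 = trace$r2[i], trace = trace)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, the sum excluding u = i, j; `TOM_ii = 1`.
#'
#' @param adj symmetric adjacency matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @return symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  if (!isSymmetric(unname(adj), tol = 1e-10) || any(diag(adj) != 0) ||
      any(adj < 0 | adj > 1))
    stop2("adjacency must be symmetric with zero diagonal and entries in [0,1]")
  k <- rowSums(adj)
  shared <- adj %*% adj                      # u = i, j terms vanish (diag 0)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (shared + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Detect modules by hierarchical clustering of topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at `cut_height` times the maximum merge height. Clusters
#' smaller than `min_module_size` are relabeled 0 (unassigned). Remaining
#' modules are labeled 1, 2, ... by decreasing size, ties broken by the
#' smallest member index.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param config a [network_config()].
#' @return list of class `module_partition` with `labels` (named integer
#'   vector) and `sizes` (table of module sizes).
#' @export
detect_modules <- function(tom, config = network_config()) {
  tom <- as.matrix(tom)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h_cut <- config$cut_height * max(hc$height)
  cl <- stats::cutree(hc, h = h_cut)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < config$min_module_size])
  cl[cl %in% small] <- 0L
  kept <- setdiff(unique(cl), 0L)
  if (length(kept)) {
    first_idx <- vapply(kept, function(l) min(which(cl == l)), numeric(1))
    sz <- vapply(kept, function(l) sum(cl == l), numeric(1))
    ord <- kept[order(-sz, first_idx)]
    new <- cl
    for (i in seq_along(ord)) new[cl == ord[i]] <- i
    cl <- new
  }
  labels <- stats::setNames(as.integer(cl), rownames(tom))
  structure(list(labels = labels,
                 sizes = table(labels[labels != 0]),
                 cut_height_used = h_cut),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d genes, %d modules (+%d unassigned)\n",
              length(x$labels), length(x$sizes), sum(x$labels == 0)))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Extract the module containing a seed gene
#'
#' @param partition a `module_partition` from [detect_modules()].
#' @param seed_gene_id seed gene identifier.
#' @return list with `label` and `members` (gene ids of the seed module).
#' @export
seed_module <- function(partition, seed_gene_id) {
  stopifnot(inherits(partition, "module_partition"))
  if (!seed_gene_id %in% names(partition$labels))
    stop2("seed gene '", seed_gene_id, "' absent from partition")
  lab <- partition$labels[[seed_gene_id]]
  if (lab == 0L)
    stop2("seed gene '", seed_gene_id,
          "' is unassigned (grey module): no seed module exists")
  list(label = lab,
       members = names(partition$labels)[partition$labels == lab])
}

#' Module eigengene (first principal component of a module)
#'
#' Computes the first principal component of the gene-standardized member
#' submatrix. Scores are scaled to unit variance and sign-oriented so the
#' eigengene correlates positively with the seed gene (or, if the seed gene
#' is not a member, with the average member gene).
#'
#' @param expr an [expr_matrix].
#' @param member_ids module member gene ids (>= 2 with nonzero variance).
#' @param seed_gene_id optional seed gene id used for sign orientation.
#' @return list of class `eigengene`: `scores` (named, unit variance),
#'   `explained_variance` (first-eigenvalue fraction), `sign` (orientation
#'   applied), `members`.
#' @export
module_eigengene <- function(expr, member_ids, seed_gene_id = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  member_ids <- intersect(member_ids, gene_ids(expr))
  sub <- expr$values[member_ids, , drop = FALSE]
  v <- apply(sub, 1, stats::var)
  if (any(v == 0)) {
    log_note("zero_variance_members_dropped", count = sum(v == 0))
    sub <- sub[v > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2) stop2("module eigengene needs >= 2 variable member genes")
  z <- t(scale(t(sub)))                     # standardize each gene
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  ev <- pc$sdev[1]^2 / sum(pc$sdev^2)
  orient <- if (!is.null(seed_gene_id) && seed_gene_id %in% rownames(sub)) {
    sign(stats::cor(scores, expr$values[seed_gene_id, ]))
  } else {
    sign(mean(stats::cor(scores, t(z))))
  }
  if (orient == 0) orient <- 1
  scores <- orient * scores / stats::sd(scores)
  structure(list(scores = stats::setNames(scores, sample_ids(expr)),
                 explained_variance = ev, sign = orient,
                 members = rownames(sub)),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("<eigengene> %d members, %d samples, PC1 explains %.1f%%\n",
              length(x$members), length(x$scores),
              100 * x$explained_variance))
  invisible(x)
}

#' Intramodular connectivity
#'
#' `kIN_g = sum_{h in module, h != g} a_gh`, ranked descending with ties
#' broken by gene id.
#'
#' @param adj adjacency matrix.
#' @param member_ids module member gene ids (must be adjacency rows).
#' @return data.frame with columns `gene`, `kIN`, `rank`, ordered by rank.
#' @export
intramodular_connectivity <- function(adj, member_ids) {
  if (!all(member_ids %in% rownames(adj)))
    stop2("member genes missing from adjacency: ",
          paste(setdiff(member_ids, rownames(adj)), collapse = ", "))
  sub <- adj[member_ids, member_ids, drop = FALSE]
  kin <- rowSums(sub)                       # diagonal is zero
  ord <- order(-kin, member_ids)
  data.frame(gene = member_ids[ord], kIN = kin[ord],
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}
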