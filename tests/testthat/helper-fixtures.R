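# Shared fixtures, cached so the expensive discovery chain runs once.

.cache <- new.env(parent = emptyenv())

# small, fast cohort for PCI-focused tests: full module, thin background
small_pci_config <- function(seed = 1, ...) {
  default_cohort_config("discovery", seed = seed,
                        n_background_genes = 15, ...)
}

# one default discovery cohort with its residualized expression and
# truth-module eigengene (no network detection)
get_discovery_chain <- function() {
  if (is.null(.cache$chain)) {
    co <- simulate_cohort(small_pci_config(seed = 1))
    prep <- residualize(co$expression, co$covariates[c("age", "sex")])
    me <- module_eigengene(prep, co$truth$module_gene_ids, "DRD2")
    .cache$chain <- list(cohort = co, prep = prep, me = me)
  }
  .cache$chain
}

# one full network run on the default cohort (background genes included)
get_network_chain <- function() {
  if (is.null(.cache$network)) {
    co <- simulate_cohort(default_cohort_config("discovery", seed = 1))
    prep <- residualize(co$expression, co$covariates[c("age", "sex")])
    nc <- network_config()
    pw <- select_soft_power(prep, nc)
    adj <- adjacency(prep, pw$power)
    tom <- topological_overlap(adj)
    part <- detect_modules(tom, nc)
    .cache$network <- list(cohort = co, prep = prep, power = pw,
                           adj = adj, tom = tom, partition = part)
  }
  .cache$network
}

# expression matrix with exactly the requested gene-gene correlations is
# hard to construct; instead build one from a latent factor
make_block_expr <- function(n = 200, block_sizes = c(50, 50), r_within = 0.7,
                            seed = 99) {
  set.seed(seed)
  lam <- sqrt(r_within)
  mats <- lapply(seq_along(block_sizes), function(b) {
    L <- rnorm(n)
    t(vapply(seq_len(block_sizes[b]),
             function(i) lam * L + sqrt(1 - lam^2) * rnorm(n),
             numeric(n)))
  })
  X <- do.call(rbind, mats)
  rownames(X) <- unlist(lapply(seq_along(block_sizes), function(b)
    sprintf("B%d_%02d", b, seq_len(block_sizes[b]))))
  colnames(X) <- sprintf("S%03d", seq_len(n))
  expr_matrix(X)
}

# independent brute-force TOM oracle (triple loop)
tom_oracle <- function(a) {
  g <- nrow(a)
  k <- rowSums(a)
  out <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# hypergeometric upper tail by complete enumeration
hyper_oracle <- function(n_module, k_module, N, K) {
  js <- max(k_module, 0):min(n_module, K)
  sum(choose(K, js) * choose(N - K, n_module - js)) / choose(N, n_module)
}

# step-up BH arithmetic, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# greedy LD pruning reference implementation (naive, quadratic)
ld_prune_oracle <- function(dosage, p, r2_max) {
  ord <- names(sort(p))
  ord <- ord[order(p[ord], ord)]
  kept <- character()
  for (s in ord) {
    ok <- TRUE
    for (t in kept) {
      if (cor(dosage[, s], dosage[, t])^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  kept
}
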