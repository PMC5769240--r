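# Shared test fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately avoid the package's own code paths.

# Build a bipartite network directly from parallel edge vectors, bypassing
# thresholds (p values are set far below any cutoff).
net_from_edges <- function(snps, genes, isolated = "none") {
  eq <- data.frame(rsID = snps, probe_id = paste0(genes, "_p"),
                   gene_symbol = genes, p = 1e-12, q = 1e-12, mode = "cis",
                   stringsAsFactors = FALSE)
  gwas <- data.frame(rsID = unique(snps), chrom = "1",
                     pos = seq_along(unique(snps)), p = 0.5,
                     stringsAsFactors = FALSE)
  build_network(eq, gwas, isolated = isolated)
}

# Dense double-sum evaluation of Barber modularity: loops over every
# (SNP, gene) cell of the incidence matrix.
dense_barber_q <- function(net, assign) {
  snps <- net$snp_nodes; genes <- net$gene_nodes
  m <- nrow(net$edges)
  A <- matrix(0, length(snps), length(genes),
              dimnames = list(snps, genes))
  for (r in seq_len(m)) A[net$edges$rsID[r], net$edges$gene_symbol[r]] <- 1
  k <- rowSums(A); d <- colSums(A)
  q <- 0
  for (i in seq_along(snps)) {
    for (j in seq_along(genes)) {
      if (assign[snps[i]] == assign[genes[j]])
        q <- q + A[i, j] - k[i] * d[j] / m
    }
  }
  as.numeric(q / m)
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  res
}

# Exhaustive maximum of Barber modularity over every partition of the nodes.
exhaustive_best_q <- function(net) {
  nodes <- c(net$snp_nodes, net$gene_nodes)
  best <- -Inf
  for (part in all_partitions(length(nodes))) {
    q <- barber_modularity(net, stats::setNames(part, nodes))
    if (q > best) best <- q
  }
  best
}

# Random small bipartite network (no self-structure constraints beyond
# non-emptiness); at most max_nodes nodes and max_edges edges.
random_small_net <- function(max_nodes = 8, max_edges = 12) {
  repeat {
    S <- sample(2:(max_nodes - 2), 1)
    G <- sample(2:min(max_nodes - S, max_nodes - 2), 1)
    all_pairs <- expand.grid(s = seq_len(S), g = seq_len(G))
    ne <- sample(seq_len(min(nrow(all_pairs), max_edges)), 1)
    pick <- all_pairs[sample(nrow(all_pairs), ne), ]
    net <- net_from_edges(paste0("s", pick$s), paste0("g", pick$g))
    if (nrow(net$edges) >= 1) return(net)
  }
}

# A tiny cohort plan used across module tests.
tiny_plan <- function(...) {
  default_plan(n_cases = 40, n_controls = 20, n_snps = 60, n_genes = 12,
               n_cpgs = 24, n_cis_effects = 4, n_trans_effects = 1,
               n_disease_causal = 2, n_dm_effects = 4, n_gwas = 600,
               ld_block_size = 5, ...)
}

# Closed-form simple linear regression (no covariates beyond intercept),
# independent of the package's scan engine.
simple_ols_oracle <- function(g, y) {
  n <- length(g)
  gc <- g - mean(g); yc <- y - mean(y)
  beta <- sum(gc * yc) / sum(gc^2)
  sse <- sum((yc - beta * gc)^2)
  df <- n - 2
  se <- sqrt(sse / df / sum(gc^2))
  t <- beta / se
  list(beta = beta, se = se, t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Normal-equations OLS of y on [1, g, C] with ordinary t on the g column.
normal_eq_oracle <- function(g, y, C = NULL) {
  X <- cbind(1, g, C)
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  res <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  t <- bhat[2] / se
  list(beta = bhat[2], se = se, t = t,
       p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  # contingency-based ARI fallback
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  exp_ij <- si * sj / sn
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}
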