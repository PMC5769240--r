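# Internal indexed view of a bip_network: integer edge endpoints and degrees.
.net_index <- function(net) {
  snps <- net$snp_nodes; genes <- net$gene_nodes
  if (!length(snps) || !nrow(net$edges)) .stopf("network is empty")
  ei <- match(net$edges$rsID, snps)
  ej <- match(net$edges$gene_symbol, genes)
  list(snps = snps, genes = genes, ei = ei, ej = ej,
       S = length(snps), G = length(genes), m = nrow(net$edges),
       k_snp = tabulate(ei, length(snps)),
       d_gene = tabulate(ej, length(genes)))
}

.check_assignment <- function(idx, assignment) {
  missing <- setdiff(c(idx$snps, idx$genes), names(assignment))
  if (length(missing))
    .stopf("assignment missing node(s): %s",
           paste(head(missing, 5), collapse = ", "))
  cs <- as.integer(factor(assignment))  # tolerate arbitrary label values
  names(cs) <- names(assignment)
  cs
}

#' Barber bipartite modularity
#'
#' Modularity for a two-mode network:
#' \deqn{Q = \frac{1}{m} \sum_{i \in SNPs}\sum_{j \in genes}
#'   \left(A_{ij} - \frac{k_i d_j}{m}\right)\,\delta(c_i, c_j)}
#' with m the edge count, k and d the side degrees. Computed sparsely as the
#' fraction of within-community edges minus the per-community degree products
#' over m squared. The all-in-one partition scores exactly 0 on every
#' network.
#'
#' @param net A \code{bip_network}.
#' @param assignment Named vector mapping every node (rsID and gene symbol)
#'   to a community label.
#' @return The modularity Q.
#' @export
barber_modularity <- function(net, assignment) {
  idx <- .net_index(net)
  cs <- .check_assignment(idx, assignment)
  c_snp <- cs[idx$snps]; c_gene <- cs[idx$genes]
  k <- max(cs)
  within <- sum(c_snp[idx$ei] == c_gene[idx$ej]) / idx$m
  K <- vapply(seq_len(k), function(s) sum(idx$k_snp[c_snp == s]), 0)
  D <- vapply(seq_len(k), function(s) sum(idx$d_gene[c_gene == s]), 0)
  within - sum(K * D) / idx$m^2
}

#' Initialize a community assignment from the gene-side projection
#'
#' Builds the gene one-mode projection (genes linked when they share at least
#' one eSNP, weighted by the shared count), runs seeded label propagation on
#' it, and assigns each eSNP to the majority community among its gene
#' neighbours (ties broken toward the lowest community id). Disconnected
#' components necessarily receive distinct labels.
#'
#' @param net A \code{bip_network}.
#' @param seed Optional integer seed (label propagation is stochastic).
#' @return Named integer vector of community ids (1..k) covering all nodes.
#' @export
initialize_assignment <- function(net, seed = NULL) {
  idx <- .net_index(net)
  A <- Matrix::sparseMatrix(i = idx$ei, j = idx$ej, x = 1,
                            dims = c(idx$S, idx$G))
  W <- Matrix::crossprod(A)          # gene x gene shared-eSNP counts
  Matrix::diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  .set_seed_if(seed)
  memb <- igraph::membership(igraph::cluster_label_prop(g))
  c_gene <- as.integer(memb)
  c_snp <- vapply(seq_len(idx$S), function(i) {
    nb <- c_gene[idx$ej[idx$ei == i]]
    tab <- table(nb)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  }, 0L)
  cs <- c(c_snp, c_gene)
  cs <- as.integer(factor(cs))
  setNames(cs, c(idx$snps, idx$genes))
}

#' Fit communities by BRIM (bipartite recursively induced modules)
#'
#' Alternating maximization of Barber modularity: given gene labels, each
#' eSNP moves to the community maximizing its modularity gain (en bloc, since
#' SNP terms are independent given the gene side); then genes move given SNP
#' labels. Sweeps run in sorted node order with gain ties broken toward the
#' lowest community id, so the fit is deterministic given its
#' initialization. Q is non-decreasing across iterations; empty communities
#' are dropped and ids recompacted after each sweep. The community count can
#' never exceed the number of labels in the initialization, so a label-rich
#' initialization (or \code{extra_singletons}) is needed to discover many
#' communities.
#'
#' @param net A \code{bip_network}.
#' @param init Optional named assignment to start from; defaults to
#'   \code{\link{initialize_assignment}}.
#' @param max_iter Maximum alternation sweeps (default 100).
#' @param tol Minimum Q improvement to continue (default 1e-10).
#' @param extra_singletons Number of highest-degree nodes split into fresh
#'   singleton labels before fitting, letting BRIM exceed the
#'   initialization's label count.
#' @param seed Optional seed, used only when \code{init} is NULL.
#' @return A \code{community_assignment}: list with \code{membership} (named
#'   vector, ids contiguous from 1), \code{side}, \code{Q},
#'   \code{n_communities}, \code{trace} (Q per iteration), \code{converged}.
#' @export
brim_fit <- function(net, init = NULL, max_iter = 100, tol = 1e-10,
                     extra_singletons = 0, seed = NULL) {
  idx <- .net_index(net)
  if (is.null(init)) init <- initialize_assignment(net, seed = seed)
  cs <- .check_assignment(idx, init)
  labels <- unname(cs[c(idx$snps, idx$genes)])
  if (extra_singletons > 0) {
    deg <- c(idx$k_snp, idx$d_gene)
    pick <- order(-deg)[seq_len(min(extra_singletons, length(deg)))]
    labels[pick] <- max(labels) + seq_along(pick)
  }
  m <- idx$m
  # sparse incidence for en-bloc sweeps
  A <- Matrix::sparseMatrix(i = idx$ei, j = idx$ej, x = 1,
                            dims = c(idx$S, idx$G))
  compact <- function(l) as.integer(factor(l))
  labels <- compact(labels)
  q_of <- function(l) {
    cS <- l[seq_len(idx$S)]; cG <- l[idx$S + seq_len(idx$G)]
    k <- max(l)
    within <- sum(cS[idx$ei] == cG[idx$ej]) / m
    K <- vapply(seq_len(k), function(s) sum(idx$k_snp[cS == s]), 0)
    D <- vapply(seq_len(k), function(s) sum(idx$d_gene[cG == s]), 0)
    within - sum(K * D) / m^2
  }
  q_prev <- q_of(labels)
  trace <- q_prev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    k <- max(labels)
    cG <- labels[idx$S + seq_len(idx$G)]
    # SNP sweep: counts of edges into each community, minus degree penalty
    Ig <- Matrix::sparseMatrix(i = seq_len(idx$G), j = cG, x = 1,
                               dims = c(idx$G, k))
    cnt <- as.matrix(A %*% Ig)                    # S x k
    D <- colSums(idx$d_gene * as.matrix(Ig))
    gain <- cnt / m - outer(idx$k_snp, D) / m^2
    labels[seq_len(idx$S)] <- max.col(gain, ties.method = "first")
    # gene sweep given new SNP labels
    cS <- labels[seq_len(idx$S)]
    Is <- Matrix::sparseMatrix(i = seq_len(idx$S), j = cS, x = 1,
                               dims = c(idx$S, k))
    cnt <- as.matrix(Matrix::crossprod(A, Is))    # G x k
    K <- colSums(idx$k_snp * as.matrix(Is))
    gain <- cnt / m - outer(idx$d_gene, K) / m^2
    labels[idx$S + seq_len(idx$G)] <- max.col(gain, ties.method = "first")
    labels <- compact(labels)
    q_now <- q_of(labels)
    trace <- c(trace, q_now)
    if (q_now - q_prev < tol) { converged <- TRUE; q_prev <- max(q_prev, q_now); break }
    q_prev <- q_now
  }
  if (!converged)
    warning("BRIM did not converge within max_iter; returning best-so-far",
            call. = FALSE)
  membership <- setNames(labels, c(idx$snps, idx$genes))
  structure(list(
    membership = membership,
    side = setNames(c(rep("snp", idx$S), rep("gene", idx$G)),
                    c(idx$snps, idx$genes)),
    Q = q_of(labels),
    n_communities = max(labels),
    trace = trace,
    converged = converged), class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf(
    "Community assignment: %d communities over %d nodes, Q = %.4f (%s)\n",
    x$n_communities, length(x$membership), x$Q,
    if (x$converged) sprintf("converged in %d sweeps", length(x$trace) - 1L)
    else "not converged"))
  invisible(x)
}

#' Locate the communities containing seed genes
#'
#' For each seed gene present in the network, reports its community with full
#' SNP/gene rosters and, when a GWAS summary is supplied, the count of member
#' eSNPs below the sub-threshold cutoff. Absent genes are listed under
#' \code{not_found}, not raised as errors; multiple seed genes falling in one
#' community yield a single community record listing all of them.
#'
#' @param assign A \code{community_assignment}.
#' @param seed_genes Character vector of gene symbols of interest.
#' @param gwas Optional GWAS summary used to count sub-threshold member SNPs.
#' @param subthreshold GWAS p cutoff for that count (default 1e-4).
#' @return List with \code{summary} (community_id, seed_genes, n_snps,
#'   n_genes, n_subthreshold_snps), \code{communities} (id -> list with snp
#'   and gene rosters), \code{not_found}.
#' @export
locate_seed_communities <- function(assign, seed_genes, gwas = NULL,
                                    subthreshold = 1e-4) {
  genes_in <- names(assign$membership)[assign$side == "gene"]
  found <- intersect(seed_genes, genes_in)
  not_found <- setdiff(seed_genes, genes_in)
  if (!length(found))
    return(list(summary = data.frame(), communities = list(),
                not_found = not_found))
  ids <- sort(unique(assign$membership[found]))
  comms <- lapply(ids, function(cid) {
    members <- names(assign$membership)[assign$membership == cid]
    snps <- members[assign$side[members] == "snp"]
    genes <- members[assign$side[members] == "gene"]
    n_sub <- if (!is.null(gwas))
      sum(gwas$p[match(intersect(snps, gwas$rsID), gwas$rsID)] < subthreshold)
    else NA_integer_
    list(community_id = cid, seed_genes = intersect(found, genes),
         snps = snps, genes = genes, n_subthreshold_snps = n_sub)
  })
  names(comms) <- as.character(ids)
  summary <- data.frame(
    community_id = ids,
    seed_genes = vapply(comms, function(x)
      paste(x$seed_genes, collapse = ","), ""),
    n_snps = vapply(comms, function(x) length(x$snps), 0L),
    n_genes = vapply(comms, function(x) length(x$genes), 0L),
    n_subthreshold_snps = vapply(comms, function(x)
      as.integer(x$n_subthreshold_snps), 0L),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, communities = comms, not_found = not_found)
}
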