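#' Build the filtered bipartite eSNP-eGene network
#'
#' Starts from a thresholded eQTL table (cis edges at p < \code{cis_p}, trans
#' at p < \code{trans_p}), drops eSNPs absent from the GWAS summary, collapses
#' probes to gene symbols (an edge exists when any probe of the gene
#' qualifies; supporting probe counts are kept on the edge), and removes
#' isolated SNP-gene pairs - edges whose two endpoints both have degree 1 -
#' iterating until a fixed point, since such pairs create no additional
#' connections. Edges are unweighted. An empty result is returned with a
#' reason code in provenance rather than an error.
#'
#' @param eqtl An \code{eqtl_table} (needs \code{rsID}, \code{gene_symbol},
#'   \code{p}, \code{mode}).
#' @param gwas GWAS summary data frame (\code{rsID}); only eSNPs represented
#'   here enter the network.
#' @param cis_p,trans_p Edge inclusion thresholds (defaults 1e-3, 1e-6).
#' @param isolated "pair" (default) removes edges whose two endpoints both
#'   have degree 1; "leaf" removes any edge with a degree-1 endpoint
#'   (iteratively); "none" keeps everything.
#' @return A \code{bip_network}: list with \code{edges} (rsID, gene_symbol,
#'   n_probes), \code{snp_nodes}, \code{gene_nodes}, \code{provenance}.
#' @export
build_network <- function(eqtl, gwas, cis_p = 1e-3, trans_p = 1e-6,
                          isolated = c("pair", "leaf", "none")) {
  isolated <- match.arg(isolated)
  keep <- (eqtl$mode == "cis" & eqtl$p < cis_p) |
    (eqtl$mode == "trans" & eqtl$p < trans_p)
  rec <- eqtl[keep, , drop = FALSE]
  n_thresholded <- nrow(rec)
  rec <- rec[rec$rsID %in% gwas$rsID, , drop = FALSE]
  n_in_gwas <- nrow(rec)
  edges <- if (nrow(rec)) {
    agg <- rowsum(rep(1L, nrow(rec)),
                  paste(rec$rsID, rec$gene_symbol, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    data.frame(rsID = vapply(key, `[`, "", 1),
               gene_symbol = vapply(key, `[`, "", 2),
               n_probes = as.integer(agg[, 1]), stringsAsFactors = FALSE)
  } else {
    data.frame(rsID = character(), gene_symbol = character(),
               n_probes = integer(), stringsAsFactors = FALSE)
  }
  n_collapsed <- nrow(edges)
  n_isolated_removed <- 0L
  repeat {
    if (!nrow(edges)) break
    ds <- table(edges$rsID); dg <- table(edges$gene_symbol)
    drop <- switch(isolated,
      none = logical(nrow(edges)),
      pair = ds[edges$rsID] == 1 & dg[edges$gene_symbol] == 1,
      leaf = ds[edges$rsID] == 1 | dg[edges$gene_symbol] == 1)
    if (!any(drop)) break
    n_isolated_removed <- n_isolated_removed + sum(drop)
    edges <- edges[!drop, , drop = FALSE]
    if (isolated == "pair") break  # pair removal cannot create new pairs
  }
  rownames(edges) <- NULL
  edges <- edges[order(edges$rsID, edges$gene_symbol), , drop = FALSE]
  rownames(edges) <- NULL
  reason <- if (nrow(edges)) NA_character_
    else if (n_thresholded == 0) "no_edges_pass_thresholds"
    else if (n_in_gwas == 0) "no_esnps_in_gwas"
    else "all_edges_isolated_pairs"
  structure(list(
    edges = edges,
    snp_nodes = sort(unique(edges$rsID)),
    gene_nodes = sort(unique(edges$gene_symbol)),
    provenance = list(cis_p = cis_p, trans_p = trans_p,
                      isolated_rule = isolated,
                      n_records_thresholded = n_thresholded,
                      n_records_in_gwas = n_in_gwas,
                      n_edges_collapsed = n_collapsed,
                      n_isolated_edges_removed = n_isolated_removed,
                      empty_reason = reason)),
    class = "bip_network")
}

#' @export
print.bip_network <- function(x, ...) {
  cat(sprintf("Bipartite eQTL network: %d eSNPs, %d eGenes, %d edges\n",
              length(x$snp_nodes), length(x$gene_nodes), nrow(x$edges)))
  if (!nrow(x$edges) && !is.na(x$provenance$empty_reason))
    cat("  empty:", x$provenance$empty_reason, "\n")
  invisible(x)
}

#' Degree distribution and hub concentration of a bipartite network
#'
#' Per-side degree tables plus a heavy-tail summary: the fraction of edges
#' incident to the top 1% of nodes by degree (hub concentration) and a
#' degree histogram per side suitable for log-log plotting.
#'
#' @param net A non-empty \code{bip_network}.
#' @return List with \code{snp_degrees}, \code{gene_degrees} (node, degree),
#'   \code{hub_fraction}, \code{hub_nodes}, and \code{histogram}
#'   (side, degree, count).
#' @export
degree_distribution <- function(net) {
  if (!nrow(net$edges)) .stopf("network is empty")
  ds <- table(net$edges$rsID); dg <- table(net$edges$gene_symbol)
  snp_deg <- data.frame(node = names(ds), degree = as.integer(ds),
                        stringsAsFactors = FALSE)
  gene_deg <- data.frame(node = names(dg), degree = as.integer(dg),
                         stringsAsFactors = FALSE)
  all_deg <- rbind(snp_deg, gene_deg)
  n_top <- max(1L, ceiling(0.01 * nrow(all_deg)))
  top <- all_deg$node[order(-all_deg$degree)][seq_len(n_top)]
  hub_frac <- mean(net$edges$rsID %in% top |
                     net$edges$gene_symbol %in% top)
  hist <- rbind(
    data.frame(side = "snp", degree = as.integer(names(table(snp_deg$degree))),
               count = as.integer(table(snp_deg$degree))),
    data.frame(side = "gene",
               degree = as.integer(names(table(gene_deg$degree))),
               count = as.integer(table(gene_deg$degree))))
  list(snp_degrees = snp_deg, gene_degrees = gene_deg,
       hub_fraction = hub_frac, hub_nodes = top, histogram = hist)
}

#' Write a bipartite network to disk
#'
#' Edge-list TSV (rsID, gene_symbol, n_probes) or GraphML via igraph, with
#' a \code{type} vertex attribute marking the gene side.
#'
#' @param net A \code{bip_network}.
#' @param path Output file path.
#' @param format "tsv" (default) or "graphml".
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- .as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("rsID", "gene_symbol")], directed = FALSE,
    vertices = data.frame(
      name = c(net$snp_nodes, net$gene_nodes),
      type = c(rep(FALSE, length(net$snp_nodes)),
               rep(TRUE, length(net$gene_nodes)))))
  g
}
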