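#' Two-sided p-value to non-negative z-score
#'
#' Inverse-normal transform of a two-sided p-value from a summary table whose
#' effect signs are unavailable: z = qnorm(1 - p/2), evaluated in log space so
#' that extreme p-values (e.g. 1e-300) map to finite z without underflow.
#' p = 1 maps to z = 0.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Non-negative z-scores.
#' @export
zscore_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) .stopf("p-values must lie in (0, 1]")
  qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

#' Wakefield-style approximate log10 Bayes factor
#'
#' Approximate Bayes factor for association at one SNP given its GWAS z-score:
#' \deqn{LBF = \log_{10}\left[\sqrt{V/(V+W)}\,
#'   \exp\left(\frac{z^2 W}{2(V+W)}\right)\right]}
#' with V the (normalized) sampling variance of the estimate and W the prior
#' variance of the effect. Positive for well-supported z, negative near z = 0,
#' so eSNPs without GWAS support penalize a gene's summed score - the
#' signature-matching behaviour the ensemble analysis relies on. W = 0 (a
#' point-null prior) gives LBF = 0 for any z.
#'
#' @param z Z-score(s).
#' @param V Sampling variance scale (> 0, default 1).
#' @param W Prior effect variance (>= 0, default 0.21).
#' @return log10 Bayes factor(s).
#' @examples
#' wakefield_lbf(0, W = 0.1)   # 0.5 * log10(1/1.1)
#' @export
wakefield_lbf <- function(z, V = 1, W = 0.21) {
  if (V <= 0) .stopf("V must be > 0")
  if (W < 0) .stopf("W must be >= 0")
  (0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))) / log(10)
}

#' Scoring configuration for LBF gene scores
#'
#' @param cis_p,trans_p eQTL p-value thresholds qualifying an eSNP
#'   contribution (defaults 1e-3 and 1e-6).
#' @param W,V Prior and sampling variance of the Wakefield kernel.
#' @param pruning_window_bp Distance window for greedy eSNP pruning (default
#'   1 Mb); set \code{prune = FALSE} to keep all qualifying eSNPs.
#' @param prune Whether to prune eSNPs by distance.
#' @return List of class \code{score_config}.
#' @export
score_config <- function(cis_p = 1e-3, trans_p = 1e-6, W = 0.21, V = 1,
                         pruning_window_bp = 1e6, prune = TRUE) {
  if (cis_p <= 0 || cis_p >= 1 || trans_p <= 0 || trans_p >= 1)
    .stopf("thresholds must lie in (0, 1)")
  if (W < 0 || V <= 0) .stopf("need W >= 0 and V > 0")
  structure(list(cis_p = cis_p, trans_p = trans_p, W = W, V = V,
                 pruning_window_bp = pruning_window_bp, prune = prune),
            class = "score_config")
}

#' Greedy distance-based eSNP pruning
#'
#' Sorts records by eQTL p-value (ties by rsID) and keeps a record iff no
#' already-kept record lies on the same chromosome within
#' \code{window_bp} (inclusive). A deterministic stand-in for LD-aware
#' pruning when no LD matrix is available.
#'
#' @param esnps Data frame with \code{rsID}, \code{chrom}, \code{pos},
#'   \code{p}.
#' @param window_bp Exclusion distance in base pairs.
#' @return The kept subset, in the sorted order.
#' @export
prune_esnps <- function(esnps, window_bp = 1e6) {
  if (!nrow(esnps)) return(esnps)
  ord <- order(esnps$p, esnps$rsID)
  esnps <- esnps[ord, , drop = FALSE]
  keep <- logical(nrow(esnps))
  for (i in seq_len(nrow(esnps))) {
    prior <- which(keep & esnps$chrom == esnps$chrom[i])
    keep[i] <- !length(prior) ||
      all(abs(esnps$pos[prior] - esnps$pos[i]) > window_bp)
  }
  esnps[keep, , drop = FALSE]
}

# The qualifying eSNP map: eQTL records passing the mode thresholds whose
# rsID is present in the GWAS summary, reduced to one record per (gene, eSNP)
# (the best probe) and pruned by distance within each gene. The map depends
# on the GWAS only through its rsID set and positions, so it is shared
# between the observed summary and phenotype-permutation summaries.
.qualifying_map <- function(eqtl, gwas, cfg) {
  rec <- eqtl[(eqtl$mode == "cis" & eqtl$p < cfg$cis_p) |
                (eqtl$mode == "trans" & eqtl$p < cfg$trans_p), , drop = FALSE]
  rec <- rec[rec$rsID %in% gwas$rsID, , drop = FALSE]
  if (!nrow(rec)) {
    rec$chrom <- character(0); rec$pos <- integer(0)
    return(as.data.frame(rec))
  }
  rec <- rec[order(rec$gene_symbol, rec$p, rec$rsID, rec$probe_id), ,
             drop = FALSE]
  rec <- rec[!duplicated(rec[c("gene_symbol", "rsID")]), , drop = FALSE]
  gi <- match(rec$rsID, gwas$rsID)
  rec$chrom <- gwas$chrom[gi]
  rec$pos <- gwas$pos[gi]
  rec <- as.data.frame(rec)
  if (cfg$prune) {
    parts <- split(rec, rec$gene_symbol)
    rec <- do.call(rbind, lapply(parts, prune_esnps,
                                 window_bp = cfg$pruning_window_bp))
  }
  rownames(rec) <- NULL
  rec
}

# Per-gene totals for one GWAS summary given a qualifying map.
.totals_from_map <- function(map, gwas, cfg) {
  gwas_p <- gwas$p[match(map$rsID, gwas$rsID)]
  lbf <- wakefield_lbf(zscore_from_p(gwas_p), V = cfg$V, W = cfg$W)
  tot <- rowsum(lbf, map$gene_symbol)
  list(total = setNames(tot[, 1], rownames(tot)), lbf = lbf, gwas_p = gwas_p)
}

#' Score one gene by summed per-eSNP log Bayes factors
#'
#' Collects the gene's eQTL records passing the cis/trans thresholds and
#' present in the GWAS summary, keeps one record per eSNP (best probe),
#' optionally prunes eSNPs by distance, converts each eSNP's GWAS p-value to a
#' z-score and a Wakefield log10 Bayes factor, and sums the contributions. By
#' convention a total of 4.0 or more marks an individually significant gene.
#'
#' @param gene Gene symbol.
#' @param eqtl An \code{eqtl_table} (with \code{gene_symbol}).
#' @param gwas GWAS summary (\code{rsID}, \code{chrom}, \code{pos}, \code{p}).
#' @param cfg A \code{\link{score_config}}.
#' @return List with \code{gene_symbol}, \code{total_lbf},
#'   \code{contributions} (rsID, mode, eqtl_p, gwas_p, z, lbf), \code{n_cis},
#'   \code{n_trans}; or \code{NULL} when no eSNP qualifies.
#' @export
score_gene <- function(gene, eqtl, gwas, cfg = score_config()) {
  map <- .qualifying_map(eqtl[eqtl$gene_symbol == gene, , drop = FALSE],
                         gwas, cfg)
  if (!nrow(map)) return(NULL)
  res <- .totals_from_map(map, gwas, cfg)
  z <- zscore_from_p(res$gwas_p)
  list(gene_symbol = gene,
       total_lbf = unname(res$total[gene]),
       contributions = data.frame(
         rsID = map$rsID, mode = map$mode, eqtl_p = map$p,
         gwas_p = res$gwas_p, z = z, lbf = res$lbf,
         stringsAsFactors = FALSE),
       n_cis = sum(map$mode == "cis"),
       n_trans = sum(map$mode == "trans"))
}

#' Score all genes with qualifying eSNPs
#'
#' Vectorized \code{\link{score_gene}} over every gene symbol in the eQTL
#' table; genes with no qualifying eSNPs are absent from the output (their
#' count is recorded in the \code{n_genes_skipped} attribute).
#'
#' @inheritParams score_gene
#' @return Data frame sorted by decreasing \code{total_lbf}:
#'   \code{gene_symbol}, \code{total_lbf}, \code{n_esnps_cis},
#'   \code{n_esnps_trans}, \code{significant_by_convention} (total >= 4);
#'   attribute \code{contributions} holds the per-eSNP tables.
#' @export
score_genes <- function(eqtl, gwas, cfg = score_config()) {
  map <- .qualifying_map(eqtl, gwas, cfg)
  if (!nrow(map)) {
    out <- data.frame(gene_symbol = character(), total_lbf = numeric(),
                      n_esnps_cis = integer(), n_esnps_trans = integer(),
                      significant_by_convention = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "n_genes_skipped") <- length(unique(eqtl$gene_symbol))
    return(out)
  }
  res <- .totals_from_map(map, gwas, cfg)
  n_cis <- rowsum((map$mode == "cis") + 0L, map$gene_symbol)[, 1]
  n_trans <- rowsum((map$mode == "trans") + 0L, map$gene_symbol)[, 1]
  genes <- names(res$total)
  out <- data.frame(
    gene_symbol = genes,
    total_lbf = unname(res$total),
    n_esnps_cis = as.integer(n_cis[genes]),
    n_esnps_trans = as.integer(n_trans[genes]),
    stringsAsFactors = FALSE)
  out$significant_by_convention <- out$total_lbf >= 4
  out <- out[order(-out$total_lbf, out$gene_symbol), ]
  rownames(out) <- NULL
  contrib <- data.frame(
    gene_symbol = map$gene_symbol, rsID = map$rsID, mode = map$mode,
    eqtl_p = map$p, gwas_p = res$gwas_p,
    z = zscore_from_p(res$gwas_p), lbf = res$lbf, stringsAsFactors = FALSE)
  attr(out, "contributions") <- split(contrib, contrib$gene_symbol)
  attr(out, "n_genes_skipped") <-
    length(setdiff(unique(eqtl$gene_symbol), genes))
  out
}

#' Empirical p-values for gene scores from permutation nulls
#'
#' Recomputes the gene scores under each permuted GWAS summary (the
#' qualifying eSNP map is shared, since permutations change only the
#' association p-values) and converts observed totals to add-one empirical
#' p-values: p = (1 + #\{null >= observed\}) / (1 + N_null). The default
#' pooled mode pools null scores across genes and permutations, giving
#' resolution finer than 1/n_perm (50 permutations over a few thousand genes
#' resolve p-values well below 1e-3); per-gene mode compares each gene only
#' to its own nulls.
#'
#' @param observed Result of \code{\link{score_genes}} on the observed GWAS.
#' @param null_summaries List of permuted GWAS summaries (from
#'   \code{\link{permute_phenotype_gwas}}); each must cover the eSNP rsIDs.
#' @param eqtl,cfg The eQTL table and configuration used for \code{observed}.
#' @param pooling "pooled" (default) or "per_gene".
#' @return \code{observed} with an \code{empirical_p} column; attribute
#'   \code{null_scores} holds the gene x permutation null score matrix.
#' @export
empirical_p <- function(observed, null_summaries, eqtl, cfg = score_config(),
                        pooling = c("pooled", "per_gene")) {
  pooling <- match.arg(pooling)
  if (!length(null_summaries)) .stopf("need at least one permutation")
  if (!nrow(observed)) { observed$empirical_p <- numeric(0); return(observed) }
  map <- .qualifying_map(eqtl, null_summaries[[1]], cfg)
  null_mat <- vapply(null_summaries, function(gw) {
    tot <- .totals_from_map(map, gw, cfg)$total
    unname(tot[observed$gene_symbol])
  }, numeric(nrow(observed)))
  null_mat <- matrix(null_mat, nrow = nrow(observed),
                     dimnames = list(observed$gene_symbol,
                                     names(null_summaries)))
  if (pooling == "pooled") {
    pool <- null_mat[is.finite(null_mat)]
    observed$empirical_p <- vapply(observed$total_lbf, function(s)
      (1 + sum(pool >= s)) / (1 + length(pool)), 0)
  } else {
    observed$empirical_p <- vapply(seq_len(nrow(observed)), function(i) {
      nulls <- null_mat[i, is.finite(null_mat[i, ])]
      (1 + sum(nulls >= observed$total_lbf[i])) / (1 + length(nulls))
    }, 0)
  }
  attr(observed, "null_scores") <- null_mat
  observed
}
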