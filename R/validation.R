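#' Per-feature differential test by case-control status
#'
#' Fits, feature by feature, a linear model of the value on status plus
#' covariates and reports the ordinary two-sided t-test on the status
#' coefficient (residual degrees of freedom). The covariate-adjusted status
#' coefficient is the \code{effect}; the raw (unadjusted) case minus control
#' mean difference is kept alongside because the methylation relevance filter
#' operates on raw beta-value differences.
#'
#' @param mat Subjects x features numeric matrix (expression or methylation
#'   betas); rownames must match \code{phen$subject}.
#' @param phen Phenotype data frame (\code{subject}, \code{status}); at least
#'   two subjects per class.
#' @param cov Optional covariate data frame aligned to subjects.
#' @param annotation Optional data frame mapping features to genes (columns:
#'   feature id - \code{probe_id} or \code{cpg_id} - and \code{gene_symbol}).
#' @return Data frame: \code{feature_id}, \code{gene_symbol}, \code{effect},
#'   \code{raw_diff}, \code{se}, \code{t}, \code{p}.
#' @export
differential_test <- function(mat, phen, cov = NULL, annotation = NULL) {
  if (!identical(rownames(mat), phen$subject))
    .stopf("subject IDs differ between matrix and phenotype")
  if (sum(phen$status == 1) < 2 || sum(phen$status == 0) < 2)
    .stopf("need at least 2 subjects per class")
  C <- .covariate_design(nrow(mat), cov)
  fit <- .fwl_scan(matrix(phen$status, ncol = 1), mat, C)
  raw <- colMeans(mat[phen$status == 1, , drop = FALSE]) -
    colMeans(mat[phen$status == 0, , drop = FALSE])
  out <- data.frame(
    feature_id = colnames(mat),
    gene_symbol = NA_character_,
    effect = as.vector(fit$beta), raw_diff = unname(raw),
    se = as.vector(fit$se), t = as.vector(fit$t), p = as.vector(fit$p),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    id_col <- intersect(c("probe_id", "cpg_id", "feature_id"),
                        names(annotation))[1]
    out$gene_symbol <-
      annotation$gene_symbol[match(out$feature_id, annotation[[id_col]])]
  }
  out
}

#' Fisher's method for combining p-values
#'
#' X = -2 sum(ln p) referred to a chi-square with 2k degrees of freedom
#' (upper tail). Permutation-invariant and monotone: decreasing any input p
#' never increases the combined p. Assumes independent inputs; for community
#' features this assumption is knowingly optimistic (probes within a
#' community are correlated) and the result is reported as a meta-analysis
#' p-value with that caveat.
#'
#' @param p_list Numeric vector of p-values in (0, 1]; non-empty.
#' @return The combined p-value.
#' @examples
#' fisher_meta(c(0.5, 0.5))  # df 4: exp(-X/2) * (1 + X/2)
#' @export
fisher_meta <- function(p_list) {
  if (!length(p_list)) .stopf("empty p-value list")
  if (anyNA(p_list) || any(p_list <= 0 | p_list > 1))
    .stopf("p-values must lie in (0, 1]")
  x <- -2 * sum(log(p_list))
  .clamp_p(pchisq(x, df = 2 * length(p_list), lower.tail = FALSE))
}

#' Filter differentially methylated CpGs by raw effect size
#'
#' Retains CpGs whose absolute raw case-control mean beta difference is
#' strictly greater than \code{min_effect} (default 5%), focusing the
#' methylation meta-analysis on biologically meaningful shifts.
#'
#' @param dm A \code{\link{differential_test}} table on methylation betas.
#' @param min_effect Minimum absolute raw difference (strict; default 0.05).
#' @return The filtered table.
#' @export
methylation_effect_filter <- function(dm, min_effect = 0.05) {
  dm[abs(dm$raw_diff) > min_effect, , drop = FALSE]
}

#' Community-level meta-analysis of differential expression and methylation
#'
#' Combines, with Fisher's method, the differential-expression p-values of
#' all probes annotated to the community's genes, and the
#' differential-methylation p-values of the community's CpGs that pass the
#' raw effect filter. A community is \code{validated_both} when both meta
#' p-values fall below \code{alpha}, \code{validated_one} when exactly one
#' does, else \code{not_validated}. Communities with no qualifying CpGs (or
#' probes) get an absent (NA) meta p-value on that side, which counts as not
#' significant.
#'
#' @param genes Character vector: the community's gene roster.
#' @param de Differential-expression table (\code{gene_symbol}, \code{p}).
#' @param dm Differential-methylation table (\code{gene_symbol}, \code{p},
#'   \code{raw_diff}).
#' @param alpha Significance level for the validation call (default 0.05).
#' @param min_effect Methylation raw-effect filter (default 0.05).
#' @param community_id Optional id recorded in the output row.
#' @return One-row data frame: \code{community_id}, \code{n_genes},
#'   \code{n_probes}, \code{n_cpgs_filtered}, \code{n_de_genes},
#'   \code{n_dm_genes}, \code{expression_meta_p}, \code{methylation_meta_p},
#'   \code{status}.
#' @export
community_meta <- function(genes, de, dm, alpha = 0.05, min_effect = 0.05,
                           community_id = NA) {
  de_sub <- de[!is.na(de$gene_symbol) & de$gene_symbol %in% genes, ,
               drop = FALSE]
  dm_f <- methylation_effect_filter(dm, min_effect)
  dm_sub <- dm_f[!is.na(dm_f$gene_symbol) & dm_f$gene_symbol %in% genes, ,
                 drop = FALSE]
  e_meta <- if (nrow(de_sub)) fisher_meta(de_sub$p) else NA_real_
  m_meta <- if (nrow(dm_sub)) fisher_meta(dm_sub$p) else NA_real_
  e_sig <- !is.na(e_meta) && e_meta < alpha
  m_sig <- !is.na(m_meta) && m_meta < alpha
  data.frame(
    community_id = community_id,
    n_genes = length(genes),
    n_probes = nrow(de_sub),
    n_cpgs_filtered = nrow(dm_sub),
    n_de_genes = length(unique(de_sub$gene_symbol[de_sub$p < alpha])),
    n_dm_genes = length(unique(dm_sub$gene_symbol[dm_sub$p < alpha])),
    expression_meta_p = e_meta,
    methylation_meta_p = m_meta,
    status = if (e_sig && m_sig) "validated_both"
      else if (e_sig || m_sig) "validated_one" else "not_validated",
    stringsAsFactors = FALSE)
}

#' Validate every community of an assignment
#'
#' Applies \code{\link{community_meta}} to each community's gene roster.
#'
#' @param assign A \code{community_assignment}.
#' @param de,dm Differential tables as in \code{\link{community_meta}}.
#' @param alpha,min_effect Passed through.
#' @return Data frame with one row per community, ordered by id.
#' @export
validate_communities <- function(assign, de, dm, alpha = 0.05,
                                 min_effect = 0.05) {
  ids <- sort(unique(assign$membership))
  rows <- lapply(ids, function(cid) {
    members <- names(assign$membership)[assign$membership == cid]
    genes <- members[assign$side[members] == "gene"]
    community_meta(genes, de, dm, alpha, min_effect, community_id = cid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
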