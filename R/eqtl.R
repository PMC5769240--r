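# Frisch-Waugh-Lovell scan engine shared by the eQTL scan and the
# differential tests: residualize predictors X (n x S) and responses Y
# (n x G) on the covariate design C (n x p, including the intercept), then
# test each (x, y) pair by simple regression of the residuals. Identical to
# per-pair OLS of y on [x, C] with an ordinary t on the x coefficient and
# n - p - 1 residual df. Zero-residual fits report the smallest representable
# p rather than failing.
.fwl_scan <- function(X, Y, C) {
  n <- nrow(X)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    .stopf("covariates are rank-deficient; collinear column(s): %s",
           paste(dropped, collapse = ", "))
  }
  df <- n - ncol(C) - 1L
  if (df < 1) .stopf("too few subjects for %d covariate columns", ncol(C))
  RX <- qr.resid(qrC, X)
  RY <- qr.resid(qrC, Y)
  sxx <- colSums(RX^2)
  syy <- colSums(RY^2)
  sxy <- crossprod(RX, RY)                       # S x G
  beta <- sxy / sxx
  syy_mat <- outer(rep(1, length(sxx)), syy)
  sse <- pmax(syy_mat - sxy^2 / sxx, 0)
  se <- sqrt((sse / df) / sxx)
  t <- beta / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # zero-residual fits with a nonzero slope are perfect signals: report the
  # smallest representable p rather than failing (relative tolerance guards
  # against qr round-off)
  perfect <- sse <= 1e-12 * syy_mat & syy_mat > 0 & beta != 0
  t[perfect] <- sign(beta[perfect]) * Inf
  p[perfect] <- 0
  # constant responses carry no evidence at all: slope 0, p = 1 (detected on
  # the unresidualized input, where constancy is exact)
  flat <- matrix(apply(Y, 2, var) == 0, nrow(sse), ncol(sse), byrow = TRUE)
  beta[flat] <- 0
  t[flat] <- 0
  p[flat] <- 1
  list(beta = beta, se = se, t = t, p = .clamp_p(p), df = df)
}

.covariate_design <- function(n, cov = NULL, extra = NULL) {
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(cov)) {
    cv <- cov[setdiff(names(cov), "subject")]
    if (ncol(cv)) {
      if (any(!vapply(cv, is.numeric, TRUE)))
        .stopf("covariate columns must be numeric")
      if (anyNA(cv)) .stopf("covariates contain missing values")
      C <- cbind(C, as.matrix(cv))
    }
  }
  if (!is.null(extra) && ncol(extra)) C <- cbind(C, extra)
  C
}

#' Assign cis/trans mode to SNP-probe pairs by genomic window
#'
#' A pair is cis when the SNP lies on the probe's chromosome within
#' \code{window_bp} of the annotated gene interval (boundary inclusive,
#' coordinates 1-based inclusive); all other pairs are trans, mirroring a
#' genome-wide trans analysis. The window is anchored at the annotated start
#' and end of the gene, so the total cis span is the gene length plus twice
#' \code{window_bp}.
#'
#' @param panel SNP panel (\code{rsID}, \code{chrom}, \code{pos}).
#' @param probes Probe annotation (\code{probe_id}, \code{gene_symbol},
#'   \code{chrom}, \code{start}, \code{end}).
#' @param window_bp Window size in base pairs on each side (default 500 kb,
#'   i.e. a 1 Mb total window).
#' @return Data frame of all SNP x probe pairs with columns \code{rsID},
#'   \code{probe_id}, \code{mode} ("cis"/"trans").
#' @examples
#' panel <- data.frame(rsID = "rs1", chrom = "1", pos = 500001)
#' probes <- data.frame(probe_id = "P1", gene_symbol = "G1", chrom = "1",
#'                      start = 1000000, end = 1005000)
#' assign_cis_pairs(panel, probes)$mode  # "cis": distance 499,999
#' @export
assign_cis_pairs <- function(panel, probes, window_bp = 500000) {
  flags <- .cis_flags(panel, probes, window_bp)
  data.frame(
    rsID = rep(panel$rsID, times = nrow(probes)),
    probe_id = rep(probes$probe_id, each = nrow(panel)),
    mode = ifelse(as.vector(flags), "cis", "trans"),
    stringsAsFactors = FALSE)
}

# S x G logical matrix of cis flags.
.cis_flags <- function(panel, probes, window_bp) {
  if (anyNA(panel$chrom) || anyNA(probes$chrom) ||
      any(panel$chrom == "") || any(probes$chrom == ""))
    .stopf("unknown chromosome label")
  same <- outer(panel$chrom, probes$chrom, "==")
  lo <- outer(panel$pos, probes$start - window_bp, ">=")
  hi <- outer(panel$pos, probes$end + window_bp, "<=")
  same & lo & hi
}

#' Single-pair dosage-expression association fit
#'
#' Ordinary least squares of one expression vector on one dosage vector plus
#' covariates (and an intercept), with a two-sided t-test on the dosage
#' coefficient at the residual degrees of freedom. A perfect (zero-residual)
#' fit reports the smallest representable p-value rather than erroring.
#'
#' @param expr_row Numeric expression vector.
#' @param dosage_row Numeric dosage vector in [0, 2] (continuous dosages
#'   allowed); must not be constant.
#' @param cov Optional covariate data frame (a \code{subject} column is
#'   ignored; remaining columns must be numeric and complete).
#' @return One-row data frame: \code{beta}, \code{se}, \code{t}, \code{p},
#'   \code{df}.
#' @export
fit_association <- function(expr_row, dosage_row, cov = NULL) {
  stopifnot(length(expr_row) == length(dosage_row))
  if (var(dosage_row) == 0) .stopf("monomorphic: dosage is constant")
  C <- .covariate_design(length(expr_row), cov)
  fit <- .fwl_scan(matrix(dosage_row, ncol = 1), matrix(expr_row, ncol = 1), C)
  data.frame(beta = fit$beta[1, 1], se = fit$se[1, 1], t = fit$t[1, 1],
             p = fit$p[1, 1], df = fit$df)
}

#' Principal components of the expression matrix
#'
#' Top-k PCs of the column-centred subjects x probes matrix, used as scan
#' covariates to absorb batch and other broad technical structure. Sign is
#' fixed deterministically: the largest-magnitude loading of each component is
#' made positive. \code{k = 0} returns an empty covariate block (the scan then
#' runs unadjusted for expression PCs).
#'
#' @param expr Subjects x probes numeric matrix.
#' @param k Number of components; must satisfy
#'   \code{k < min(nrow(expr), ncol(expr))}.
#' @return Subjects x k matrix (columns \code{expr_pc1}, ...).
#' @export
compute_expression_pcs <- function(expr, k = 13) {
  if (k < 0) .stopf("k must be >= 0")
  if (k == 0)
    return(matrix(0, nrow(expr), 0, dimnames = list(rownames(expr), NULL)))
  if (k >= min(dim(expr))) .stopf("k must be < min(n_subjects, n_probes)")
  pc <- prcomp(expr, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(pc$rotation[, i]))
    if (pc$rotation[j, i] < 0) scores[, i] <- -scores[, i]
  }
  colnames(scores) <- paste0("expr_pc", seq_len(k))
  rownames(scores) <- rownames(expr)
  scores
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH adjustment (via \code{stats::p.adjust}) with input validation:
#' p-values must lie in (0, 1]. Order-preserving; adjusted values can equal
#' the raw p.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of BH-adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) && (anyNA(p) || any(p <= 0 | p > 1)))
    .stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Genome-wide eQTL scan with cis/trans FDR
#'
#' Tests every SNP-probe pair by covariate-adjusted linear regression of
#' expression on dosage (ordinary t-test on the dosage coefficient), assigns
#' cis/trans mode by the genomic window rule, and applies Benjamini-Hochberg
#' FDR separately within the cis and trans families (they are reported as
#' separate analyses with separate counts). Expression principal components
#' are computed internally and appended to the covariates. Monomorphic SNPs
#' and zero-variance probes are dropped with counts recorded in the
#' provenance attribute, not errors.
#'
#' @param gt A \code{genotype_matrix} (or list with \code{dosage},
#'   \code{panel}).
#' @param expr Subjects x probes matrix; rownames must match the genotype
#'   subjects in order.
#' @param probes Probe annotation (\code{probe_id}, \code{gene_symbol},
#'   \code{chrom}, \code{start}, \code{end}).
#' @param cov Optional covariate data frame aligned to subjects (e.g. age,
#'   sex, pack-years, ancestry PCs).
#' @param window_bp Cis window per side (default 500 kb).
#' @param n_expr_pcs Number of expression PCs to append (default 13).
#' @param cis_alpha,trans_alpha FDR levels recorded in provenance and used by
#'   downstream significance filters.
#' @return An \code{eqtl_table} data frame sorted by p: \code{rsID},
#'   \code{probe_id}, \code{gene_symbol}, \code{beta}, \code{se}, \code{t},
#'   \code{p}, \code{q}, \code{mode}; attribute \code{provenance} holds test
#'   counts, drops, window, df and thresholds.
#' @export
run_scan <- function(gt, expr, probes, cov = NULL, window_bp = 500000,
                     n_expr_pcs = 13, cis_alpha = 0.05, trans_alpha = 0.05) {
  dos <- gt$dosage
  panel <- gt$panel
  if (!identical(rownames(dos), rownames(expr)))
    .stopf("subject IDs differ between genotypes and expression")
  if (!is.null(cov) && !identical(cov$subject, rownames(dos)))
    .stopf("subject IDs differ between genotypes and covariates")
  keep_snp <- apply(dos, 2, var) > 0
  keep_probe <- apply(expr, 2, var) > 0
  n_drop_snp <- sum(!keep_snp); n_drop_probe <- sum(!keep_probe)
  dos <- dos[, keep_snp, drop = FALSE]
  expr <- expr[, keep_probe, drop = FALSE]
  panel <- panel[keep_snp, , drop = FALSE]
  probes <- probes[match(colnames(expr), probes$probe_id), , drop = FALSE]
  if (!ncol(dos) || !ncol(expr)) .stopf("empty pair set after filtering")

  pcs <- compute_expression_pcs(expr, n_expr_pcs)
  C <- .covariate_design(nrow(dos), cov, pcs)
  fit <- .fwl_scan(dos, expr, C)
  cis <- .cis_flags(panel, probes, window_bp)

  tab <- data.frame(
    rsID = rep(panel$rsID, times = nrow(probes)),
    probe_id = rep(probes$probe_id, each = nrow(panel)),
    gene_symbol = rep(probes$gene_symbol, each = nrow(panel)),
    beta = as.vector(fit$beta), se = as.vector(fit$se),
    t = as.vector(fit$t), p = as.vector(fit$p),
    q = NA_real_, mode = ifelse(as.vector(cis), "cis", "trans"),
    stringsAsFactors = FALSE)
  for (m in c("cis", "trans")) {
    idx <- tab$mode == m
    if (any(idx)) tab$q[idx] <- bh_fdr(tab$p[idx])
  }
  tab <- tab[order(tab$p, tab$rsID, tab$probe_id), ]
  rownames(tab) <- NULL
  attr(tab, "provenance") <- list(
    n_tests_cis = sum(tab$mode == "cis"),
    n_tests_trans = sum(tab$mode == "trans"),
    n_dropped_monomorphic_snps = n_drop_snp,
    n_dropped_zero_variance_probes = n_drop_probe,
    window_bp = window_bp, n_expr_pcs = n_expr_pcs,
    n_covariate_columns = ncol(C), df_resid = fit$df,
    cis_alpha = cis_alpha, trans_alpha = trans_alpha)
  class(tab) <- c("eqtl_table", "data.frame")
  tab
}
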