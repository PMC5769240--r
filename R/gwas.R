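#' Load GWAS summary statistics (PLINK-assoc-like dialect)
#'
#' Reads a whitespace-delimited file with a header row naming at least the
#' rsID and p-value columns (\code{SNP}/\code{rsID}, \code{CHR}/\code{chrom},
#' \code{BP}/\code{pos}, \code{P}/\code{p}; case-insensitive). Rows whose p is
#' non-numeric or outside (0, 1] are rejected with a warning listing their
#' 1-based file line numbers; duplicate rsIDs and a malformed header are
#' errors.
#'
#' @param path Path to the summary file.
#' @return Data frame \code{rsID}, \code{chrom}, \code{pos}, \code{p}.
#' @export
load_gwas_summary <- function(path) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  nm <- toupper(names(raw))
  pick <- function(cands) {
    hit <- match(cands, nm)
    hit[!is.na(hit)][1]
  }
  i_snp <- pick(c("SNP", "RSID", "ID"))
  i_p <- pick("P")
  if (is.na(i_snp) || is.na(i_p))
    .stopf("malformed header: need SNP/rsID and P columns, got: %s",
           paste(names(raw), collapse = ", "))
  i_chr <- pick(c("CHR", "CHROM"))
  i_bp <- pick(c("BP", "POS"))
  p <- suppressWarnings(as.numeric(raw[[i_p]]))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad))
    warning(sprintf("rejected %d row(s) with invalid p at file line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
  out <- data.frame(
    rsID = raw[[i_snp]][!bad],
    chrom = if (!is.na(i_chr)) raw[[i_chr]][!bad] else NA_character_,
    pos = if (!is.na(i_bp)) as.integer(raw[[i_bp]][!bad]) else NA_integer_,
    p = p[!bad], stringsAsFactors = FALSE)
  dup <- unique(out$rsID[duplicated(out$rsID)])
  if (length(dup))
    .stopf("duplicate rsID(s): %s", paste(head(dup, 5), collapse = ", "))
  out
}

#' Intersect significant eQTLs with suggestive GWAS SNPs
#'
#' Returns the GWAS SNPs below the suggestive threshold that are also eSNPs at
#' the given eQTL FDR, each annotated with its best (minimum-p) eGene probe.
#' Ties in the best probe are broken by (p, then lexicographic probe_id). An
#' empty result is a valid outcome, not an error.
#'
#' @param eqtl An \code{eqtl_table} (needs \code{rsID}, \code{probe_id},
#'   \code{p}, \code{q}, \code{mode}).
#' @param gwas GWAS summary data frame (\code{rsID}, \code{p}).
#' @param gwas_thresh Suggestive GWAS threshold (default 1e-4).
#' @param fdr eQTL FDR threshold on \code{q} (default 0.05).
#' @param mode Which eQTL mode defines eSNP status (default "cis", matching
#'   an intersection of cis results; "any" uses both).
#' @return Data frame \code{rsID}, \code{gwas_p}, \code{best_eqtl_probe},
#'   \code{best_eqtl_p}, \code{q}, \code{genomewide} (GWAS p < 5e-8).
#' @export
intersect_eqtl_gwas <- function(eqtl, gwas, gwas_thresh = 1e-4, fdr = 0.05,
                                mode = c("cis", "any")) {
  mode <- match.arg(mode)
  es <- eqtl[eqtl$q < fdr & (mode == "any" | eqtl$mode == "cis"), , drop = FALSE]
  hits <- gwas[gwas$p < gwas_thresh, , drop = FALSE]
  es <- es[es$rsID %in% hits$rsID, , drop = FALSE]
  if (!nrow(es))
    return(data.frame(rsID = character(), gwas_p = numeric(),
                      best_eqtl_probe = character(), best_eqtl_p = numeric(),
                      q = numeric(), genomewide = logical(),
                      stringsAsFactors = FALSE))
  es <- es[order(es$rsID, es$p, es$probe_id), , drop = FALSE]
  best <- es[!duplicated(es$rsID), , drop = FALSE]
  out <- data.frame(
    rsID = best$rsID,
    gwas_p = hits$p[match(best$rsID, hits$rsID)],
    best_eqtl_probe = best$probe_id,
    best_eqtl_p = best$p,
    q = best$q,
    stringsAsFactors = FALSE)
  out$genomewide <- out$gwas_p < 5e-8
  out <- out[order(out$gwas_p, out$rsID), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of an overlap
#'
#' Fold enrichment and upper-tail hypergeometric probability for observing
#' \code{k} eSNPs among \code{n} GWAS hits when \code{K} of the \code{N}
#' universe SNPs are eSNPs. The universe should be the SNPs tested in both
#' analyses. The tail probability P(X >= k) is computed with
#' \code{stats::phyper}, which evaluates stably in log space internally.
#'
#' @param k Overlap count.
#' @param n GWAS-hit count.
#' @param K eSNP count in the universe.
#' @param N Universe size.
#' @return List with \code{fold} = (k/n)/(K/N) and \code{p} = P(X >= k).
#' @examples
#' hypergeometric_enrichment(3, 5, 4, 10)$p  # 66/252
#' @export
hypergeometric_enrichment <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || any(c(k, n, K, N) < 0))
    .stopf("inconsistent counts: need k <= min(n, K) and n, K <= N")
  if (n == 0 || K == 0)
    return(list(fold = 0, p = 1))
  list(fold = (k / n) / (K / N),
       p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Permutation-null GWAS summaries from phenotype shuffles
#'
#' Shuffles the case-control labels (preserving class totals), recomputes
#' per-SNP association p-values with the same allelic trend test used for the
#' simulated GWAS, and returns one summary per permutation. With a fixed seed
#' the sequence of summaries is deterministic.
#'
#' @param gt A \code{genotype_matrix}.
#' @param phen Phenotype data frame (\code{subject}, \code{status}); at least
#'   two subjects per class.
#' @param n_perm Number of permutations (default 50).
#' @param seed Optional integer seed.
#' @return Named list (\code{perm_001}, ...) of GWAS summary data frames
#'   (\code{rsID}, \code{chrom}, \code{pos}, \code{p}, \code{monomorphic}).
#' @export
permute_phenotype_gwas <- function(gt, phen, n_perm = 50, seed = NULL) {
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (sum(phen$status == 1) < 2 || sum(phen$status == 0) < 2)
    .stopf("need at least 2 subjects in each class")
  if (!identical(phen$subject, rownames(gt$dosage)))
    .stopf("subject IDs differ between genotypes and phenotype")
  .set_seed_if(seed)
  panel <- gt$panel
  out <- lapply(seq_len(n_perm), function(b) {
    res <- .assoc_score_test(gt$dosage, sample(phen$status))
    data.frame(rsID = panel$rsID, chrom = panel$chrom, pos = panel$pos,
               p = res$p, monomorphic = res$monomorphic,
               stringsAsFactors = FALSE)
  })
  names(out) <- sprintf("perm_%03d", seq_len(n_perm))
  out
}
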