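#' Build a synthetic-cohort simulation plan
#'
#' A simulation plan bundles the SNP panel, probe and CpG annotations, and the
#' planted effects that together define a synthetic case-control eQTL study:
#' LD-blocked genotypes, expression with cis/trans eQTLs, a disease liability
#' driven by a subset of the eQTL SNPs (the "shared" loci), an independent GWAS
#' cohort, and case-control methylation shifts. The default scale mirrors a
#' severe-COPD lung-tissue study design: 86 cases and 31 controls.
#'
#' SNPs are laid out on \code{n_chrom} chromosomes at regular spacing; genes are
#' spread evenly along the same chromosomes so that every gene has SNPs inside
#' its cis window. Cis effects are planted on the SNP nearest each affected
#' gene's start; trans effects pair a gene with a SNP on another chromosome.
#' Disease-causal SNPs are (by default) the first \code{n_disease_causal} cis
#' eSNPs, making their genes "shared" between expression and disease liability.
#' CpGs are annotated to genes round-robin; differential methylation is planted
#' on the first CpG of each of the first \code{n_dm_effects} genes.
#'
#' @param n_cases,n_controls Cohort quota (defaults 86 / 31).
#' @param n_snps,n_genes,n_cpgs Panel sizes.
#' @param n_chrom Number of chromosomes the panel spans.
#' @param snp_spacing_bp Base pairs between adjacent panel SNPs.
#' @param gene_length_bp Length of each annotated gene interval.
#' @param maf_range Range minor-allele frequencies are drawn from (must lie
#'   within (0, 0.5]; the downstream panel filter assumes MAF > 5%).
#' @param ld_block_size SNPs per LD block for the haplotype-copying model.
#' @param ld_rho Within-block copying probability in [0, 1).
#' @param n_cis_effects,cis_beta Number and size (expression units per allele)
#'   of planted cis eQTLs.
#' @param n_trans_effects,trans_beta Planted trans eQTLs.
#' @param n_disease_causal,disease_log_or Number of cis eSNPs that also carry
#'   disease liability, and their per-allele log odds ratio.
#' @param n_dm_effects,dm_diff Number of CpGs with a planted case-control mean
#'   beta-value difference, and that difference (in [0, 1]).
#' @param noise_sd Residual SD of expression.
#' @param meth_latent_sd SD of the latent Gaussian behind methylation betas.
#' @param n_gwas Size of the independently simulated GWAS cohort.
#' @param cis_window_bp Cis window used to validate planted cis effects.
#' @param seed Integer seed fixing the randomized parts of the plan itself
#'   (MAFs, CpG baselines).
#'
#' @return An object of class \code{sim_plan}: a list with the panel,
#'   annotations, planted-effect tables and scalar parameters.
#' @examples
#' plan <- default_plan(n_snps = 100, n_genes = 10, n_cpgs = 20)
#' plan$cis_effects[1:3, ]
#' @export
default_plan <- function(n_cases = 86, n_controls = 31,
                         n_snps = 2000, n_genes = 200, n_cpgs = 500,
                         n_chrom = 2, snp_spacing_bp = 10000,
                         gene_length_bp = 5000, maf_range = c(0.1, 0.5),
                         ld_block_size = 10, ld_rho = 0.8,
                         n_cis_effects = 30, cis_beta = 0.8,
                         n_trans_effects = 5, trans_beta = 1.2,
                         n_disease_causal = 10, disease_log_or = 0.4,
                         n_dm_effects = 25, dm_diff = 0.10,
                         noise_sd = 1, meth_latent_sd = 0.5,
                         n_gwas = 5000, cis_window_bp = 500000L,
                         seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= n_chrom,
            n_genes >= n_chrom, n_cpgs >= 1, n_chrom >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    .stopf("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) .stopf("ld_rho must be in [0, 1)")
  if (dm_diff < 0 || dm_diff > 1) .stopf("dm_diff must be in [0, 1]")
  if (n_cis_effects + n_trans_effects > n_genes)
    .stopf("more planted effects than genes")
  if (n_disease_causal > n_cis_effects)
    .stopf("disease-causal SNPs are drawn from the cis eSNPs")

  seed <- as.integer(seed)
  rng <- local({ set.seed(seed); list(maf = runif(n_snps, maf_range[1], maf_range[2]),
                                      base = runif(n_cpgs, 0.25, 0.75)) })

  # SNP panel: round-robin chromosome assignment keeps per-chrom counts even.
  chrom_of_snp <- rep(seq_len(n_chrom), length.out = n_snps)
  idx_in_chrom <- stats::ave(seq_len(n_snps), chrom_of_snp, FUN = seq_along)
  panel <- data.frame(
    rsID  = sprintf("rs%06d", seq_len(n_snps)),
    chrom = as.character(chrom_of_snp),
    pos   = 50000L + (idx_in_chrom - 1L) * as.integer(snp_spacing_bp),
    maf   = rng$maf,
    stringsAsFactors = FALSE)

  # Genes spread evenly along each chromosome, anchored at a panel SNP.
  chrom_of_gene <- rep(seq_len(n_chrom), length.out = n_genes)
  probes <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    g_idx <- which(chrom_of_gene == ch)
    s_pos <- panel$pos[panel$chrom == as.character(ch)]
    anchor <- s_pos[pmax(1L, round(seq_along(g_idx) * length(s_pos) /
                                     (length(g_idx) + 1L)))]
    data.frame(gene_idx = g_idx, chrom = as.character(ch),
               start = anchor + 1L, end = anchor + as.integer(gene_length_bp),
               stringsAsFactors = FALSE)
  }))
  probes <- probes[order(probes$gene_idx), ]
  probes <- data.frame(
    probe_id    = sprintf("P%04d", probes$gene_idx),
    gene_symbol = sprintf("G%04d", probes$gene_idx),
    chrom = probes$chrom, start = probes$start, end = probes$end,
    stringsAsFactors = FALSE)
  rownames(probes) <- NULL

  nearest_snp <- function(i) {
    on_chr <- which(panel$chrom == probes$chrom[i])
    on_chr[which.min(abs(panel$pos[on_chr] - probes$start[i]))]
  }

  cis_effects <- trans_effects <- data.frame(
    rsID = character(), gene_symbol = character(), beta = numeric(),
    stringsAsFactors = FALSE)
  if (n_cis_effects > 0) {
    gi <- seq_len(n_cis_effects)
    cis_effects <- data.frame(
      rsID = panel$rsID[vapply(gi, nearest_snp, 1L)],
      gene_symbol = probes$gene_symbol[gi],
      beta = cis_beta, stringsAsFactors = FALSE)
  }
  if (n_trans_effects > 0) {
    gi <- n_cis_effects + seq_len(n_trans_effects)
    # a SNP far from the gene: anchor of a gene on a different chromosome
    other <- vapply(gi, function(i) {
      off <- which(panel$chrom != probes$chrom[i])
      off[((i * 37L) %% length(off)) + 1L]
    }, 1L)
    trans_effects <- data.frame(
      rsID = panel$rsID[other],
      gene_symbol = probes$gene_symbol[gi],
      beta = trans_beta, stringsAsFactors = FALSE)
  }

  disease_causal <- data.frame(rsID = character(), log_odds = numeric(),
                               stringsAsFactors = FALSE)
  if (n_disease_causal > 0)
    disease_causal <- data.frame(
      rsID = cis_effects$rsID[seq_len(n_disease_causal)],
      log_odds = disease_log_or, stringsAsFactors = FALSE)

  cpgs <- data.frame(
    cpg_id = sprintf("cg%05d", seq_len(n_cpgs)),
    gene_symbol = probes$gene_symbol[rep(seq_len(n_genes),
                                         length.out = n_cpgs)],
    baseline = rng$base, stringsAsFactors = FALSE)

  dm_effects <- data.frame(cpg_id = character(), diff = numeric(),
                           stringsAsFactors = FALSE)
  if (n_dm_effects > 0) {
    first_cpg <- cpgs$cpg_id[match(probes$gene_symbol[seq_len(n_dm_effects)],
                                   cpgs$gene_symbol)]
    dm_effects <- data.frame(cpg_id = first_cpg, diff = dm_diff,
                             stringsAsFactors = FALSE)
  }

  plan <- structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_subjects = as.integer(n_cases + n_controls),
    panel = panel, probes = probes, cpgs = cpgs,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    cis_effects = cis_effects, trans_effects = trans_effects,
    disease_causal = disease_causal, dm_effects = dm_effects,
    noise_sd = noise_sd, meth_latent_sd = meth_latent_sd,
    n_gwas = as.integer(n_gwas), cis_window_bp = as.integer(cis_window_bp),
    seed = seed), class = "sim_plan")
  validate_plan(plan)
  plan
}

#' Validate a simulation plan's internal consistency
#'
#' Checks the invariants the downstream analysis assumes: unique rsIDs,
#' strictly increasing positions within chromosomes, MAFs in (0, 0.5], every
#' cis effect within the cis window of its gene, disease-causal SNPs drawn from
#' the panel, and methylation differences within [0, 1].
#'
#' @param plan A \code{sim_plan}.
#' @return The plan, invisibly; errors describe the first violated invariant.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  p <- plan$panel
  if (anyDuplicated(p$rsID)) .stopf("duplicated rsIDs in panel")
  if (any(p$maf <= 0 | p$maf > 0.5)) .stopf("panel MAF outside (0, 0.5]")
  for (ch in unique(p$chrom)) {
    pos <- p$pos[p$chrom == ch]
    if (any(diff(pos) <= 0))
      .stopf("positions not strictly increasing on chrom %s", ch)
  }
  if (!all(plan$disease_causal$rsID %in% p$rsID))
    .stopf("disease_causal references SNPs absent from the panel")
  if (!all(plan$dm_effects$cpg_id %in% plan$cpgs$cpg_id))
    .stopf("dm_effects references unknown CpGs")
  if (any(plan$dm_effects$diff < -1 | plan$dm_effects$diff > 1))
    .stopf("methylation differences must lie in [-1, 1]")
  ce <- plan$cis_effects
  if (nrow(ce)) {
    si <- match(ce$rsID, p$rsID)
    gi <- match(ce$gene_symbol, plan$probes$gene_symbol)
    if (anyNA(si) || anyNA(gi)) .stopf("cis effect references unknown SNP/gene")
    ok <- p$chrom[si] == plan$probes$chrom[gi] &
      p$pos[si] >= plan$probes$start[gi] - plan$cis_window_bp &
      p$pos[si] <= plan$probes$end[gi] + plan$cis_window_bp
    if (!all(ok))
      .stopf("cis effect %s-%s lies outside the cis window",
             ce$rsID[!ok][1], ce$gene_symbol[!ok][1])
  }
  invisible(plan)
}

#' Read a simulation plan from a YAML file
#'
#' The YAML file holds scalar knobs (any argument of
#' \code{\link{default_plan}}, e.g. \code{n_cases}, \code{n_snps},
#' \code{cis_beta}, \code{seed}); the full panel, annotations and effect
#' tables are derived deterministically from them.
#'
#' @param path Path to a YAML file.
#' @return A \code{sim_plan}.
#' @export
read_plan_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(default_plan))
  bad <- setdiff(names(raw), known)
  if (length(bad)) .stopf("unknown plan fields: %s", paste(bad, collapse = ", "))
  do.call(default_plan, raw)
}

#' @export
print.sim_plan <- function(x, ...) {
  cat("Simulation plan:",
      sprintf("%d cases / %d controls, %d SNPs (%d chrom), %d genes, %d CpGs",
              x$n_cases, x$n_controls, nrow(x$panel),
              length(unique(x$panel$chrom)), nrow(x$probes), nrow(x$cpgs)),
      sprintf("planted: %d cis, %d trans eQTLs; %d disease SNPs; %d DM CpGs",
              nrow(x$cis_effects), nrow(x$trans_effects),
              nrow(x$disease_causal), nrow(x$dm_effects)),
      sprintf("LD blocks of %d (rho = %.2f), noise_sd = %.2f, seed = %d",
              x$ld_block_size, x$ld_rho, x$noise_sd, x$seed),
      sep = "\n  ")
  invisible(x)
}
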