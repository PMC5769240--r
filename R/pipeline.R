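#' Run the full ensemble analysis on a synthetic cohort
#'
#' End-to-end chain: simulate the cohort (genotypes, covariates, expression,
#' phenotype, methylation, an independent GWAS cohort's summary), run the
#' eQTL scan, intersect significant cis eQTLs with suggestive GWAS SNPs and
#' quantify hypergeometric enrichment, build phenotype-permutation null GWAS
#' summaries, compute LBF gene scores with pooled empirical p-values, build
#' the filtered bipartite eSNP-eGene network, detect communities by BRIM, and
#' validate every community by Fisher meta-analysis of differential
#' expression and methylation. All declared output files plus a provenance
#' JSON (thresholds recorded verbatim) are written under \code{out_dir}.
#'
#' @param plan A \code{sim_plan} (default \code{\link{default_plan}()}).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving the whole run.
#' @param n_expr_pcs Expression PCs used as scan covariates (default 13).
#' @param window_bp Cis window per side (default 500 kb).
#' @param cis_fdr eQTL FDR defining eSNPs for the intersection (default 5%).
#' @param cis_p,trans_p Nominal eQTL thresholds feeding the gene scores and
#'   the network (defaults 1e-3, 1e-6).
#' @param gwas_thresh Suggestive GWAS threshold (default 1e-4).
#' @param n_perm Phenotype permutations for the null scores (default 50).
#' @param sherlock_p Empirical p cutoff selecting seed genes for the
#'   community lookup (default 1e-3).
#' @param write_graphml Also export the network as GraphML.
#' @return Invisibly, a list with every intermediate object (\code{plan},
#'   \code{genotypes}, \code{eqtl}, \code{intersection}, \code{enrichment},
#'   \code{scores}, \code{network}, \code{communities}, \code{validation},
#'   \code{provenance}, \code{files}, ...).
#' @export
run_ensemble_pipeline <- function(plan = default_plan(), out_dir = tempfile("eqtlens_"),
                                  seed = 1L,
                                  n_expr_pcs = 13, window_bp = plan$cis_window_bp,
                                  cis_fdr = 0.05, cis_p = 1e-3, trans_p = 1e-6,
                                  gwas_thresh = 1e-4, n_perm = 50,
                                  sherlock_p = 1e-3, write_graphml = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  set.seed(as.integer(seed))

  # --- simulate -------------------------------------------------------------
  covariates <- generate_covariates(plan$n_subjects)
  gt <- generate_genotypes(plan$panel, plan$n_subjects,
                           plan$ld_block_size, plan$ld_rho)
  expr <- generate_expression(gt, plan, covariates)
  phen <- generate_disease_phenotype(gt, plan)
  meth <- generate_methylation(phen, plan)
  gwas <- generate_gwas_summary(plan$panel, plan, plan$n_gwas)

  write_genotype_vcf(gt, fp("genotypes.vcf"))
  write_matrix_tsv(gt$dosage, fp("genotypes.tsv"))
  .write_tsv(plan$panel, fp("snp_annotation.tsv"))
  write_matrix_tsv(expr, fp("expression.tsv"))
  .write_tsv(plan$probes, fp("probe_annotation.tsv"))
  write_matrix_tsv(meth, fp("methylation.tsv"))
  .write_tsv(plan$cpgs[c("cpg_id", "gene_symbol")], fp("cpg_annotation.tsv"))
  .write_tsv(phen, fp("phenotype.tsv"))
  .write_tsv(covariates, fp("covariates.tsv"))
  write_gwas_summary(gwas, fp("gwas.assoc"))

  # --- eQTL scan ------------------------------------------------------------
  eqtl <- run_scan(gt, expr, plan$probes, covariates,
                   window_bp = window_bp, n_expr_pcs = n_expr_pcs,
                   cis_alpha = cis_fdr)
  .write_tsv(eqtl, fp("eqtl.tsv"))

  # --- GWAS intersection & enrichment --------------------------------------
  intersection <- intersect_eqtl_gwas(eqtl, gwas, gwas_thresh, cis_fdr)
  .write_tsv(intersection, fp("intersection.tsv"))
  cis_tab <- eqtl[eqtl$mode == "cis", ]
  universe <- intersect(unique(cis_tab$rsID), gwas$rsID)
  esnps <- unique(cis_tab$rsID[cis_tab$q < cis_fdr])
  hits <- gwas$rsID[gwas$p < gwas_thresh]
  enrichment <- hypergeometric_enrichment(
    k = length(intersect(intersect(esnps, hits), universe)),
    n = length(intersect(hits, universe)),
    K = length(intersect(esnps, universe)),
    N = length(universe))
  enrichment$universe <- "SNPs tested in both the cis-eQTL scan and the GWAS"

  # --- permutation nulls & gene scores -------------------------------------
  perms <- permute_phenotype_gwas(gt, phen, n_perm = n_perm)
  for (nm in names(perms)) write_gwas_summary(perms[[nm]],
                                              fp(paste0(nm, ".assoc")))
  cfg <- score_config(cis_p = cis_p, trans_p = trans_p)
  scores <- score_genes(eqtl, gwas, cfg)
  scores <- empirical_p(scores, perms, eqtl, cfg)
  .write_tsv(scores, fp("gene_scores.tsv"))

  # --- network & communities ------------------------------------------------
  network <- build_network(eqtl, gwas, cis_p = cis_p, trans_p = trans_p)
  write_network(network, fp("network_edges.tsv"))
  if (write_graphml) write_network(network, fp("network.graphml"), "graphml")
  communities <- brim_fit(network, seed = seed)
  .write_tsv(data.frame(node = names(communities$membership),
                        side = unname(communities$side),
                        community = unname(communities$membership),
                        stringsAsFactors = FALSE),
             fp("communities.tsv"))
  seed_genes <- scores$gene_symbol[scores$empirical_p < sherlock_p]
  seeded <- locate_seed_communities(communities, seed_genes, gwas,
                                    subthreshold = gwas_thresh)

  # --- community validation -------------------------------------------------
  de <- differential_test(expr, phen, covariates, annotation = plan$probes)
  dm <- differential_test(meth, phen, covariates, annotation = plan$cpgs)
  validation <- validate_communities(communities, de, dm)
  validation$has_seed_gene <-
    validation$community_id %in% seeded$summary$community_id
  .write_tsv(validation, fp("validation.tsv"))
  comm_summary <- data.frame(
    community_id = sort(unique(communities$membership)),
    stringsAsFactors = FALSE)
  memb <- communities$membership; side <- communities$side
  comm_summary$n_snps <- vapply(comm_summary$community_id, function(cid)
    sum(memb == cid & side == "snp"), 0L)
  comm_summary$n_genes <- vapply(comm_summary$community_id, function(cid)
    sum(memb == cid & side == "gene"), 0L)
  sub_snps <- gwas$rsID[gwas$p < gwas_thresh]
  comm_summary$n_subthreshold_snps <- vapply(
    comm_summary$community_id, function(cid)
      sum(memb == cid & side == "snp" & names(memb) %in% sub_snps), 0L)
  .write_tsv(comm_summary, fp("community_summary.tsv"))

  # --- provenance -----------------------------------------------------------
  provenance <- list(
    package = "eqtlens",
    version = as.character(packageVersion("eqtlens")),
    seed = as.integer(seed),
    thresholds = list(cis_p = "1e-3", trans_p = "1e-6",
                      gwas_suggestive_p = "1e-4", eqtl_fdr = "5%",
                      cis_p_value = cis_p, trans_p_value = trans_p,
                      gwas_suggestive_value = gwas_thresh,
                      eqtl_fdr_value = cis_fdr),
    cohort = list(n_cases = plan$n_cases, n_controls = plan$n_controls,
                  n_snps = nrow(plan$panel), n_genes = nrow(plan$probes),
                  n_cpgs = nrow(plan$cpgs), n_gwas = plan$n_gwas),
    scan = attr(eqtl, "provenance"),
    enrichment = enrichment,
    n_permutations = n_perm,
    network = network$provenance,
    n_communities = communities$n_communities,
    barber_q = communities$Q,
    files = list.files(out_dir))
  jsonlite::write_json(provenance, fp("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(plan = plan, covariates = covariates, genotypes = gt,
                 expression = expr, phenotype = phen, methylation = meth,
                 gwas = gwas, eqtl = eqtl, intersection = intersection,
                 enrichment = enrichment, perms = perms, scores = scores,
                 network = network, communities = communities,
                 seeded = seeded, de = de, dm = dm, validation = validation,
                 provenance = provenance, out_dir = out_dir))
}
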