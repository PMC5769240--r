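test_that("genotype simulation matches binomial and copying-process oracles", {
  panel <- data.frame(rsID = c("rs1", "rs2"), chrom = "1",
                      pos = c(100L, 200L), maf = 0.3,
                      stringsAsFactors = FALSE)
  # ld_rho = 0: dosages are Binomial(2, maf); empirical MAF within 3 SEs
  gt <- generate_genotypes(panel, 10000, ld_block_size = 2, ld_rho = 0,
                           seed = 11)
  emp <- colMeans(gt$dosage) / 2
  se3 <- 3 * sqrt(0.3 * 0.7 / (2 * 10000))
  expect_true(all(abs(emp - 0.3) < se3))
  expect_true(all(gt$dosage %in% 0:2))

  # strong copying: dosage correlation of a 2-SNP block approaches 1
  gt2 <- generate_genotypes(panel, 5000, ld_block_size = 2, ld_rho = 0.99,
                            seed = 12)
  r2 <- cor(gt2$dosage[, 1], gt2$dosage[, 2])^2
  expect_gt(r2, 0.9)

  # copying preserves marginal frequency
  expect_lt(abs(mean(gt2$dosage[, 2]) / 2 - 0.3), se3 * sqrt(2))
})

test_that("genotype simulation is seed-deterministic and validates inputs", {
  panel <- data.frame(rsID = "rs1", chrom = "1", pos = 1L, maf = 0.2)
  a <- generate_genotypes(panel, 2, seed = 5)
  b <- generate_genotypes(panel, 2, seed = 5)
  expect_identical(a$dosage, b$dosage)
  c <- generate_genotypes(panel, 50, seed = 6)
  expect_false(identical(generate_genotypes(panel, 50, seed = 7)$dosage,
                         c$dosage))
  expect_error(generate_genotypes(panel, 10, ld_block_size = 0), "positive")
  bad <- panel; bad$maf <- 0.6
  expect_error(generate_genotypes(bad, 10), "maf")
  expect_error(generate_genotypes(panel, 1), "n_subjects")
})

test_that("expression is the planted linear genetic signal plus noise", {
  plan <- tiny_plan()
  plan$noise_sd <- 0
  plan$cis_effects <- plan$cis_effects[1, , drop = FALSE]
  plan$cis_effects$beta <- 1
  plan$trans_effects <- plan$trans_effects[0, , drop = FALSE]
  gt <- generate_genotypes(plan$panel, plan$n_subjects, seed = 3)
  expr <- generate_expression(gt, plan, seed = 4)
  probe <- plan$probes$probe_id[plan$probes$gene_symbol ==
                                  plan$cis_effects$gene_symbol]
  # zero noise, beta = 1: expression IS the dosage
  expect_equal(unname(expr[, probe]),
               unname(gt$dosage[, plan$cis_effects$rsID]))
  # genes without effects are exactly zero at noise_sd = 0
  other <- setdiff(colnames(expr), probe)
  expect_true(all(expr[, other] == 0))

  # linearity: two effects on one gene sum exactly
  plan2 <- plan
  plan2$cis_effects <- data.frame(
    rsID = c(plan$cis_effects$rsID, plan$panel$rsID[2]),
    gene_symbol = plan$cis_effects$gene_symbol,
    beta = c(1, 0.5), stringsAsFactors = FALSE)
  expr2 <- generate_expression(gt, plan2, seed = 4)
  expect_equal(unname(expr2[, probe]),
               unname(gt$dosage[, plan2$cis_effects$rsID[1]] +
                        0.5 * gt$dosage[, plan2$cis_effects$rsID[2]]))

  bad <- plan
  bad$cis_effects$rsID <- "rs_missing"
  expect_error(generate_expression(gt, bad), "unknown SNP")
})

test_that("disease phenotype hits the exact case/control quota", {
  plan <- default_plan(n_snps = 50, n_genes = 5, n_cpgs = 5,
                       n_cis_effects = 3, n_trans_effects = 0,
                       n_disease_causal = 2, n_dm_effects = 0)
  gt <- generate_genotypes(plan$panel, plan$n_subjects, seed = 21)
  phen <- generate_disease_phenotype(gt, plan, seed = 22)
  expect_identical(sum(phen$status == 1), 86L)
  expect_identical(sum(phen$status == 0), 31L)

  # null model: status independent of genotype
  plan0 <- plan; plan0$disease_causal <- plan$disease_causal[0, ]
  cors <- replicate(20, {
    ph <- generate_disease_phenotype(gt, plan0)
    cor(gt$dosage[, 1], ph$status)
  })
  expect_lt(abs(mean(cors)), 0.1)

  # large effect at large n: case dosage mean exceeds control mean
  planL <- default_plan(n_cases = 5000, n_controls = 5000, n_snps = 10,
                        n_genes = 2, n_cpgs = 2, n_cis_effects = 1,
                        n_trans_effects = 0, n_disease_causal = 1,
                        disease_log_or = 1.5, n_dm_effects = 0)
  gtL <- generate_genotypes(planL$panel, 10000, seed = 23)
  phL <- generate_disease_phenotype(gtL, planL, seed = 24)
  snp <- planL$disease_causal$rsID[1]
  expect_gt(mean(gtL$dosage[phL$status == 1, snp]),
            mean(gtL$dosage[phL$status == 0, snp]))

  gt_small <- generate_genotypes(plan$panel, 10, seed = 25)
  expect_error(generate_disease_phenotype(gt_small, plan), "quota")
})

test_that("simulated GWAS summaries are null-uniform, powered, and seeded", {
  plan <- default_plan(n_snps = 500, n_genes = 10, n_cpgs = 5,
                       n_cis_effects = 5, n_trans_effects = 0,
                       n_disease_causal = 0, n_dm_effects = 0,
                       ld_rho = 0)
  gw <- generate_gwas_summary(plan$panel, plan, n_gwas = 2000, seed = 31)
  expect_identical(nrow(gw), 500L)
  expect_gt(suppressWarnings(stats::ks.test(gw$p, "punif"))$p.value, 0.01)

  # same seed, identical table
  gw2 <- generate_gwas_summary(plan$panel, plan, n_gwas = 2000, seed = 31)
  expect_identical(gw, gw2)
  expect_error(generate_gwas_summary(plan$panel, plan, n_gwas = 50), "100")

  # a strongly causal SNP clears the suggestive threshold in >90% of reps
  planC <- default_plan(n_snps = 40, n_genes = 4, n_cpgs = 2,
                        n_cis_effects = 2, n_trans_effects = 0,
                        n_disease_causal = 1, disease_log_or = 0.4,
                        n_dm_effects = 0, ld_block_size = 5)
  set.seed(32)
  hits <- replicate(20, {
    g <- generate_gwas_summary(planC$panel, planC, n_gwas = 5000)
    g$p[g$rsID == planC$disease_causal$rsID[1]] < 1e-4
  })
  expect_gte(mean(hits), 0.9)
})

test_that("methylation betas stay in [0,1] and recover planted differences", {
  plan <- tiny_plan()
  gt <- generate_genotypes(plan$panel, plan$n_subjects, seed = 41)
  phen <- generate_disease_phenotype(gt, plan, seed = 42)
  meth <- generate_methylation(phen, plan, seed = 43)
  expect_true(all(meth >= 0 & meth <= 1))

  # planted difference recovered within 3 SEs (Monte-Carlo check)
  cg <- plan$dm_effects$cpg_id[1]
  obs <- mean(meth[phen$status == 1, cg]) - mean(meth[phen$status == 0, cg])
  sd_b <- sd(meth[, cg])
  se3 <- 3 * sd_b * sqrt(1 / sum(phen$status) + 1 / sum(!phen$status))
  expect_lt(abs(obs - plan$dm_effects$diff[1]), se3)

  # zero latent noise: betas sit exactly at the planned group means
  plan0 <- plan; plan0$meth_latent_sd <- 0
  meth0 <- generate_methylation(phen, plan0, seed = 44)
  base <- plan$cpgs$baseline[plan$cpgs$cpg_id == cg]
  expect_equal(unique(meth0[phen$status == 0, cg]), base, tolerance = 1e-9)
  expect_equal(unique(meth0[phen$status == 1, cg]),
               base + plan$dm_effects$diff[1], tolerance = 1e-9)

  # impossible planned mean errors out
  bad <- plan
  bad$dm_effects$diff <- 0.9
  expect_error(generate_methylation(phen, bad), "outside")
})
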