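test_that("cis window rule is boundary-inclusive at 500 kb from the gene", {
  panel <- data.frame(rsID = c("rs_in", "rs_out", "rs_body", "rs_edge"),
                      chrom = "1",
                      pos = c(500001L, 499999L, 1002000L, 500000L),
                      stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = "P1", gene_symbol = "G1", chrom = "1",
                       start = 1000000L, end = 1005000L,
                       stringsAsFactors = FALSE)
  pairs <- assign_cis_pairs(panel, probes)
  mode <- setNames(pairs$mode, pairs$rsID)
  expect_identical(unname(mode["rs_in"]), "cis")    # distance 499,999
  expect_identical(unname(mode["rs_out"]), "trans") # just past the window
  expect_identical(unname(mode["rs_body"]), "cis")  # inside the gene body
  expect_identical(unname(mode["rs_edge"]), "cis")  # exactly at the boundary

  # different chromosome is always trans
  panel2 <- data.frame(rsID = "rs_o", chrom = "2", pos = 1000000L)
  expect_identical(assign_cis_pairs(panel2, probes)$mode, "trans")
  panel_na <- data.frame(rsID = "x", chrom = NA_character_, pos = 1L)
  expect_error(assign_cis_pairs(panel_na, probes), "chromosome")
})

test_that("fit_association reproduces closed-form and normal-equations OLS", {
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0.1, -0.1, 1.1, 0.9, 2.05, 1.95)
  oracle <- simple_ols_oracle(g, y)
  fit <- fit_association(y, g)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-12)
  expect_equal(fit$se, oracle$se, tolerance = 1e-12)
  expect_equal(fit$p, oracle$p, tolerance = 1e-12)

  # with covariates, against an independent normal-equations solver
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 2, 0.3)
    if (var(g) == 0) next
    C <- cbind(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5))
    y <- 0.3 * g + 0.05 * C[, 1] + rnorm(n)
    fit <- fit_association(y, g, cov = as.data.frame(C))
    orc <- normal_eq_oracle(g, y, C)
    expect_equal(fit$beta, unname(orc$beta), tolerance = 1e-8)
    expect_equal(fit$se, unname(orc$se), tolerance = 1e-8)
    expect_equal(fit$p, unname(orc$p), tolerance = 1e-8)
  }
})

test_that("fit_association flags monomorphic dosage, collinearity, perfect fit", {
  y <- rnorm(10)
  expect_error(fit_association(y, rep(1, 10)), "monomorphic")
  g <- rbinom(10, 2, 0.5)
  cov <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(fit_association(y, g, cov), "b")
  # perfect fit: beta = 1, smallest representable p, no exception
  g <- c(0, 1, 2, 0, 1, 2)
  fit <- fit_association(g, g)
  expect_equal(fit$beta, 1)
  expect_identical(fit$p, .Machine$double.xmin)
})

test_that("null association p-values are uniform", {
  set.seed(202)
  p <- replicate(1000, {
    g <- rbinom(30, 2, 0.4)
    while (var(g) == 0) g <- rbinom(30, 2, 0.4)
    fit_association(rnorm(30), g)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("expression PCs are orthogonal, sign-fixed, and size-checked", {
  set.seed(303)
  X <- matrix(rnorm(40 * 15), 40, 15,
              dimnames = list(sprintf("S%02d", 1:40), NULL))
  pcs <- compute_expression_pcs(X, 2)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-8)
  # deterministic sign: recomputation identical even after column flip of input
  expect_identical(pcs, compute_expression_pcs(X, 2))

  # rank-1 matrix: PC1 carries all variance
  R <- outer(rnorm(20), rnorm(5))
  rownames(R) <- sprintf("S%02d", 1:20)
  p1 <- compute_expression_pcs(R, 1)
  expect_equal(sum(apply(R, 2, var)) * 19, sum(p1^2), tolerance = 1e-8)

  expect_identical(ncol(compute_expression_pcs(X, 0)), 0L)
  expect_error(compute_expression_pcs(X, -1), ">= 0")
  expect_error(compute_expression_pcs(X, 15), "min")
})

test_that("bh_fdr follows the step-up rule and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.50)), c(0.04, 0.04, 0.04, 0.50))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("run_scan recovers a planted signal and keeps honest bookkeeping", {
  plan <- tiny_plan()
  plan$noise_sd <- 0
  plan$cis_effects <- plan$cis_effects[1, , drop = FALSE]
  plan$trans_effects <- plan$trans_effects[0, , drop = FALSE]
  set.seed(404)
  gt <- generate_genotypes(plan$panel, plan$n_subjects,
                           plan$ld_block_size, ld_rho = 0)
  expr <- generate_expression(gt, plan)
  # some pure-noise genes have zero variance at noise_sd = 0: add tiny noise
  expr <- expr + matrix(rnorm(length(expr), 0, 1e-6), nrow(expr))
  tab <- run_scan(gt, expr, plan$probes, n_expr_pcs = 0)
  # the planted pair ranks p-minimum
  expect_identical(tab$rsID[1], plan$cis_effects$rsID[1])
  expect_identical(tab$gene_symbol[1], plan$cis_effects$gene_symbol[1])
  prov <- attr(tab, "provenance")
  expect_identical(prov$n_tests_cis + prov$n_tests_trans, nrow(tab))
  expect_true(all(tab$q >= 0 & tab$q <= 1))

  # 1 SNP x 1 gene scan yields exactly one record
  g1 <- list(dosage = gt$dosage[, 1, drop = FALSE],
             panel = plan$panel[1, , drop = FALSE])
  class(g1) <- "genotype_matrix"
  t1 <- run_scan(g1, expr[, 1, drop = FALSE],
                 plan$probes[1, , drop = FALSE], n_expr_pcs = 0)
  expect_identical(nrow(t1), 1L)
})

test_that("scan results are invariant under a joint subject permutation", {
  plan <- tiny_plan()
  set.seed(505)
  gt <- generate_genotypes(plan$panel, plan$n_subjects, plan$ld_block_size,
                           plan$ld_rho)
  cov <- generate_covariates(plan$n_subjects)
  expr <- generate_expression(gt, plan, cov)
  tab <- run_scan(gt, expr, plan$probes, cov, n_expr_pcs = 3)
  perm <- sample(plan$n_subjects)
  gtp <- gt
  gtp$dosage <- gt$dosage[perm, ]
  covp <- cov[perm, ]
  tabp <- run_scan(gtp, expr[perm, ], plan$probes, covp, n_expr_pcs = 3)
  key <- paste(tab$rsID, tab$probe_id)
  keyp <- paste(tabp$rsID, tabp$probe_id)
  expect_equal(tab$p, tabp$p[match(key, keyp)], tolerance = 1e-9)

  # misaligned subjects must error
  expect_error(run_scan(gtp, expr, plan$probes, cov), "subject")
})
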