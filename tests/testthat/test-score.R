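test_that("p-to-z transform matches inverse-normal quantiles without overflow", {
  expect_equal(zscore_from_p(1), 0)
  expect_equal(zscore_from_p(0.05), 1.959964, tolerance = 1e-6)
  z8 <- zscore_from_p(1e-8)
  expect_equal(z8, qnorm(1 - 1e-8 / 2), tolerance = 1e-6)
  # far beyond double underflow of 1 - p/2: still finite and increasing
  expect_true(is.finite(zscore_from_p(1e-300)))
  expect_gt(zscore_from_p(1e-300), zscore_from_p(1e-100))
  expect_error(zscore_from_p(0), "\\(0, 1\\]")
})

test_that("Wakefield LBF has the closed form and the right limits", {
  expect_equal(wakefield_lbf(3, W = 0), 0)
  expect_equal(wakefield_lbf(0, W = 0), 0)
  expect_equal(wakefield_lbf(0, V = 1, W = 0.1), 0.5 * log10(1 / 1.1),
               tolerance = 1e-12)
  # direct formula evaluation at z = 3, V = 1, W = 0.21
  z <- 3; V <- 1; W <- 0.21
  direct <- log10(sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W))))
  expect_equal(wakefield_lbf(z, V, W), direct, tolerance = 1e-12)
  # unsupported z penalizes, strong z rewards
  expect_lt(wakefield_lbf(0), 0)
  expect_gt(wakefield_lbf(6), 0)
  expect_error(wakefield_lbf(1, V = 0), "V")
  expect_error(wakefield_lbf(1, W = -1), "W")
})

test_that("distance pruning keeps the best eSNP per window, per chromosome", {
  esnps <- data.frame(rsID = c("a", "b", "c"),
                      chrom = c("1", "1", "2"),
                      pos = c(1000L, 2000L, 1500L),
                      p = c(1e-5, 1e-7, 1e-3), stringsAsFactors = FALSE)
  kept <- prune_esnps(esnps, window_bp = 1e5)
  # b beats a within the window; c survives on its own chromosome
  expect_setequal(kept$rsID, c("b", "c"))

  # random instances: no two kept eSNPs violate the window (pairwise oracle)
  set.seed(909)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    df <- data.frame(rsID = sprintf("r%02d", 1:n),
                     chrom = sample(c("1", "2"), n, replace = TRUE),
                     pos = sample.int(5e6, n),
                     p = runif(n), stringsAsFactors = FALSE)
    k <- prune_esnps(df, window_bp = 1e6)
    if (nrow(k) > 1) {
      pairs <- utils::combn(nrow(k), 2)
      viol <- apply(pairs, 2, function(ij)
        k$chrom[ij[1]] == k$chrom[ij[2]] &&
          abs(k$pos[ij[1]] - k$pos[ij[2]]) <= 1e6)
      expect_false(any(viol))
    }
    # every dropped record is blocked by a kept, smaller-p record
    dropped <- df[!df$rsID %in% k$rsID, ]
    for (i in seq_len(nrow(dropped))) {
      blockers <- k[k$chrom == dropped$chrom[i] &
                      abs(k$pos - dropped$pos[i]) <= 1e6, ]
      expect_true(any(blockers$p <= dropped$p[i]))
    }
  }
})

make_eqtl <- function(rsID, gene, p, mode = "cis") {
  data.frame(rsID = rsID, probe_id = paste0(gene, "_p"), gene_symbol = gene,
             p = p, q = p, mode = mode, stringsAsFactors = FALSE)
}
make_gwas <- function(rsID, p) {
  data.frame(rsID = rsID, chrom = "1",
             pos = seq_along(rsID) * 2e6, p = p, stringsAsFactors = FALSE)
}

test_that("gene scores sum per-eSNP LBFs and respect the thresholds", {
  cfg <- score_config()
  eqtl <- rbind(
    make_eqtl(c("rs1", "rs2"), "G1", c(1e-5, 1e-4)),
    make_eqtl("rs3", "G2", 1e-4, mode = "trans"),   # fails trans 1e-6
    make_eqtl("rs4", "G3", 1e-5))                   # absent from GWAS
  gwas <- make_gwas(c("rs1", "rs2", "rs3"), c(1e-6, 0.3, 1e-8))
  sc <- score_gene("G1", eqtl, gwas, cfg)
  expect_equal(sc$total_lbf, sum(sc$contributions$lbf), tolerance = 1e-10)
  expect_equal(sort(sc$contributions$rsID), c("rs1", "rs2"))
  manual <- sum(wakefield_lbf(zscore_from_p(c(1e-6, 0.3)), cfg$V, cfg$W))
  expect_equal(sc$total_lbf, manual, tolerance = 1e-10)
  # singleton sum for a one-eSNP gene
  expect_null(score_gene("G2", eqtl, gwas, cfg))  # trans fails its threshold
  expect_null(score_gene("G3", eqtl, gwas, cfg))  # eSNP not in GWAS

  tab <- score_genes(eqtl, gwas, cfg)
  expect_identical(tab$gene_symbol, "G1")
  expect_identical(attr(tab, "n_genes_skipped"), 2L)
  # threshold bookkeeping: every contribution satisfies its mode's cutoff
  contr <- attr(tab, "contributions")$G1
  expect_true(all((contr$mode == "cis" & contr$eqtl_p < cfg$cis_p) |
                    (contr$mode == "trans" & contr$eqtl_p < cfg$trans_p)))

  # 4.0 convention flag
  eqtl4 <- make_eqtl(c("rs1", "rs3"), "G9", c(1e-5, 1e-6))
  tab4 <- score_genes(eqtl4, make_gwas(c("rs1", "rs3"), c(1e-15, 1e-15)), cfg)
  expect_true(tab4$total_lbf > 4 && tab4$significant_by_convention)
})

test_that("total LBF is order-invariant and monotone in GWAS evidence", {
  cfg <- score_config()
  eqtl <- make_eqtl(c("rs1", "rs2", "rs3"), "G1", c(1e-5, 2e-5, 3e-5))
  gwas <- make_gwas(c("rs1", "rs2", "rs3"), c(0.01, 0.2, 0.6))
  base <- score_gene("G1", eqtl, gwas, cfg)$total_lbf
  shuf <- score_gene("G1", eqtl[c(3, 1, 2), ], gwas[c(2, 3, 1), ], cfg)
  expect_equal(shuf$total_lbf, base, tolerance = 1e-12)
  # decreasing one eSNP's GWAS p never decreases the total
  gwas2 <- gwas; gwas2$p[2] <- 1e-6
  expect_gte(score_gene("G1", eqtl, gwas2, cfg)$total_lbf, base)
})

test_that("empirical p-values hit the add-one bounds", {
  cfg <- score_config()
  eqtl <- make_eqtl("rs1", "G1", 1e-6)
  obs_gwas <- make_gwas("rs1", 1e-10)
  observed <- score_genes(eqtl, obs_gwas, cfg)
  # 999 permutations with no GWAS support: observed exceeds every null
  nulls <- lapply(seq_len(999), function(i) make_gwas("rs1", 1))
  names(nulls) <- sprintf("perm_%03d", seq_along(nulls))
  withp <- empirical_p(observed, nulls, eqtl, cfg)
  expect_equal(withp$empirical_p, 1 / 1000)
  # observed below every null
  observed_lo <- score_genes(eqtl, make_gwas("rs1", 1), cfg)
  nulls_hi <- lapply(seq_len(99), function(i) make_gwas("rs1", 1e-10))
  withp_lo <- empirical_p(observed_lo, nulls_hi, eqtl, cfg)
  expect_equal(withp_lo$empirical_p, 1.0)
  expect_error(empirical_p(observed, list(), eqtl, cfg), "one permutation")

  # per-gene pooling agrees on a single-gene problem
  pg <- empirical_p(observed, nulls, eqtl, cfg, pooling = "per_gene")
  expect_equal(pg$empirical_p, 1 / 1000)
})
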