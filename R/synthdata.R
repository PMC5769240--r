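.subject_ids <- function(n) sprintf("S%04d", seq_len(n))

.set_seed_if <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

# Haplotype-copying simulator: within an LD block the allele at each SNP is
# copied from the previous SNP of the same haplotype with probability rho,
# otherwise drawn fresh at the SNP's MAF. Copying a Bernoulli(maf) allele
# preserves the marginal frequency, so empirical MAF converges to the panel
# value regardless of rho. Block boundaries (and chromosome changes) always
# draw fresh.
.sim_haplotypes <- function(n_hap, panel, block_size, rho) {
  S <- nrow(panel)
  h <- matrix(0L, n_hap, S)
  idx_in_chrom <- stats::ave(seq_len(S), panel$chrom, FUN = seq_along)
  fresh_start <- ((idx_in_chrom - 1L) %% block_size) == 0L
  for (j in seq_len(S)) {
    new <- rbinom(n_hap, 1L, panel$maf[j])
    if (fresh_start[j] || rho == 0) {
      h[, j] <- new
    } else {
      copy <- runif(n_hap) < rho
      h[, j] <- ifelse(copy, h[, j - 1L], new)
    }
  }
  h
}

#' Simulate LD-blocked genotype dosages
#'
#' Two haplotypes per subject are simulated under a block-wise
#' haplotype-copying model and summed to a dosage in {0, 1, 2}. Within a block
#' of \code{ld_block_size} SNPs, each haplotype allele copies its left
#' neighbour with probability \code{ld_rho} and is otherwise drawn fresh at
#' that SNP's minor-allele frequency, which yields tunable within-block
#' r-squared while preserving marginal allele frequencies.
#'
#' @param panel SNP panel data frame with columns \code{rsID}, \code{chrom},
#'   \code{pos}, \code{maf} (MAF in (0, 0.5]).
#' @param n_subjects Number of subjects (>= 2).
#' @param ld_block_size SNPs per LD block (positive).
#' @param ld_rho Copying probability in [0, 1).
#' @param seed Optional integer seed.
#' @return A \code{genotype_matrix}: list with \code{dosage} (subjects x SNPs
#'   integer matrix, dimnames set) and \code{panel}.
#' @examples
#' panel <- default_plan(n_snps = 10, n_genes = 2, n_cpgs = 2)$panel
#' gt <- generate_genotypes(panel, 50, ld_block_size = 5, ld_rho = 0.9, seed = 1)
#' dim(gt$dosage)
#' @export
generate_genotypes <- function(panel, n_subjects, ld_block_size = 10,
                               ld_rho = 0, seed = NULL) {
  if (ld_block_size <= 0) .stopf("ld_block_size must be positive")
  if (any(panel$maf <= 0 | panel$maf > 0.5)) .stopf("maf outside (0, 0.5]")
  if (n_subjects < 2) .stopf("n_subjects must be >= 2")
  if (nrow(panel) < 1) .stopf("panel is empty")
  .set_seed_if(seed)
  dos <- .sim_haplotypes(n_subjects, panel, ld_block_size, ld_rho) +
    .sim_haplotypes(n_subjects, panel, ld_block_size, ld_rho)
  dimnames(dos) <- list(.subject_ids(n_subjects), panel$rsID)
  structure(list(dosage = dos, panel = panel), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$panel$chrom), collapse = ", ")))
  invisible(x)
}

#' Simulate subject covariates
#'
#' Age, sex, pack-years of smoking and ancestry principal components, the
#' covariates a tissue eQTL scan in a smoking-related disease cohort adjusts
#' for. Values are draws from plausible marginal distributions; they carry no
#' built-in association with genotype or expression.
#'
#' @param n_subjects Number of subjects.
#' @param n_ancestry_pcs Number of ancestry PC columns.
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{subject}, \code{age}, \code{sex},
#'   \code{pack_years}, \code{ancestry_pc1}, ...
#' @export
generate_covariates <- function(n_subjects, n_ancestry_pcs = 2, seed = NULL) {
  .set_seed_if(seed)
  cov <- data.frame(
    subject = .subject_ids(n_subjects),
    age = round(rnorm(n_subjects, 65, 8), 1),
    sex = rbinom(n_subjects, 1L, 0.55),
    pack_years = round(pmax(0, rnorm(n_subjects, 45, 25)), 1),
    stringsAsFactors = FALSE)
  for (k in seq_len(n_ancestry_pcs))
    cov[[paste0("ancestry_pc", k)]] <- rnorm(n_subjects)
  cov
}

#' Simulate expression with planted cis/trans eQTLs
#'
#' Each probe's expression is the sum of its planted genotype effects
#' (\code{beta} expression units per allele of the named SNP), optional
#' covariate terms, and Gaussian noise with SD \code{plan$noise_sd}. Probes of
#' genes without planted effects are covariates-plus-noise only. Disease
#' status never enters directly: any case-control expression difference arises
#' through genotype, as in a cohort where liability is genotype-driven.
#'
#' @param gt A \code{genotype_matrix}.
#' @param plan A \code{sim_plan} supplying probe annotation and effects.
#' @param covariates Optional covariate table; used only when
#'   \code{covariate_coefs} is non-zero.
#' @param covariate_coefs Named numeric vector of coefficients on covariate
#'   columns (default: none), for studies that want confounded expression.
#' @param seed Optional integer seed.
#' @return Subjects x probes numeric matrix with dimnames.
#' @export
generate_expression <- function(gt, plan, covariates = NULL,
                                covariate_coefs = NULL, seed = NULL) {
  .set_seed_if(seed)
  n <- nrow(gt$dosage)
  probes <- plan$probes
  eff <- rbind(plan$cis_effects, plan$trans_effects)
  if (nrow(eff)) {
    if (!all(eff$rsID %in% colnames(gt$dosage)))
      .stopf("effect references unknown SNP: %s",
             setdiff(eff$rsID, colnames(gt$dosage))[1])
    if (!all(eff$gene_symbol %in% probes$gene_symbol))
      .stopf("effect references unknown gene: %s",
             setdiff(eff$gene_symbol, probes$gene_symbol)[1])
  }
  expr <- matrix(rnorm(n * nrow(probes), 0, plan$noise_sd), n, nrow(probes),
                 dimnames = list(rownames(gt$dosage), probes$probe_id))
  for (i in seq_len(nrow(eff))) {
    cols <- which(probes$gene_symbol == eff$gene_symbol[i])
    expr[, cols] <- expr[, cols] + eff$beta[i] * gt$dosage[, eff$rsID[i]]
  }
  if (!is.null(covariate_coefs) && length(covariate_coefs)) {
    stopifnot(!is.null(covariates),
              all(names(covariate_coefs) %in% names(covariates)))
    part <- as.matrix(covariates[names(covariate_coefs)]) %*% covariate_coefs
    expr <- expr + as.vector(part)
  }
  expr
}

#' Simulate a case-control phenotype from a logistic liability model
#'
#' Liability is the dosage-weighted sum of the plan's per-allele log odds; the
#' intercept is tuned by bisection so the expected case count matches
#' \code{plan$n_cases}. Statuses are drawn from the tuned model, then the exact
#' quota is enforced: surplus cases are demoted uniformly at random, missing
#' cases are promoted from controls with probability proportional to their
#' model odds.
#'
#' @param gt A \code{genotype_matrix} for the cohort.
#' @param plan A \code{sim_plan} (uses \code{disease_causal}, quotas).
#' @param seed Optional integer seed.
#' @return Data frame \code{subject}, \code{status} (case = 1, control = 0)
#'   with exactly \code{n_cases} ones.
#' @export
generate_disease_phenotype <- function(gt, plan, seed = NULL) {
  .set_seed_if(seed)
  n <- nrow(gt$dosage)
  n_cases <- plan$n_cases; n_controls <- plan$n_controls
  if (n_cases + n_controls != n)
    .stopf("plan quota (%d + %d) does not match %d subjects",
           n_cases, n_controls, n)
  dc <- plan$disease_causal
  if (nrow(dc) && !all(dc$rsID %in% colnames(gt$dosage)))
    .stopf("disease_causal references SNPs absent from genotypes")
  eta <- if (nrow(dc)) as.vector(gt$dosage[, dc$rsID, drop = FALSE] %*%
                                   dc$log_odds) else rep(0, n)
  f <- function(b0) sum(plogis(b0 + eta)) - n_cases
  b0 <- uniroot(f, c(-50, 50))$root
  pr <- plogis(b0 + eta)
  status <- rbinom(n, 1L, pr)
  excess <- sum(status) - n_cases
  if (excess > 0) {
    status[sample(which(status == 1L), excess)] <- 0L
  } else if (excess < 0) {
    pool <- which(status == 0L)
    status[sample(pool, -excess, prob = pr[pool] / (1 - pr[pool]))] <- 1L
  }
  data.frame(subject = rownames(gt$dosage), status = status,
             stringsAsFactors = FALSE)
}

# Allelic trend test of dosage vs a binary status: the dosage-status
# correlation referred to a t distribution on n - 2 df (the regression form
# of the Armitage trend test). Better tail calibration at modest n than the
# asymptotic chi-square form. Monomorphic SNPs get p = 1 with a flag rather
# than an error.
.assoc_score_test <- function(dosage, status) {
  n <- nrow(dosage)
  yc <- status - mean(status)
  gc <- sweep(dosage, 2, colMeans(dosage))
  sxx <- colSums(gc^2)
  mono <- sxx <= 0 | sum(yc^2) <= 0
  r2 <- rep(0, ncol(dosage))
  ok <- !mono
  r2[ok] <- (crossprod(gc[, ok, drop = FALSE], yc)[, 1])^2 /
    (sxx[ok] * sum(yc^2))
  r2 <- pmin(r2, 1)
  tstat <- sqrt(r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- .clamp_p(2 * pt(tstat, df = n - 2, lower.tail = FALSE))
  p[mono] <- 1
  list(p = p, monomorphic = mono)
}

#' Simulate GWAS summary statistics from an independent cohort
#'
#' Draws a fresh cohort of \code{n_gwas} subjects from the same SNP panel and
#' disease model as the study cohort (cases and controls balanced, as in a
#' typical external case-control GWAS), then computes per-SNP two-sided
#' association p-values with an allelic trend test: the dosage-status
#' correlation referred to a t distribution on n - 2 degrees of freedom (the
#' regression form of the Armitage trend test; better tail calibration at
#' modest n than the asymptotic chi-square form). SNPs monomorphic in the
#' simulated cohort receive p = 1 and a \code{monomorphic} flag.
#'
#' @param panel SNP panel (as in \code{\link{generate_genotypes}}).
#' @param plan A \code{sim_plan} (LD parameters and disease model).
#' @param n_gwas GWAS cohort size (>= 100).
#' @param seed Optional integer seed.
#' @return A GWAS summary data frame: \code{rsID}, \code{chrom}, \code{pos},
#'   \code{p}, \code{monomorphic}.
#' @export
generate_gwas_summary <- function(panel, plan, n_gwas = plan$n_gwas,
                                  seed = NULL) {
  if (n_gwas < 100) .stopf("n_gwas must be >= 100")
  .set_seed_if(seed)
  gt <- generate_genotypes(panel, n_gwas, plan$ld_block_size, plan$ld_rho)
  n_cases <- n_gwas %/% 2L
  gplan <- plan
  gplan$n_cases <- n_cases
  gplan$n_controls <- as.integer(n_gwas - n_cases)
  phen <- generate_disease_phenotype(gt, gplan)
  res <- .assoc_score_test(gt$dosage, phen$status)
  data.frame(rsID = panel$rsID, chrom = panel$chrom, pos = panel$pos,
             p = res$p, monomorphic = res$monomorphic,
             stringsAsFactors = FALSE)
}

# Expected value of plogis(mu + sd * Z), Z ~ N(0,1), by fixed-grid quadrature.
.eplogis <- function(mu, sd) {
  if (sd == 0) return(plogis(mu))
  z <- seq(-8, 8, length.out = 321)
  w <- dnorm(z); w <- w / sum(w)
  sum(w * plogis(mu + sd * z))
}

# Latent mean giving a target expected beta under the logistic transform.
.latent_mean_for <- function(target, sd) {
  if (sd == 0) return(qlogis(pmin(pmax(target, 1e-12), 1 - 1e-12)))
  uniroot(function(mu) .eplogis(mu, sd) - target, c(-40, 40))$root
}

#' Simulate methylation beta values with case-control shifts
#'
#' Beta values are the logistic transform of a Gaussian latent variable, which
#' keeps them inside [0, 1]. For each CpG the control-group latent mean is
#' calibrated (by solving for the latent mean whose transformed expectation
#' hits the target) so that the expected beta equals the plan's baseline, and
#' the case-group mean equals baseline plus the planted difference; planted
#' mean differences are therefore recovered up to sampling error, and with
#' zero latent noise betas sit exactly at the planned means.
#'
#' @param phen Phenotype data frame (\code{subject}, \code{status}).
#' @param plan A \code{sim_plan} (uses \code{cpgs}, \code{dm_effects},
#'   \code{meth_latent_sd}).
#' @param seed Optional integer seed.
#' @return Subjects x CpGs matrix of beta values in [0, 1].
#' @export
generate_methylation <- function(phen, plan, seed = NULL) {
  .set_seed_if(seed)
  cpgs <- plan$cpgs
  if (!all(plan$dm_effects$cpg_id %in% cpgs$cpg_id))
    .stopf("dm_effects reference unknown CpGs")
  diff <- setNames(rep(0, nrow(cpgs)), cpgs$cpg_id)
  diff[plan$dm_effects$cpg_id] <- plan$dm_effects$diff
  ctrl_mean <- cpgs$baseline
  case_mean <- cpgs$baseline + diff
  if (any(case_mean < 0 | case_mean > 1 | ctrl_mean < 0 | ctrl_mean > 1))
    .stopf("planned difference pushes a group mean outside [0, 1]")
  sdl <- plan$meth_latent_sd
  mu_ctrl <- vapply(ctrl_mean, .latent_mean_for, 0, sd = sdl)
  mu_case <- vapply(case_mean, .latent_mean_for, 0, sd = sdl)
  n <- nrow(phen)
  lat <- matrix(rnorm(n * nrow(cpgs), 0, sdl), n, nrow(cpgs))
  mu <- outer(phen$status, mu_case) + outer(1 - phen$status, mu_ctrl)
  beta <- plogis(mu + lat)
  dimnames(beta) <- list(phen$subject, cpgs$cpg_id)
  beta
}
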