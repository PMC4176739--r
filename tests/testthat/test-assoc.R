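test_that("null REML matches a brute-force likelihood oracle at small n", {
  set.seed(101)
  n <- 150
  Z <- matrix(rbinom(n * 80, 2, 0.4), n)
  G <- compute_grm(Z)
  Gs <- G / mean(diag(G))
  u <- sqrt(0.5) * drop(crossprod(chol(Gs + diag(1e-8, n)), rnorm(n)))
  pheno <- tibble::tibble(animal_id = paste0("a", 1:n),
                          group = rep(c("g1", "g2"), length.out = n),
                          y = 1 + u + rnorm(n, sd = sqrt(0.5)))
  fit <- fit_null_model(pheno, "group", G)

  # independent oracle: direct REML over (log sg, log se) with dense solves
  X <- stats::model.matrix(~group, pheno)
  reml_direct <- function(par) {
    V <- exp(par[1]) * Gs + exp(par[2]) * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% pheno$y)
    r <- pheno$y - X %*% beta
    0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
             t(r) %*% Vi %*% r)[1]
  }
  opt <- stats::optim(c(0, 0), reml_direct, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$sigma_g, exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(fit$sigma_e, exp(opt$par[2]), tolerance = 1e-3)
})

test_that("variance components behave at the boundaries and under scaling", {
  set.seed(102)
  n <- 800
  Z <- matrix(rbinom(n * 300, 2, runif(300, 0.1, 0.9)), n)
  G <- compute_grm(Z)
  pheno <- tibble::tibble(animal_id = paste0("a", 1:n),
                          group = "g", y = rnorm(n))
  # pure noise: essentially no polygenic variance
  fit0 <- fit_null_model(pheno, character(0), G)
  expect_lt(fit0$h2, 0.05)

  # doubling y multiplies both variance components by four
  pheno2 <- dplyr::mutate(pheno, y = 2 * y)
  fit2 <- fit_null_model(pheno2, character(0), G)
  expect_equal(fit2$sigma_g + fit2$sigma_e, 4 * (fit0$sigma_g + fit0$sigma_e),
               tolerance = 1e-6)
  expect_equal(fit2$delta, fit0$delta, tolerance = 1e-4)

  expect_error(fit_null_model(dplyr::mutate(pheno, y = 1), grm = G), "variance")
  expect_error(fit_null_model(pheno, character(0), G - 2 * diag(n)),
               "positive semi-definite")

  # broom-style accessors
  expect_identical(names(glance(fit0)),
                   c("n", "sigma_g", "sigma_e", "h2", "loglik_reml"))
  expect_identical(tidy(fit0)$term, "(Intercept)")
})

test_that("heritability is recovered across simulation replicates", {
  h2_hat <- vapply(1:8, function(i) {
    sim <- quick_sim(seed = 200 + i, h2 = 0.4, n_t = 500, n_i = 500,
                     n_c = 0, n_chr = 1, m = 300)
    fit_null_model(sim$phenotypes, "group", sim$grm)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.4), 0.05)
})

test_that("with no polygenic term the SNP test equals the OLS oracle", {
  sim <- quick_sim(seed = 111, h2 = 0,
                   qtl = qtl_spec(1, 150, "shared_same_phase", 0.4),
                   n_t = 300, n_i = 300, n_c = 200, n_chr = 1, m = 300)
  ao <- classify_sim(sim)
  null_fit <- fit_null_model(sim$phenotypes, "group", grm = NULL)
  des <- build_design(ao, 150, "conventional",
                      covariates = covmx <- stats::model.matrix(
                        ~group, sim$phenotypes)[, -1, drop = FALSE])
  res <- test_snp(null_fit, des)

  # closed-form GLS oracle with the same known residual variance
  X <- cbind(1, covmx, snp = origwas:::contrast_counts(ao)$x1[, 150])
  XtXi <- solve(crossprod(X))
  bh <- drop(XtXi %*% crossprod(X, sim$phenotypes$y))
  se <- sqrt(diag(XtXi) * null_fit$sigma_e)
  expect_equal(res$estimate, unname(bh[length(bh)]), tolerance = 1e-8)
  expect_equal(res$se, unname(se[length(se)]), tolerance = 1e-8)
  z <- unname(bh[length(bh)] / se[length(se)])
  expect_equal(res$p_value, pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("null SNPs give approximately uniform p-values", {
  # iid sites so SNPs are independent for the KS check
  sim <- quick_sim(seed = 112, h2 = 0, n_t = 300, n_i = 300, n_c = 0,
                   n_chr = 1, m = 1000, n_templates = NULL)
  ao <- classify_sim(sim)
  res <- run_conventional_gwas(ao, sim$phenotypes)
  p <- res$p_value[!is.na(res$p_value)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a tagged QTL effect is recovered within sampling error", {
  sim <- quick_sim(seed = 113, h2 = 0.3,
                   qtl = qtl_spec(1, 150, "shared_same_phase", 0.5,
                                  mutant_freq = 0.4),
                   n_t = 700, n_i = 700, n_c = 600, n_chr = 1, m = 300)
  ao <- classify_sim(sim)
  res <- run_conventional_gwas(ao, sim$phenotypes, grm = sim$grm,
                               snp_subset = 150)
  expect_lt(abs(res$estimate - 0.5), 3 * res$se)
})

test_that("subset scans reflect where a one-subspecies QTL segregates", {
  sim <- quick_sim(seed = 114, h2 = 0,
                   qtl = qtl_spec(1, 150, "taurus_only", 0.6, mutant_freq = 0.5),
                   n_t = 500, n_i = 500, n_c = 800, n_chr = 1, m = 300,
                   admix_proportion = 0.5)
  ao <- classify_sim(sim)
  p_at <- function(subset) {
    run_conventional_gwas(ao, sim$phenotypes, subset = subset,
                          snp_subset = 150)$p_value
  }
  expect_lt(p_at("taurus"), 1e-4)
  expect_lt(p_at("composite"), 1e-2)
  p_ind <- p_at("indicus")
  expect_true(is.na(p_ind) || p_ind > 1e-3)
  expect_error(run_conventional_gwas(ao, sim$phenotypes, subset = "zebu"))
})

test_that("interaction scan separates phase-reversed and one-sided QTL", {
  sim <- quick_sim(seed = 115, h2 = 0,
                   qtl = dplyr::bind_rows(
                     qtl_spec(1, 150, "shared_reversed_phase", 0.45),
                     qtl_spec(2, 150, "taurus_only", 0.45, mutant_freq = 0.5)),
                   n_t = 600, n_i = 600, n_c = 500, n_chr = 2, m = 300)
  ao <- classify_sim(sim)
  res <- run_interaction_gwas(ao, sim$phenotypes, snp_subset = c(150, 450))

  rev_ <- res[res$snp_id == "chr1_snp150", ]
  expect_lt(rev_$p_value[rev_$term == "x3"], 1e-6)
  expect_gt(rev_$p_value[rev_$term == "x1"],
            rev_$p_value[rev_$term == "x3"])

  tau <- res[res$snp_id == "chr2_snp150", ]
  expect_lt(tau$p_value[tau$term == "x6"], 1e-6)
  # the indicine pool is fixed at this site, so the within-indicine allele
  # contrast is either untestable (dropped) or null
  p_x7 <- tau$p_value[tau$term == "x7"]
  expect_true(length(p_x7) == 0 || p_x7 > 1e-3)

  # both parameterisations give the same joint statistic
  jt <- dplyr::distinct(res, snp_id, joint_stat, joint_stat_reparam)
  expect_equal(jt$joint_stat, jt$joint_stat_reparam, tolerance = 1e-8)
})

test_that("best-variable scan finds the causal contrast and reports freqs", {
  sim <- quick_sim(seed = 116, h2 = 0,
                   qtl = qtl_spec(1, 150, "indicus_only", 0.7, mutant_freq = 0.5,
                                  mutant_allele = "B"),
                   n_t = 600, n_i = 600, n_c = 500, n_chr = 1, m = 300)
  ao <- classify_sim(sim)
  res <- run_best_variable_gwas(ao, sim$phenotypes, snp_subset = 145:155)
  at_qtl <- res[res$snp_id == "chr1_snp150", ]
  expect_identical(at_qtl$best_variable, "x7")
  expect_true(all(res$freq_B_all >= 0 & res$freq_B_all <= 1, na.rm = TRUE))
  # within-origin B frequencies track the founder pools' at the QTL site
  expect_lt(abs(at_qtl$freq_B_indicine - 0.5), 0.1)
  expect_lt(abs(at_qtl$freq_B_taurine - sim$freqs$p_taurus[150]), 0.1)

  # smoke property under the null: no crash, p-values present and in (0,1]
  null_res <- run_best_variable_gwas(ao, sim$phenotypes, snp_subset = 10:20)
  expect_true(all(is.na(null_res$p_value) |
                    (null_res$p_value > 0 & null_res$p_value <= 1)))
})

test_that("monomorphic SNPs are flagged untestable, not errors", {
  sim <- quick_sim(seed = 117, h2 = 0, n_t = 80, n_i = 80, n_c = 40,
                   n_chr = 1, m = 90)
  ao <- classify_sim(sim)
  ao$panel$haps[, 5] <- 0L   # force monomorphic
  res <- run_conventional_gwas(ao, sim$phenotypes, snp_subset = 5)
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  null_fit <- fit_null_model(sim$phenotypes, "group")
  des <- build_design(ao, 5, "conventional")
  expect_true(des$untestable)
  out <- test_snp(null_fit, des)
  expect_true(attr(out, "untestable"))
})
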