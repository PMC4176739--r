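test_that("founder differentiation matches the Balding-Nichols parameter", {
  set.seed(11)
  # Hudson-style ratio-of-means estimator from the two drawn frequency
  # vectors: mean (p1-p2)^2 / mean (p1 q2 + p2 q1); expectation F.
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 10000,
                    divergence_fst = 0.5, fixed_diff_fraction = 0,
                    ancestral_freq_range = c(0.5, 0.5), seed = 11)
  fr <- simulate_founder_frequencies(cfg)
  num <- mean((fr$p_taurus - fr$p_indicus)^2)
  den <- mean(fr$p_taurus * (1 - fr$p_indicus) + fr$p_indicus * (1 - fr$p_taurus))
  expect_equal(num / den, 0.5, tolerance = 0.02)

  # weak-divergence limit: pool frequencies collapse onto the ancestral one
  cfg_lo <- sim_config(n_chromosomes = 1, snps_per_chromosome = 5000,
                       divergence_fst = 0.001, fixed_diff_fraction = 0, seed = 12)
  fr_lo <- simulate_founder_frequencies(cfg_lo)
  expect_lt(mean(abs(fr_lo$p_taurus - fr_lo$p_indicus)), 0.05)
  expect_lt(mean(abs(fr_lo$p_taurus - fr_lo$p_indicus)),
            mean(abs(fr$p_taurus - fr$p_indicus)))
})

test_that("degenerate divergence and bad fractions are rejected", {
  expect_error(sim_config(divergence_fst = 0), "divergence_fst")
  expect_error(sim_config(divergence_fst = 1), "divergence_fst")
  expect_error(qtl_spec(1, 1, "taurus_only", 0.5, mutant_freq = 0), "mutant_freq")
})

test_that("QTL sites override founder frequencies per segregation mode", {
  q <- dplyr::bind_rows(
    qtl_spec(1, 10, "fixed_difference", 0.3),
    qtl_spec(1, 20, "taurus_only", 0.3, mutant_freq = 0.4, mutant_allele = "B"),
    qtl_spec(1, 30, "indicus_only", 0.3, mutant_freq = 0.4, mutant_allele = "A"),
    qtl_spec(1, 40, "shared_reversed_phase", 0.3, mutant_freq = 0.3)
  )
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 50,
                    qtl_specs = q, seed = 3)
  set.seed(3)
  fr <- simulate_founder_frequencies(cfg)
  expect_identical(c(fr$p_taurus[10], fr$p_indicus[10]), c(0, 1))
  # one-subspecies modes pin the marker frequency only where the causal
  # class segregates; the other pool's frequency stays a free draw
  expect_equal(fr$p_taurus[20], 0.4)
  expect_true(fr$p_indicus[20] >= 0 && fr$p_indicus[20] <= 1)
  # mutant A at 0.4 in indicus means B frequency 0.6 there
  expect_equal(fr$p_indicus[30], 0.6)
  expect_equal(c(fr$p_taurus[40], fr$p_indicus[40]), c(0.3, 0.7))
})

test_that("pure haplotypes reproduce input frequencies (iid mode)", {
  fr <- toy_freqs(c(0, 0.3, 1, 0.5))
  set.seed(21)
  panel <- simulate_pure_haplotypes(fr, n_animals = 5000, n_templates = NULL)
  f_hat <- colMeans(panel$haps)
  expect_identical(f_hat[1], 0)
  expect_identical(f_hat[3], 1)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(f_hat[2] - 0.3), 3 * se)
})

test_that("template mosaics induce recurring segment haplotypes", {
  fr <- toy_freqs(runif(60, 0.2, 0.8), chrom_length = 0.005)
  set.seed(22)
  panel <- simulate_pure_haplotypes(fr, n_animals = 200, n_templates = 10,
                                    template_tract_mean = 0.005)
  segs <- define_segments(panel$map, 30)
  ft <- tabulate_haplotype_frequencies(panel, panel, segs)
  n_distinct <- table(ft$seg_id)
  # iid draws would make essentially every 30-SNP string unique (~400);
  # the mosaic scheme collapses diversity so strings recur and their pool
  # frequencies are estimable
  expect_true(all(n_distinct < 200))
  top10 <- tapply(ft$p_taurus, ft$seg_id, function(p) sum(sort(p, TRUE)[1:10]))
  expect_true(all(top10 > 0.5))
  # same seed reproduces the panel exactly
  set.seed(22)
  panel2 <- simulate_pure_haplotypes(fr, n_animals = 200, n_templates = 10,
                                     template_tract_mean = 0.005)
  expect_identical(panel$haps, panel2$haps)
})

test_that("composite tract lengths follow the exponential admixture law", {
  # long chromosome so interval truncation of interior tracts is negligible
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 400,
                    chromosome_length = 20, n_taurus = 30, n_indicus = 30,
                    n_composite = 250, admix_generations = 8,
                    admix_proportion = 0.6, seed = 31)
  set.seed(31)
  fr <- simulate_founder_frequencies(cfg)
  pt <- simulate_pure_haplotypes(fr, cfg$n_taurus, "p_taurus", "taurus")
  pi_ <- simulate_pure_haplotypes(fr, cfg$n_indicus, "p_indicus", "indicus")
  comp <- simulate_composite_haplotypes(pt, pi_, cfg)
  inner <- comp$tracts[comp$tracts$interior, ]
  len <- inner$end_m - inner$start_m
  se <- 0.125 / sqrt(length(len))   # exponential: sd equals the mean
  expect_lt(abs(mean(len) - 0.125), 3 * se)
  # genome-wide indicine fraction matches the admixture proportion
  frac_hap <- rowMeans(comp$truth)
  se_frac <- stats::sd(frac_hap) / sqrt(length(frac_hap))
  expect_lt(abs(mean(frac_hap) - 0.6), 3 * se_frac)
})

test_that("fully indicine admixture gives constant ancestry", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 100,
                    n_taurus = 20, n_indicus = 20, n_composite = 10,
                    admix_proportion = 1, seed = 32)
  set.seed(32)
  fr <- simulate_founder_frequencies(cfg)
  pt <- simulate_pure_haplotypes(fr, 20, "p_taurus", "taurus")
  pi_ <- simulate_pure_haplotypes(fr, 20, "p_indicus", "indicus")
  comp <- simulate_composite_haplotypes(pt, pi_, cfg)
  expect_true(all(comp$truth == 1L))
})

test_that("empty founder pools are rejected", {
  cfg <- sim_config(seed = 1)
  set.seed(1)
  fr <- simulate_founder_frequencies(sim_config(n_chromosomes = 1,
                                                snps_per_chromosome = 40, seed = 1))
  pt <- simulate_pure_haplotypes(fr, 5, "p_taurus", "taurus")
  empty <- pt
  empty$haps <- pt$haps[integer(0), , drop = FALSE]
  expect_error(simulate_composite_haplotypes(empty, pt, cfg), "non-empty")
})

test_that("phenotypes decompose into QTL, polygenic and residual parts", {
  # pure noise: no QTL, h2 = 0 -> unit variance noise
  sim0 <- quick_sim(seed = 41, h2 = 0, n_t = 400, n_i = 400, n_c = 0,
                    n_chr = 1, m = 200)
  y0 <- sim0$phenotypes$y - sim0$config$group_effects[sim0$phenotypes$group]
  expect_equal(stats::var(y0), 1, tolerance = 0.15)

  # single QTL, effect 0.5 SD, no polygenic term: OLS on causal dosage
  q <- qtl_spec(1, 100, "shared_same_phase", 0.5, mutant_freq = 0.4)
  sim1 <- quick_sim(seed = 42, qtl = q, h2 = 0, n_t = 700, n_i = 700,
                    n_c = 600, n_chr = 1, m = 200)
  dose <- sim1$pheno_truth$qtl_dosages[, 1]
  fit <- stats::lm(sim1$phenotypes$y ~ dose + sim1$phenotypes$group)
  est <- summary(fit)$coefficients["dose", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])

  # taurine-only QTL carries no signal inside the indicine group
  q2 <- qtl_spec(1, 100, "taurus_only", 0.5, mutant_freq = 0.4)
  sim2 <- quick_sim(seed = 43, qtl = q2, h2 = 0, n_t = 1000, n_i = 1000,
                    n_c = 0, n_chr = 1, m = 200)
  ind <- sim2$phenotypes$group == "indicus"
  cnt <- allele_counts(sim2$panel)[ind, 100]
  if (stats::var(cnt) > 0) {
    fit2 <- summary(stats::lm(sim2$phenotypes$y[ind] ~ cnt))$coefficients
    expect_lt(abs(fit2["cnt", "Estimate"]), 3 * fit2["cnt", "Std. Error"])
  }
  expect_error(
    simulate_phenotypes(sim1$panel, sim1$truth_ancestry,
                        sim_config(qtl_specs = qtl_spec(1, 100, "shared_same_phase",
                                                        3, mutant_freq = 0.5),
                                   heritability_polygenic = 0.9, seed = 1)),
    "variance")
})

test_that("the generator is deterministic given a config", {
  cfg <- sim_config(n_taurus = 40, n_indicus = 40, n_composite = 20,
                    snps_per_chromosome = 120, seed = 99)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$panel$haps, s2$panel$haps)
  expect_identical(s1$truth_ancestry, s2$truth_ancestry)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("composite ancestry labels are tract-consistent", {
  sim <- quick_sim(seed = 55, n_t = 30, n_i = 30, n_c = 30, n_chr = 1, m = 150)
  comp_rows <- which(rep(sim$panel$group, each = 2) == "composite")
  tr <- truth_tracts(sim$truth_ancestry[comp_rows, , drop = FALSE],
                     sim$panel$map)
  # every SNP position falls in exactly one tract with the matching label
  one_hap <- rownames(sim$panel$haps)[comp_rows[1]]
  tr1 <- tr[tr$hap_id == one_hap, ]
  for (j in seq_len(ncol(sim$panel$haps))) {
    pos <- sim$panel$map$pos_bp[j]
    hit <- tr1[tr1$start_bp <= pos & pos < tr1$end_bp, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$origin == "indicine",
                     unname(sim$truth_ancestry[comp_rows[1], j] == 1L))
  }
})

test_that("polygenic variance matches its target across replicate draws", {
  sim <- quick_sim(seed = 61, h2 = 0.4, n_t = 800, n_i = 800, n_c = 400,
                   n_chr = 1, m = 300)
  grm <- sim$grm
  h2_hat <- replicate(30, {
    ph <- simulate_phenotypes(sim$panel, sim$truth_ancestry, sim$config, grm)
    stats::var(ph$truth$polygenic)
  })
  expect_lt(abs(mean(h2_hat) - 0.4), 0.05)
})
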