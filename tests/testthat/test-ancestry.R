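test_that("segment partition covers every SNP with 30/31-sized pieces", {
  m90 <- toy_map(90)
  s90 <- define_segments(m90)
  expect_identical(s90$n_snps, rep(30L, 3))

  s92 <- define_segments(toy_map(92))
  expect_identical(s92$n_snps, c(30L, 31L, 31L))
  expect_identical(sum(s92$n_snps), 92L)
  expect_identical(s92$start_idx, c(1L, 31L, 62L))

  expect_warning(s29 <- define_segments(toy_map(29)), "only 29 SNPs")
  expect_identical(nrow(s29), 1L)
  expect_identical(s29$n_snps, 29L)

  # partition property across chromosomes
  map2 <- dplyr::bind_rows(toy_map(92, chrom = 1L), toy_map(61, chrom = 2L))
  s <- define_segments(map2)
  expect_identical(sum(s$n_snps[s$chrom == 1]), 92L)
  expect_identical(sum(s$n_snps[s$chrom == 2]), 61L)
  expect_identical(s$start_idx[-1], s$end_idx[-nrow(s)] + 1L)
})

test_that("haplotype frequency tabulation counts exactly", {
  # 2-segment toy panel, enumerable by hand
  map <- toy_map(4)
  # taurine haplotypes: s1="0000" x2, s2="0011", s3="1100" over segments of 2
  h_t <- rbind(c(0,0,0,0), c(0,0,0,0), c(0,0,1,1), c(1,1,0,0))
  h_i <- rbind(c(1,1,1,1), c(1,1,1,1), c(1,1,1,1), c(0,0,1,1))
  pt <- toy_panel(h_t, "taurus", map)
  pii <- toy_panel(h_i, "indicus", map)
  segs <- define_segments(map, target_size = 2)
  ft <- tabulate_haplotype_frequencies(pt, pii, segs)

  seg1 <- ft[ft$seg_id == 1, ]
  expect_equal(seg1$p_taurus[seg1$hap_str == "00"], 0.75)
  expect_equal(seg1$p_taurus[seg1$hap_str == "11"], 0.25)
  expect_equal(seg1$p_indicus[seg1$hap_str == "11"], 0.75)
  expect_equal(seg1$p_indicus[seg1$hap_str == "00"], 0.25)
  # string seen only in one panel has frequency 0 in the other
  seg2 <- ft[ft$seg_id == 2, ]
  expect_equal(seg2$p_indicus[seg2$hap_str == "00"], 0)
  # frequencies within each panel sum to 1 when all haplotypes observed
  sums <- tapply(ft$p_taurus, ft$seg_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # brute-force oracle: enumerate counts directly
  all_str <- apply(h_t[, 1:2], 1, paste0, collapse = "")
  expect_equal(seg1$p_taurus[match("00", seg1$hap_str)],
               sum(all_str == "00") / length(all_str))
})

test_that("raw origin probability is the indicine share of panel frequency", {
  ft <- tibble::tibble(seg_id = 1L, hap_str = c("01", "10", "11"),
                       p_taurus = c(0.1, 0.2, 0.2),
                       p_indicus = c(0.4, 0.2, 0.0))
  expect_equal(raw_origin_probability(ft, 1L, "01"), 0.8)
  expect_equal(raw_origin_probability(ft, 1L, "10"), 0.5)
  expect_equal(raw_origin_probability(ft, 1L, "11"), 0.0)
  expect_true(is.na(raw_origin_probability(ft, 1L, "00")))
  expect_error(raw_origin_probability(ft, 1L, "010"), "length")
  expect_error(raw_origin_probability(ft, 2L, "01"), "unknown segment")
})

test_that("smoothing is a truncated centred mean that skips missing values", {
  expect_equal(smooth_origin_probability(rep(0.9, 10)), rep(0.9, 10))
  s <- smooth_origin_probability(c(1, 1, 1, 0, 1, 1, 1), window = 7)
  expect_equal(s[4], 6 / 7)
  expect_equal(smooth_origin_probability(c(0.2, NA, 0.4), window = 3)[2], 0.3)
  x <- c(0.0, 0.6, 0.9, 0.8, 0.7, 0.5, 0.3, 0.1)
  # truncated window at the first element: mean of positions 1..4
  expect_equal(smooth_origin_probability(x, 7)[1], mean(x[1:4]))
  expect_equal(smooth_origin_probability(rep(NA_real_, 5))[3], 0.5)

  # contraction: smoothed value stays within the window's raw range
  set.seed(5)
  for (rep in 1:20) {
    x <- runif(15)
    sm <- smooth_origin_probability(x, 7)
    for (i in seq_along(x)) {
      w <- x[max(1, i - 3):min(15, i + 3)]
      expect_gte(sm[i] + 1e-12, min(w))
      expect_lte(sm[i] - 1e-12, max(w))
    }
  }
})

test_that("origin calls use a strict 0.6 boundary", {
  expect_identical(classify_origin(c(0.95, 0.1, 0.6, 0.601)),
                   c("indicine", "taurine", "taurine", "indicine"))
})

test_that("b is symmetric under swapping the reference panels", {
  sim <- quick_sim(seed = 71, n_t = 50, n_i = 50, n_c = 20, n_chr = 1, m = 120)
  segs <- define_segments(sim$panel$map)
  pt <- subset_panel(sim$panel, "taurus")
  pii <- subset_panel(sim$panel, "indicus")
  ft <- tabulate_haplotype_frequencies(pt, pii, segs)
  ft_swap <- tabulate_haplotype_frequencies(pii, pt, segs)
  org <- segment_origins(sim$panel, ft, segs)
  org_swap <- segment_origins(sim$panel, ft_swap, segs)
  expect_equal(org$raw_b, 1 - org_swap$raw_b, tolerance = 1e-12)
  expect_true(all(org$raw_b >= 0 & org$raw_b <= 1, na.rm = TRUE))
})

test_that("allele classes combine segment origin with the allele call", {
  panel <- toy_panel(rbind(c(0, 1), c(1, 0)), "composite", toy_map(2))
  ao <- toy_allele_origin(panel, rbind(c(1L, 1L), c(0L, 0L)))
  tb <- as_tibble_allele_origin(ao)
  expect_identical(tb$class[tb$slot == "paternal" & tb$snp_id == "chr1_snp1"],
                   "indicine_A")
  expect_identical(tb$class[tb$slot == "maternal" & tb$snp_id == "chr1_snp2"],
                   "taurine_A")
  # a pure taurine panel classified against itself gets taurine everywhere
  sim <- quick_sim(seed = 72, n_t = 60, n_i = 60, n_c = 0, n_chr = 1, m = 90)
  ao2 <- classify_sim(sim)
  tau_rows <- rep(sim$panel$group, each = 2) == "taurus"
  expect_true(all(ao2$origin[tau_rows, ] == 0L))
})

test_that("classification accuracy rises with divergence and panel size", {
  acc_at <- function(fst, n_ref, seed) {
    sim <- simulate_population(sim_config(
      n_chromosomes = 1, snps_per_chromosome = 300,
      n_taurus = n_ref, n_indicus = n_ref, n_composite = 40,
      divergence_fst = fst, seed = seed))
    ao <- classify_sim(sim)
    comp <- rep(sim$panel$group, each = 2) == "composite"
    mean(ao$origin[comp, ] == sim$truth_ancestry[comp, ])
  }
  by_fst <- vapply(c(0.05, 0.2, 0.5), acc_at, numeric(1), n_ref = 150, seed = 81)
  expect_true(all(diff(by_fst) > -0.005))
  by_ref <- vapply(c(25, 100, 300), function(nr) acc_at(0.15, nr, seed = 82),
                   numeric(1))
  expect_true(all(diff(by_ref) > -0.005))
})

test_that("ancestry fractions summarise groups as expected", {
  sim <- quick_sim(seed = 91, n_t = 100, n_i = 100, n_c = 80)
  ao <- classify_sim(sim)
  segs <- ao$segments
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs)
  rep_ <- ancestry_fraction_report(
    org, stats::setNames(sim$panel$group, sim$panel$animals))
  fr <- rep_$per_group
  expect_equal(fr$indicine_fraction[fr$group == "taurus"], 0)
  expect_gt(fr$indicine_fraction[fr$group == "indicus"], 0.98)
  expect_lt(abs(fr$indicine_fraction[fr$group == "composite"] - 0.75), 0.05)
  expect_true(all(rep_$b_histogram$count >= 0))
})
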