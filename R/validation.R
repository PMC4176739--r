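# Simulation studies packaged as reusable experiments. Each function builds
# its own synthetic population(s), runs the analysis pipeline, and returns
# the summary a methods paper would report: classification accuracy, power
# comparisons, best-variable recovery, null calibration, and the numerical
# equivalence of the two interaction parameterisations.

#' Accuracy of ancestry classification against simulated truth
#'
#' Simulates two reference pools plus composites, classifies every segment
#' from reference haplotype frequencies, and compares the per-allele origin
#' calls with the generator's truth.
#'
#' @param divergence_fst Founder differentiation.
#' @param n_ref Reference animals per pool.
#' @param n_composite Composite animals.
#' @param admix_generations Generations since admixture.
#' @param admix_proportion Expected indicine fraction.
#' @param seed RNG seed.
#' @param ... Further [sim_config()] overrides.
#' @return One-row tibble: `accuracy` (fraction of composite alleles whose
#'   origin call matches truth), `indicine_fraction_est` (group-level call),
#'   `indicine_fraction_true`, `admix_proportion`.
#' @export
ancestry_validation <- function(divergence_fst = 0.3, n_ref = 250,
                                n_composite = 200, admix_generations = 8,
                                admix_proportion = 0.75, seed = 1, ...) {
  sim <- simulate_population(sim_config(
    divergence_fst = divergence_fst, n_taurus = n_ref, n_indicus = n_ref,
    n_composite = n_composite, admix_generations = admix_generations,
    admix_proportion = admix_proportion, heritability_polygenic = 0,
    seed = seed, ...))
  segs <- define_segments(sim$panel$map)
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs)
  ao <- assign_allele_origins(sim$panel, org, segs)
  comp <- rep(sim$panel$group, each = 2) == "composite"
  rep_ <- ancestry_fraction_report(
    org, stats::setNames(sim$panel$group, sim$panel$animals))
  est <- rep_$per_group
  tibble::tibble(
    accuracy = mean(ao$origin[comp, ] == sim$truth_ancestry[comp, ]),
    indicine_fraction_est =
      est$indicine_fraction[est$group == "composite"],
    indicine_fraction_true = mean(sim$truth_ancestry[comp, ]),
    admix_proportion = admix_proportion
  )
}

# shared scaffolding: simulate with one QTL per chromosome, classify, and
# return the pieces the scan experiments need
qtl_experiment_data <- function(seed, mode, effect, mutant_freq,
                                mutant_allele, n_chromosomes, m,
                                n_taurus, n_indicus, n_composite, h2) {
  q <- purrr::map_dfr(seq_len(n_chromosomes), function(k) {
    qtl_spec(k, m %/% 2, mode, effect, mutant_freq, mutant_allele)
  })
  sim <- simulate_population(sim_config(
    n_chromosomes = n_chromosomes, snps_per_chromosome = m,
    n_taurus = n_taurus, n_indicus = n_indicus, n_composite = n_composite,
    heritability_polygenic = h2, qtl_specs = q, seed = seed))
  segs <- define_segments(sim$panel$map)
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs)
  ao <- assign_allele_origins(sim$panel, org, segs)
  qtl_idx <- (seq_len(n_chromosomes) - 1L) * m + m %/% 2
  list(sim = sim, ao = ao, qtl_idx = qtl_idx)
}

#' Power of the interaction scan versus the conventional scan
#'
#' Plants one phase-reversed (or other mode) QTL per chromosome, repeats the
#' simulation `n_reps` times, and counts how many planted QTL each scan
#' declares at `threshold` (interaction: joint 3-df test; conventional:
#' allele test). With reversed LD phase the pooled allele contrast cancels
#' between origins, so the interaction scan is expected to dominate.
#'
#' @param n_reps Replicates.
#' @param qtl_per_rep QTL (= chromosomes) per replicate.
#' @param effect QTL effect (phenotypic SD per causal allele).
#' @param mode QTL segregation mode.
#' @param n_taurus,n_indicus,n_composite Group sizes.
#' @param h2 Polygenic heritability (mixed model used when > 0).
#' @param threshold Declaration threshold.
#' @param m SNPs per chromosome.
#' @param seed Base seed (replicate r uses seed + r).
#' @return Tibble per replicate: `hits_interaction`, `hits_conventional`,
#'   `n_qtl`.
#' @export
power_experiment <- function(n_reps = 10, qtl_per_rep = 10, effect = 0.3,
                             mode = "shared_reversed_phase",
                             n_taurus = 1200, n_indicus = 1200,
                             n_composite = 600, h2 = 0.3,
                             threshold = 1e-4, m = 200, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    dat <- qtl_experiment_data(seed + r, mode, effect, 0.5, "B",
                               qtl_per_rep, m, n_taurus, n_indicus,
                               n_composite, h2)
    grm <- dat$sim$grm
    nf <- fit_null_model(dat$sim$phenotypes, "group", grm)
    conv <- run_conventional_gwas(dat$ao, dat$sim$phenotypes, grm = grm,
                                  snp_subset = dat$qtl_idx, null_fit = nf)
    inter <- run_interaction_gwas(dat$ao, dat$sim$phenotypes, grm = grm,
                                  snp_subset = dat$qtl_idx, null_fit = nf)
    joint <- dplyr::distinct(inter, snp_id, joint_p)
    tibble::tibble(
      rep = r,
      hits_interaction = sum(joint$joint_p < threshold, na.rm = TRUE),
      hits_conventional = sum(conv$p_value < threshold, na.rm = TRUE),
      n_qtl = qtl_per_rep
    )
  })
}

#' Best-variable recovery of the QTL segregation pattern
#'
#' For a one-subspecies QTL, the most significant single variable at the top
#' tag SNP is expected to identify the subspecies (x4/x6 for taurine-only,
#' x5/x7 for indicine-only) and, through which of the pair wins, the linked
#' allele. Repeats the simulation and reports the best variable at the
#' genome-wide top SNP of each replicate.
#'
#' @inheritParams power_experiment
#' @param mutant_allele SNP allele linked to the mutant ("A"/"B").
#' @param mutant_freq Mutant frequency where it segregates.
#' @return Tibble per replicate: `top_snp`, `best_variable`, `p_value`.
#' @export
best_variable_experiment <- function(n_reps = 50, mode = "taurus_only",
                                     mutant_allele = "A", effect = 0.5,
                                     mutant_freq = 0.5,
                                     n_taurus = 1200, n_indicus = 1200,
                                     n_composite = 600, h2 = 0,
                                     m = 300, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    dat <- qtl_experiment_data(seed + r, mode, effect, mutant_freq,
                               mutant_allele, 1, m, n_taurus, n_indicus,
                               n_composite, h2)
    res <- run_best_variable_gwas(dat$ao, dat$sim$phenotypes,
                                  grm = dat$sim$grm)
    top <- res[which.min(res$p_value), ]
    tibble::tibble(rep = r, top_snp = top$snp_id,
                   best_variable = top$best_variable, p_value = top$p_value)
  })
}

#' Joint-test calibration under the global null
#'
#' Simulates a QTL-free population with a polygenic background, runs the
#' interaction scan over every SNP, and reports the fraction of joint tests
#' below `threshold` together with the central 99% binomial band around the
#' nominal rate and the resulting false-discovery-rate report.
#'
#' @inheritParams power_experiment
#' @param n_snps Total SNPs simulated (split over 5 chromosomes).
#' @return One-row tibble: `n_tests`, `n_hits`, `rate`, `lower`, `upper`
#'   (99% binomial band on counts), `fdr_percent`, `h2_estimate`.
#' @export
null_calibration_experiment <- function(n_snps = 5000, n_taurus = 800,
                                        n_indicus = 800, n_composite = 400,
                                        h2 = 0.3, threshold = 1e-4, seed = 1) {
  n_chr <- 5
  sim <- simulate_population(sim_config(
    n_chromosomes = n_chr, snps_per_chromosome = n_snps %/% n_chr,
    n_taurus = n_taurus, n_indicus = n_indicus, n_composite = n_composite,
    heritability_polygenic = h2, seed = seed))
  segs <- define_segments(sim$panel$map)
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs)
  ao <- assign_allele_origins(sim$panel, org, segs)
  null_fit <- fit_null_model(sim$phenotypes, "group", sim$grm)
  res <- run_interaction_gwas(ao, sim$phenotypes, grm = sim$grm,
                              null_fit = null_fit)
  joint <- dplyr::distinct(res, snp_id, joint_p)
  p <- joint$joint_p[!is.na(joint$joint_p)]
  hits <- sum(p < threshold)
  fdr <- estimate_fdr(hits, length(p), threshold)
  tibble::tibble(
    n_tests = length(p), n_hits = hits, rate = hits / length(p),
    lower = stats::qbinom(0.005, length(p), threshold),
    upper = stats::qbinom(0.995, length(p), threshold),
    fdr_percent = fdr$fdr_percent,
    h2_estimate = null_fit$h2
  )
}

#' Numerical equivalence of the two interaction parameterisations
#'
#' The {allele, origin, interaction} and {origin, allele-within-taurine,
#' allele-within-indicine} codings span the same column space, so their
#' joint 3-df statistics must agree to numerical precision.
#'
#' @inheritParams power_experiment
#' @param n_snps SNPs compared (random subset of the simulated map).
#' @param n_animals Total animals (split 40/40/20 across groups).
#' @return One-row tibble: `n_snps_compared`, `max_rel_diff`.
#' @export
model_equivalence_experiment <- function(n_snps = 100, n_animals = 1000,
                                         h2 = 0.3, seed = 1) {
  n_t <- round(0.4 * n_animals); n_i <- n_t
  n_c <- n_animals - 2 * n_t
  sim <- simulate_population(sim_config(
    n_chromosomes = 2, snps_per_chromosome = 300,
    n_taurus = n_t, n_indicus = n_i, n_composite = n_c,
    heritability_polygenic = h2, seed = seed))
  segs <- define_segments(sim$panel$map)
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs)
  ao <- assign_allele_origins(sim$panel, org, segs)
  set.seed(seed)
  snps <- sort(sample.int(ncol(sim$panel$haps), n_snps))
  res <- run_interaction_gwas(ao, sim$phenotypes, grm = sim$grm,
                              snp_subset = snps)
  jt <- dplyr::distinct(res, snp_id, joint_stat, joint_stat_reparam)
  jt <- jt[!is.na(jt$joint_stat) & !is.na(jt$joint_stat_reparam), ]
  tibble::tibble(
    n_snps_compared = nrow(jt),
    max_rel_diff = max(abs(jt$joint_stat - jt$joint_stat_reparam) /
                         pmax(jt$joint_stat, 1e-12))
  )
}
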