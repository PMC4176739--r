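#' Genomic relationship matrix (VanRaden)
#'
#' Centred-scaled cross-product of allele counts:
#' G = Z Z' / (2 * sum p(1-p)) with Z = M - 2p, p estimated from the data.
#' Monomorphic SNPs contribute nothing and are skipped.
#'
#' @param panel A [hap_panel()] (or a 0/1/2 count matrix).
#' @return Symmetric PSD matrix `n_animals x n_animals`.
#' @export
compute_grm <- function(panel) {
  M <- if (inherits(panel, "hap_panel")) allele_counts(panel) else as.matrix(panel)
  p <- colMeans(M, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

# number of causal alleles per animal for one QTL, from haplotype calls and
# true per-allele ancestry (0 = taurine, 1 = indicine)
qtl_dosage <- function(q, hap_col, anc_col) {
  # causal classes per mode: the mutant QTL allele rides on `mutant_allele`
  # within the stated subspecies origin(s); alleles of other classes carry
  # the ancestral (null) QTL allele

  mut <- as.integer(q$mutant_allele == "B")      # mutant allele as 0/1 call
  causal <- switch(q$mode,
    taurus_only = (anc_col == 0L) & (hap_col == mut),
    indicus_only = (anc_col == 1L) & (hap_col == mut),
    shared_same_phase = hap_col == mut,
    shared_reversed_phase = ((anc_col == 0L) & (hap_col == mut)) |
      ((anc_col == 1L) & (hap_col != mut)),
    fixed_difference = anc_col == 1L,
    stop("unknown QTL mode: ", q$mode)
  )
  n <- length(causal) / 2
  as.integer(causal[2 * seq_len(n) - 1]) + as.integer(causal[2 * seq_len(n)])
}

#' Simulate phenotypes under a polygenic + QTL model
#'
#' Generates y = group offset + sum_k (causal dosage_k x effect_k) +
#' polygenic value + residual, on a phenotypic-SD scale of 1. Polygenic
#' values are multivariate normal with covariance
#' `heritability_polygenic * G` (G the genomic relationship matrix of all
#' animals); the residual variance is set to
#' 1 - h2_poly - var(QTL contribution) so the total variance is 1 in
#' expectation. Causal dosages use the true per-allele ancestry so that
#' reversed-phase and one-subspecies QTL behave exactly as their mode
#' describes.
#'
#' @param panel Combined [hap_panel()] of all animals.
#' @param truth Ancestry matrix (`n_hap x n_snp`, 0 taurine / 1 indicine)
#'   aligned with `panel$haps`.
#' @param config A [sim_config()]; uses `qtl_specs`,
#'   `heritability_polygenic`, `group_effects`.
#' @param grm Optional precomputed GRM; computed from the panel when NULL
#'   and `heritability_polygenic > 0`.
#' @return List with `phenotypes` (tibble: `animal_id`, `group`, `y`) and
#'   `truth` (list: per-animal polygenic values, per-QTL causal dosage
#'   matrix, residual SD).
#' @export
simulate_phenotypes <- function(panel, truth, config, grm = NULL) {
  n <- n_animals(panel)
  qtl <- config$qtl_specs
  g_qtl <- rep(0, n)
  dosages <- NULL
  if (!is.null(qtl) && nrow(qtl) > 0) {
    snp_global <- (qtl$chromosome - 1L) * config$snps_per_chromosome + qtl$snp_index
    dosages <- matrix(0L, n, nrow(qtl))
    for (k in seq_len(nrow(qtl))) {
      j <- snp_global[k]
      dosages[, k] <- qtl_dosage(qtl[k, ], panel$haps[, j], truth[, j])
    }
    g_qtl <- as.vector(dosages %*% qtl$effect)
  }
  var_qtl <- if (n > 1) stats::var(g_qtl) else 0
  h2 <- config$heritability_polygenic
  var_e <- 1 - h2 - var_qtl
  if (var_e <= 0) {
    stop(sprintf(
      "QTL variance (%.3f) + polygenic h2 (%.3f) reaches/exceeds total variance 1",
      var_qtl, h2))
  }
  u <- rep(0, n)
  if (h2 > 0) {
    if (is.null(grm)) grm <- compute_grm(panel)
    # mean-diagonal-1 scaling so var(u_i) ~ h2
    Gs <- grm / mean(diag(grm))
    L <- chol(Gs + diag(1e-8, n))
    u <- sqrt(h2) * as.vector(crossprod(L, stats::rnorm(n)))
  }
  offs <- config$group_effects[panel$group]
  offs[is.na(offs)] <- 0
  y <- as.numeric(offs) + g_qtl + u + stats::rnorm(n, sd = sqrt(var_e))
  list(
    phenotypes = tibble::tibble(animal_id = panel$animals,
                                group = panel$group, y = y),
    truth = list(polygenic = u, qtl_dosages = dosages,
                 residual_sd = sqrt(var_e), var_qtl = var_qtl)
  )
}

#' Run the whole synthetic-data generator
#'
#' Draws founder frequencies, pure taurine and indicine panels, composite
#' panels with known ancestry, and phenotypes, all from `config$seed`.
#' Identical configs give identical output.
#'
#' @param config A [sim_config()].
#' @return An `origwas_sim` list: `panel` (all animals; taurus, then indicus,
#'   then composites), `truth_ancestry` (matrix over all haplotypes),
#'   `phenotypes`, `pheno_truth`, `freqs`, `grm`, `config`.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  freqs <- simulate_founder_frequencies(config)
  templates <- if (is.null(config$n_templates)) NULL
               else draw_pool_templates(freqs, config)
  taurus <- simulate_pure_haplotypes(
    freqs, config$n_taurus, "p_taurus", "taurus",
    n_templates = config$n_templates,
    template_tract_mean = config$template_tract_mean,
    templates = templates$taurus)
  indicus <- simulate_pure_haplotypes(
    freqs, config$n_indicus, "p_indicus", "indicus",
    n_templates = config$n_templates,
    template_tract_mean = config$template_tract_mean,
    templates = templates$indicus)
  truth_t <- matrix(0L, nrow(taurus$haps), ncol(taurus$haps))
  truth_i <- matrix(1L, nrow(indicus$haps), ncol(indicus$haps))
  if (config$n_composite > 0) {
    comp <- simulate_composite_haplotypes(taurus, indicus, config, templates)
    panel <- bind_panels(taurus, indicus, comp$panel)
    truth <- rbind(truth_t, truth_i, comp$truth)
  } else {
    panel <- bind_panels(taurus, indicus)
    truth <- rbind(truth_t, truth_i)
  }
  rownames(truth) <- rownames(panel$haps)
  grm <- if (config$heritability_polygenic > 0) compute_grm(panel) else NULL
  ph <- simulate_phenotypes(panel, truth, config, grm = grm)
  structure(
    list(panel = panel, truth_ancestry = truth,
         phenotypes = ph$phenotypes, pheno_truth = ph$truth,
         freqs = freqs, grm = grm, config = config),
    class = "origwas_sim"
  )
}

#' @export
print.origwas_sim <- function(x, ...) {
  cat("<origwas_sim>\n")
  print(x$panel)
  cat(sprintf("  h2_poly = %.2f, QTL var = %.3f, %d QTL\n",
              x$config$heritability_polygenic, x$pheno_truth$var_qtl,
              if (is.null(x$config$qtl_specs)) 0L else nrow(x$config$qtl_specs)))
  invisible(x)
}
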