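#' QTL specification for the synthetic-data generator
#'
#' Each QTL sits at an existing SNP on the map and follows one of five
#' segregation modes that span the hypothesis space of a two-subspecies
#' admixture design:
#' \describe{
#'   \item{taurus_only}{the mutant allele segregates only in the taurine
#'     founder pool (frequency `mutant_freq` there, 0 in the indicine pool).}
#'   \item{indicus_only}{mirror image of `taurus_only`.}
#'   \item{shared_same_phase}{the mutant segregates at `mutant_freq` in both
#'     pools and the SNP-QTL linkage phase is identical, so the plain allele
#'     contrast carries the whole signal.}
#'   \item{shared_reversed_phase}{the mutant segregates in both pools but the
#'     linkage phase is reversed between them: the effect attaches to
#'     `mutant_allele` on taurine-origin haplotypes and to the opposite allele
#'     on indicine-origin haplotypes, so the pooled allele contrast cancels.}
#'   \item{fixed_difference}{the pools are fixed for alternate alleles and the
#'     effect attaches to subspecies origin itself.}
#' }
#'
#' @param chromosome Chromosome index (1-based).
#' @param snp_index SNP index within that chromosome (1-based).
#' @param mode One of the five modes above.
#' @param effect Effect per causal allele, in phenotypic SD units.
#' @param mutant_freq Frequency of the mutant allele in the pool(s) where it
#'   segregates; must be in (0, 1) for segregating modes.
#' @param mutant_allele Which SNP allele ("A" or "B") tags the mutant.
#' @return A `qtl_spec` row (tibble).
#' @export
qtl_spec <- function(chromosome, snp_index, mode, effect,
                     mutant_freq = 0.5, mutant_allele = "B") {
  mode <- match.arg(mode, c("taurus_only", "indicus_only", "shared_same_phase",
                            "shared_reversed_phase", "fixed_difference"))
  mutant_allele <- match.arg(mutant_allele, c("A", "B"))
  if (mode != "fixed_difference" &&
      (mutant_freq <= 0 || mutant_freq >= 1)) {
    stop("mutant_freq must be in (0, 1) for segregating modes")
  }
  tibble::tibble(
    chromosome = as.integer(chromosome),
    snp_index = as.integer(snp_index),
    mode = mode,
    effect = as.numeric(effect),
    mutant_freq = as.numeric(mutant_freq),
    mutant_allele = mutant_allele
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe a
#' small two-subspecies admixture design: two deeply diverged founder pools
#' (Balding-Nichols differentiation `divergence_fst`), composites formed by
#' recent admixture (`admix_generations` back, expected indicine fraction
#' `admix_proportion`), local LD induced by a template-mosaic copying scheme,
#' and a polygenic + residual phenotype.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param snps_per_chromosome SNPs per chromosome (uniformly spaced).
#' @param chromosome_length Chromosome length in Morgans.
#' @param n_taurus,n_indicus,n_composite Animals per group.
#' @param divergence_fst Balding-Nichols differentiation parameter in (0, 1).
#' @param admix_generations Generations since admixture (integer >= 1);
#'   ancestry tract lengths are exponential with mean `1/admix_generations`
#'   Morgan.
#' @param admix_proportion Expected indicine genome fraction of composites.
#' @param qtl_specs Tibble of QTL rows from [qtl_spec()], or NULL.
#' @param heritability_polygenic Polygenic variance fraction in [0, 1).
#' @param fixed_diff_fraction Fraction of SNPs forced to fixed alternate
#'   alleles between the pools (beyond what drift produces).
#' @param n_templates Template haplotypes per founder pool for the LD scheme;
#'   NULL draws every haplotype independently (no LD).
#' @param template_tract_mean Mean template-switch tract length (Morgans).
#' @param template_share_scale Exponent controlling identity-by-descent
#'   haplotype sharing between the pools: a template is identical in both
#'   pools with probability `(1 - divergence_fst)^template_share_scale`.
#'   The default (30, one segment's worth of SNPs) makes sharing vanish for
#'   strongly diverged pools and become common as divergence approaches 0.
#' @param ancestral_freq_range Range of the uniform ancestral allele
#'   frequency distribution.
#' @param group_effects Named numeric of group mean offsets (phenotypic SD).
#' @param seed RNG seed; a fixed seed makes the whole simulation
#'   reproducible.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_chromosomes = 2,
                       snps_per_chromosome = 600,
                       chromosome_length = 0.05,
                       n_taurus = 250,
                       n_indicus = 250,
                       n_composite = 100,
                       divergence_fst = 0.3,
                       admix_generations = 8,
                       admix_proportion = 0.75,
                       qtl_specs = NULL,
                       heritability_polygenic = 0.3,
                       fixed_diff_fraction = 0.005,
                       n_templates = 20,
                       template_tract_mean = 0.005,
                       template_share_scale = 30,
                       ancestral_freq_range = c(0.05, 0.95),
                       group_effects = c(taurus = 0, indicus = 0.5, composite = 0.25),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length = as.numeric(chromosome_length),
    n_taurus = as.integer(n_taurus),
    n_indicus = as.integer(n_indicus),
    n_composite = as.integer(n_composite),
    divergence_fst = as.numeric(divergence_fst),
    admix_generations = as.integer(admix_generations),
    admix_proportion = as.numeric(admix_proportion),
    qtl_specs = qtl_specs,
    heritability_polygenic = as.numeric(heritability_polygenic),
    fixed_diff_fraction = as.numeric(fixed_diff_fraction),
    n_templates = if (is.null(n_templates)) NULL else as.integer(n_templates),
    template_tract_mean = as.numeric(template_tract_mean),
    template_share_scale = as.numeric(template_share_scale),
    ancestral_freq_range = as.numeric(ancestral_freq_range),
    group_effects = group_effects,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_chromosomes > 0, snps_per_chromosome > 0, chromosome_length > 0,
      n_taurus > 0, n_indicus > 0, n_composite >= 0,
      admix_generations >= 1,
      admix_proportion > 0, admix_proportion <= 1,
      heritability_polygenic >= 0, heritability_polygenic < 1,
      fixed_diff_fraction >= 0, fixed_diff_fraction < 1,
      length(ancestral_freq_range) == 2,
      ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
      template_tract_mean > 0, template_share_scale >= 0
    )
    if (divergence_fst <= 0 || divergence_fst >= 1) {
      stop("divergence_fst must be strictly inside (0, 1)")
    }
    if (!is.null(n_templates) && n_templates < 2) {
      stop("n_templates must be >= 2 (or NULL for iid haplotypes)")
    }
  })
  if (!is.null(cfg$qtl_specs)) {
    q <- cfg$qtl_specs
    stopifnot(all(q$chromosome >= 1), all(q$chromosome <= cfg$n_chromosomes),
              all(q$snp_index >= 1), all(q$snp_index <= cfg$snps_per_chromosome))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d chrom x %d SNPs (%.2f M each); ",
           "animals t/i/c = %d/%d/%d\n  fst = %.2f, admix g = %d, ",
           "indicine prop = %.2f, h2_poly = %.2f, %s QTL, seed = %d\n"),
    x$n_chromosomes, x$snps_per_chromosome, x$chromosome_length,
    x$n_taurus, x$n_indicus, x$n_composite,
    x$divergence_fst, x$admix_generations, x$admix_proportion,
    x$heritability_polygenic,
    if (is.null(x$qtl_specs)) 0L else nrow(x$qtl_specs), x$seed
  ))
  invisible(x)
}

# uniform SNP map in Morgans, emitted as bp at 1e8 bp/Morgan
build_snp_map <- function(config) {
  m <- config$snps_per_chromosome
  len <- config$chromosome_length
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    pos_m <- (seq_len(m) - 0.5) / m * len
    tibble::tibble(
      chrom = ch,
      pos_morgan = pos_m,
      pos_bp = as.integer(round(morgans_to_bp(pos_m))),
      snp_id = sprintf("chr%d_snp%d", ch, seq_len(m))
    )
  })
}
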