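#' Genotype quality-control filters
#'
#' Applies the standard filters in order: (1) SNPs with genotype call rate
#' below `snp_call_rate` removed; (2) SNPs with both homozygous genotype
#' classes observed but zero heterozygotes removed (the degenerate
#' Hardy-Weinberg failure typical of assay artefacts — no chi-square test,
#' just the exact degenerate pattern); (3) animals with call rate below
#' `animal_call_rate` removed. A genotype is called only when both of the
#' animal's alleles at the SNP are called.
#'
#' @param panel A [hap_panel()] (may contain NA alleles).
#' @param snp_call_rate Minimum SNP call rate (default 0.90).
#' @param animal_call_rate Minimum animal call rate (default 0.90).
#' @return List: `panel` (filtered) and `report` (one-row tibble with
#'   removed/retained counts per rule).
#' @export
apply_qc <- function(panel, snp_call_rate = 0.90, animal_call_rate = 0.90) {
  n <- length(panel$animals)
  pat <- panel$haps[2L * seq_len(n) - 1L, , drop = FALSE]
  mat <- panel$haps[2L * seq_len(n), , drop = FALSE]
  called <- !(is.na(pat) | is.na(mat))
  geno <- pat + mat   # NA where not called

  snp_cr <- colMeans(called)
  rm_callrate <- snp_cr < snp_call_rate

  n_aa <- colSums(geno == 0L, na.rm = TRUE)
  n_ab <- colSums(geno == 1L, na.rm = TRUE)
  n_bb <- colSums(geno == 2L, na.rm = TRUE)
  rm_hwe <- !rm_callrate & n_aa > 0 & n_bb > 0 & n_ab == 0

  keep_snp <- !(rm_callrate | rm_hwe)

  animal_cr <- rowMeans(called[, keep_snp, drop = FALSE])
  keep_animal <- animal_cr >= animal_call_rate

  filtered <- panel
  hap_keep <- rep(keep_animal, each = 2)
  filtered <- hap_panel(panel$haps[hap_keep, keep_snp, drop = FALSE],
                        panel$map[keep_snp, , drop = FALSE],
                        panel$animals[keep_animal],
                        panel$group[keep_animal])
  report <- tibble::tibble(
    snps_in = ncol(panel$haps),
    snps_removed_callrate = sum(rm_callrate),
    snps_removed_hwe = sum(rm_hwe),
    snps_out = sum(keep_snp),
    animals_in = n,
    animals_removed_callrate = sum(!keep_animal),
    animals_out = sum(keep_animal)
  )
  stopifnot(report$snps_in == report$snps_out + report$snps_removed_callrate +
              report$snps_removed_hwe,
            report$animals_in == report$animals_out +
              report$animals_removed_callrate)
  list(panel = filtered, report = report)
}

#' Inject missing genotypes into a panel (for QC testing)
#'
#' Sets both alleles of randomly chosen animal-SNP genotypes to NA at the
#' given rate.
#'
#' @param panel A [hap_panel()].
#' @param rate Fraction of genotypes to blank.
#' @return The panel with missingness injected.
#' @export
inject_missingness <- function(panel, rate) {
  stopifnot(rate >= 0, rate < 1)
  n <- length(panel$animals)
  m <- ncol(panel$haps)
  drop <- matrix(stats::runif(n * m) < rate, n, m)
  haps <- panel$haps
  idx <- which(drop, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    haps[cbind(2L * idx[, 1] - 1L, idx[, 2])] <- NA_integer_
    haps[cbind(2L * idx[, 1], idx[, 2])] <- NA_integer_
  }
  hap_panel(haps, panel$map, panel$animals, panel$group)
}
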