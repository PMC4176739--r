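#' Estimate the false discovery rate of a significance count
#'
#' FDR is taken as the expected number of false positives at threshold P
#' over T tests (P x T) divided by the observed count of significant SNPs A,
#' expressed as a truncated integer percent: floor(100 * P * T / A), capped
#' at 100. With A = 0 the FDR is undefined and reported as NA. A refined
#' variant P(1 - A/T) / ((A/T)(1 - P)) is available behind `refined = TRUE`;
#' the two differ negligibly for small P.
#'
#' @param n_significant Observed significant count A (>= 0), vectorised.
#' @param n_tests Number of tests T (> 0).
#' @param threshold Significance threshold P in (0, 1).
#' @param refined Use the refined estimator (default FALSE).
#' @return Tibble `n_significant`, `n_tests`, `threshold`, `fdr_percent`
#'   (integer, NA when A = 0).
#' @export
estimate_fdr <- function(n_significant, n_tests, threshold, refined = FALSE) {
  stopifnot(all(n_significant >= 0), all(n_tests > 0),
            all(threshold > 0), all(threshold < 1))
  if (any(n_significant > n_tests)) {
    stop("significant count exceeds number of tests")
  }
  frac <- if (refined) {
    a <- n_significant / n_tests
    threshold * (1 - a) / (a * (1 - threshold))
  } else {
    threshold * n_tests / n_significant
  }
  pct <- ifelse(n_significant == 0, NA_integer_,
                as.integer(pmin(100, floor(100 * frac))))
  tibble::tibble(n_significant = as.integer(n_significant),
                 n_tests = as.integer(n_tests),
                 threshold = threshold, fdr_percent = pct)
}

#' FDR summary of a scan result
#'
#' Counts testable SNPs and significant SNPs in a results tibble and applies
#' [estimate_fdr()]. The number of tests is the number of testable SNPs, not
#' the nominal map size.
#'
#' @param results Scan tibble with a p-value column.
#' @param threshold Significance threshold (default 1e-4).
#' @param p_col Which column holds the p-value (default `p_value`; use
#'   `joint_p` for interaction scans).
#' @return One-row tibble from [estimate_fdr()].
#' @export
fdr_summary <- function(results, threshold = 1e-4, p_col = "p_value") {
  p <- results[[p_col]]
  if (p_col == "joint_p") p <- p[!duplicated(results$snp_id)]
  p <- p[!is.na(p)]
  estimate_fdr(sum(p < threshold), length(p), threshold)
}

#' Classify QTL segregation patterns from the re-parameterised fit
#'
#' For each SNP significant for at least one of the three contrasts —
#' subspecies origin (O = x2), allele within taurine (T = x6), allele within
#' indicine (I = x7) — builds the three-letter pattern label ("O--", "-TI",
#' "OTI", ...). A QTL segregating in one subspecies only is expected to show
#' "OT-"/"-T-" or "O-I"/"--I"; a fixed difference shows "O--".
#'
#' @param interaction_results Output of [run_interaction_gwas()].
#' @param threshold Marginal significance threshold (default 1e-4).
#' @return Tibble `snp_id`, `chrom`, `pos_bp`, `origin_sig`, `taurine_sig`,
#'   `indicine_sig`, `pattern`; one row per SNP significant for >= 1
#'   contrast.
#' @export
classify_patterns <- function(interaction_results, threshold = 1e-4) {
  wide <- interaction_results |>
    dplyr::filter(term %in% c("x2", "x6", "x7")) |>
    dplyr::select(snp_id, chrom, pos_bp, term, p_value) |>
    tidyr::pivot_wider(names_from = term, values_from = p_value)
  for (v in c("x2", "x6", "x7")) if (is.null(wide[[v]])) wide[[v]] <- NA_real_
  wide |>
    dplyr::mutate(
      origin_sig = !is.na(x2) & x2 < threshold,
      taurine_sig = !is.na(x6) & x6 < threshold,
      indicine_sig = !is.na(x7) & x7 < threshold,
      pattern = paste0(ifelse(origin_sig, "O", "-"),
                       ifelse(taurine_sig, "T", "-"),
                       ifelse(indicine_sig, "I", "-"))
    ) |>
    dplyr::filter(pattern != "---") |>
    dplyr::select(snp_id, chrom, pos_bp, origin_sig, taurine_sig,
                  indicine_sig, pattern)
}

#' Direction consistency of within-origin allele effects
#'
#' For SNPs whose allele effect is significant within both origins, flags
#' whether the taurine (b6) and indicine (b7) effects share a sign — the
#' signature of a QTL segregating in both subspecies with conserved phase.
#'
#' @param interaction_results Output of [run_interaction_gwas()].
#' @param threshold Marginal significance threshold (default 1e-4).
#' @return Tibble `snp_id`, `b6`, `b7`, `consistent` (logical), restricted
#'   to doubly-significant SNPs.
#' @export
sign_consistency_check <- function(interaction_results, threshold = 1e-4) {
  wide <- interaction_results |>
    dplyr::filter(term %in% c("x6", "x7")) |>
    dplyr::select(snp_id, term, estimate, p_value) |>
    tidyr::pivot_wider(names_from = term,
                       values_from = c(estimate, p_value))
  wide |>
    dplyr::filter(!is.na(p_value_x6), !is.na(p_value_x7),
                  p_value_x6 < threshold, p_value_x7 < threshold) |>
    dplyr::transmute(snp_id,
                     b6 = estimate_x6, b7 = estimate_x7,
                     consistent = sign(b6) == sign(b7))
}

#' Select the top SNP per trait-by-chromosome combination
#'
#' To avoid counting a QTL once per tag SNP, keeps only the single most
#' significant SNP passing `threshold` on each chromosome (per trait when a
#' `trait` column is present); exact p ties are broken by smallest position.
#'
#' @param best_results Output of [run_best_variable_gwas()], optionally with
#'   a `trait` column.
#' @param threshold Significance threshold (default 1e-4).
#' @return Tibble of top records with `signed_t` = estimate / se added.
#' @export
select_top_snps <- function(best_results, threshold = 1e-4) {
  grp <- intersect(c("trait", "chrom"), names(best_results))
  best_results |>
    dplyr::filter(!is.na(p_value), p_value < threshold) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(p_value, pos_bp, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(signed_t = estimate / se)
}

#' Infer which allele tracks the mutant QTL allele
#'
#' When the best variable is one of the four origin-by-allele classes
#' (x4..x7), the allele whose effect differs from the other three is read as
#' tracking the mutant QTL allele, giving its subspecies, allele letter,
#' within-subspecies frequency, and signed effect. When the best variable is
#' x1 (plain allele) or x2 (origin), the mutant cannot be attributed to one
#' subspecies: x2 in particular marks a fixed-difference candidate.
#'
#' @param top_records Output of [select_top_snps()].
#' @return Input with `mutant_subspecies`, `mutant_allele`, `mutant_freq`
#'   (frequency of the implicated allele within its subspecies), and
#'   `mutant_effect` columns; "shared/indeterminate" rows carry NAs.
#' @export
infer_mutant_allele <- function(top_records) {
  info <- tibble::tibble(
    best_variable = c("x4", "x5", "x6", "x7"),
    mutant_subspecies = c("taurus", "indicus", "taurus", "indicus"),
    mutant_allele = c("A", "A", "B", "B")
  )
  top_records |>
    dplyr::left_join(info, by = "best_variable") |>
    dplyr::mutate(
      mutant_subspecies = ifelse(best_variable %in% c("x1", "x2"),
                                 "shared/indeterminate", mutant_subspecies),
      freq_B_within = dplyr::case_when(
        mutant_subspecies == "taurus" ~ freq_B_taurine,
        mutant_subspecies == "indicus" ~ freq_B_indicine,
        TRUE ~ NA_real_
      ),
      mutant_freq = dplyr::case_when(
        mutant_allele == "B" ~ freq_B_within,
        mutant_allele == "A" ~ 1 - freq_B_within,
        TRUE ~ NA_real_
      ),
      mutant_effect = ifelse(best_variable %in% c("x1", "x2"),
                             NA_real_, estimate)
    ) |>
    dplyr::select(-freq_B_within)
}

#' Table behind the effect-versus-frequency scatter
#'
#' One row per top SNP whose best variable implicates an allele within one
#' subspecies: the signed standardized effect (estimate / SE) against the
#' implicated allele's frequency within that subspecies.
#'
#' @param top_records Output of [select_top_snps()] (after
#'   [infer_mutant_allele()] or not; inference is applied if absent).
#' @return Tibble `trait` (if present), `snp_id`, `subspecies`, `frequency`,
#'   `signed_t`.
#' @export
effect_frequency_plot_table <- function(top_records) {
  if (nrow(top_records) == 0) {
    return(tibble::tibble(snp_id = character(0), subspecies = character(0),
                          frequency = numeric(0), signed_t = numeric(0)))
  }
  if (!"mutant_subspecies" %in% names(top_records)) {
    top_records <- infer_mutant_allele(top_records)
  }
  out <- top_records |>
    dplyr::filter(mutant_subspecies %in% c("taurus", "indicus")) |>
    dplyr::transmute(
      dplyr::across(dplyr::any_of(c("trait", "snp_id"))),
      subspecies = mutant_subspecies,
      frequency = mutant_freq,
      signed_t = estimate / se
    )
  out
}
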