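#' Simulate founder-pool allele frequencies
#'
#' Draws per-SNP allele frequencies for the two founder pools under the
#' Balding-Nichols construction: an ancestral frequency p is drawn uniformly
#' inside `ancestral_freq_range`, then each pool's frequency is an independent
#' Beta(p (1-F)/F, (1-p)(1-F)/F) draw with F = `divergence_fst`, so the
#' expected differentiation between the pools equals F. A configurable
#' fraction of SNPs is forced to fixed alternate alleles (B frequency 1 in
#' the indicine pool, 0 in the taurine pool), emulating sites where drift or
#' new mutation has fixed a difference. QTL sites from `config$qtl_specs`
#' override the drawn frequencies according to their segregation mode.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per SNP: `chrom`, `snp_index`, `snp_id`,
#'   `pos_bp`, `pos_morgan`, `p_anc`, `p_taurus`, `p_indicus` (B-allele
#'   frequencies), and `is_fixed_diff`.
#' @export
simulate_founder_frequencies <- function(config) {
  validate_sim_config(config)
  map <- build_snp_map(config)
  n <- nrow(map)
  fst <- config$divergence_fst
  p_anc <- stats::runif(n, config$ancestral_freq_range[1],
                        config$ancestral_freq_range[2])
  shape_scale <- (1 - fst) / fst
  p_taurus <- stats::rbeta(n, p_anc * shape_scale, (1 - p_anc) * shape_scale)
  p_indicus <- stats::rbeta(n, p_anc * shape_scale, (1 - p_anc) * shape_scale)

  is_fixed <- rep(FALSE, n)
  if (config$fixed_diff_fraction > 0) {
    n_fix <- round(config$fixed_diff_fraction * n)
    if (n_fix > 0) {
      pick <- sample.int(n, n_fix)
      is_fixed[pick] <- TRUE
      p_taurus[pick] <- 0
      p_indicus[pick] <- 1
    }
  }

  freqs <- dplyr::mutate(map,
    snp_index = dplyr::row_number() - (chrom - 1L) * config$snps_per_chromosome,
    p_anc = p_anc, p_taurus = p_taurus, p_indicus = p_indicus,
    is_fixed_diff = is_fixed,
    forced = is_fixed   # sites whose pool frequencies are pinned
  )

  if (!is.null(config$qtl_specs)) {
    for (k in seq_len(nrow(config$qtl_specs))) {
      q <- config$qtl_specs[k, ]
      i <- which(freqs$chrom == q$chromosome & freqs$snp_index == q$snp_index)
      stopifnot(length(i) == 1)
      freqs$forced[i] <- TRUE
      fm <- q$mutant_freq
      # frequencies below are of the B allele; convert when the mutant is A
      fB <- function(f_mut) if (q$mutant_allele == "B") f_mut else 1 - f_mut
      if (q$mode == "taurus_only") {
        # the causal class is allele-within-taurine; the marker itself still
        # segregates freely in the indicine pool (as a chip SNP would)
        freqs$p_taurus[i] <- fB(fm)
      } else if (q$mode == "indicus_only") {
        freqs$p_indicus[i] <- fB(fm)
      } else if (q$mode == "shared_same_phase") {
        freqs$p_taurus[i] <- fB(fm); freqs$p_indicus[i] <- fB(fm)
      } else if (q$mode == "shared_reversed_phase") {
        # mutant tagged by `mutant_allele` in taurus, by the other in indicus
        freqs$p_taurus[i] <- fB(fm); freqs$p_indicus[i] <- 1 - fB(fm)
      } else if (q$mode == "fixed_difference") {
        freqs$p_taurus[i] <- 0; freqs$p_indicus[i] <- 1
        freqs$is_fixed_diff[i] <- TRUE
      }
    }
  }
  freqs
}

#' Draw the template haplotype sets of the two founder pools
#'
#' Templates are the small set of haplotypes whose mosaics make up every
#' simulated chromosome; they carry the local LD and the haplotype sharing
#' structure. Each of the `n_templates` slots is identical by descent in the
#' two pools (drawn once from the ancestral frequencies) with probability
#' `(1 - divergence_fst)^template_share_scale`, and otherwise drawn
#' independently from each pool's own frequencies — so deeply diverged pools
#' share essentially no multi-SNP haplotypes while weakly diverged pools
#' share most of them. Sites with pinned frequencies (fixed differences,
#' QTL sites; column `forced`) always use the pool's own frequency.
#'
#' @param freqs Founder-frequency tibble from
#'   [simulate_founder_frequencies()].
#' @param config A [sim_config()].
#' @return List of two 0/1 matrices (`taurus`, `indicus`), each
#'   `n_templates x n_snp`, plus attribute `shared` (logical per template).
#' @export
draw_pool_templates <- function(freqs, config) {
  k <- config$n_templates
  n <- nrow(freqs)
  draw <- function(p) matrix(stats::rbinom(k * n, 1L, rep(p, each = k)), k, n)
  anc <- draw(freqs$p_anc)
  tpl_t <- draw(freqs$p_taurus)
  tpl_i <- draw(freqs$p_indicus)
  share_p <- (1 - config$divergence_fst)^config$template_share_scale
  shared <- stats::runif(k) < share_p
  forced <- freqs$forced %||% rep(FALSE, n)
  if (any(shared)) {
    keep_t <- tpl_t[shared, , drop = FALSE]
    keep_i <- tpl_i[shared, , drop = FALSE]
    anc_s <- anc[shared, , drop = FALSE]
    anc_s[, forced] <- keep_t[, forced]
    tpl_t[shared, ] <- anc_s
    anc_s[, forced] <- keep_i[, forced]
    tpl_i[shared, ] <- anc_s
  }
  out <- list(taurus = tpl_t, indicus = tpl_i)
  attr(out, "shared") <- shared
  out
}

# template-mosaic haplotype sampler shared by the pure-pool generator.
# templates: n_templates x n_snp 0/1 matrix; pos_morgan: map positions of one
# chromosome; returns n_hap x n_snp matrix plus the template index per site.
sample_mosaic <- function(templates, pos_morgan, n_hap, tract_mean) {
  n_snp <- length(pos_morgan)
  L <- pos_morgan[n_snp]
  out <- matrix(0L, n_hap, n_snp)
  for (h in seq_len(n_hap)) {
    bks <- exp_breakpoints(pos_morgan[1], L, tract_mean)
    tract <- findInterval(pos_morgan, bks) + 1L
    tpl <- sample.int(nrow(templates), length(bks) + 1L, replace = TRUE)
    out[h, ] <- templates[cbind(tpl[tract], seq_len(n_snp))]
  }
  out
}

# successive exponential tract boundaries in (start, end)
exp_breakpoints <- function(start, end, tract_mean) {
  bks <- numeric(0)
  x <- start + stats::rexp(1, rate = 1 / tract_mean)
  while (x < end) {
    bks <- c(bks, x)
    x <- x + stats::rexp(1, rate = 1 / tract_mean)
  }
  bks
}

#' Simulate phased haplotypes for one founder pool
#'
#' Haplotypes are drawn either independently per site (Bernoulli at the given
#' frequency; `n_templates = NULL`) or, by default, as mosaics of a small set
#' of template haplotypes per pool. The template scheme induces local LD so
#' that 30-SNP segment haplotypes recur in the population and their pool
#' frequencies are estimable — the property the ancestry classifier relies
#' on. Under the template scheme the realized site frequency converges to the
#' template pool's frequency (which is centred on the input frequency with
#' binomial noise of size `n_templates`).
#'
#' @param freqs Founder-frequency tibble (rows for one pool's frequencies are
#'   taken from column `freq_col`).
#' @param n_animals Number of diploid animals to draw.
#' @param freq_col Which frequency column to use ("p_taurus" or "p_indicus").
#' @param group Group label stored in the panel.
#' @param n_templates Templates per pool (NULL = iid sites).
#' @param template_tract_mean Mean template-switch tract length (Morgans).
#' @param templates Optional pre-drawn template matrix (one pool's element of
#'   [draw_pool_templates()]); overrides `n_templates`.
#' @return A [hap_panel()] of `2 * n_animals` haplotypes.
#' @export
simulate_pure_haplotypes <- function(freqs, n_animals,
                                     freq_col = "p_taurus",
                                     group = "taurus",
                                     n_templates = 20,
                                     template_tract_mean = 0.005,
                                     templates = NULL) {
  stopifnot(n_animals > 0, freq_col %in% names(freqs))
  p <- freqs[[freq_col]]
  stopifnot(all(p >= 0), all(p <= 1))
  n_hap <- 2L * n_animals
  n_snp <- nrow(freqs)

  if (is.null(templates) && is.null(n_templates)) {
    haps <- matrix(stats::rbinom(n_hap * n_snp, 1L, rep(p, each = n_hap)),
                   n_hap, n_snp)
  } else {
    haps <- mosaic_panel(freqs, n_hap, p, n_templates, template_tract_mean,
                         templates)
  }
  hap_panel(
    haps,
    map = freqs[, c("chrom", "pos_bp", "snp_id", "pos_morgan")],
    animals = sprintf("%s%04d", substr(group, 1, 3), seq_len(n_animals)),
    group = rep(group, n_animals)
  )
}

# draw n_hap template-mosaic haplotypes over the whole map
mosaic_panel <- function(freqs, n_hap, p, n_templates, template_tract_mean,
                         templates = NULL) {
  n_snp <- nrow(freqs)
  if (is.null(templates)) {
    templates <- matrix(
      stats::rbinom(n_templates * n_snp, 1L, rep(p, each = n_templates)),
      n_templates, n_snp)
  }
  haps <- matrix(0L, n_hap, n_snp)
  for (ch in unique(freqs$chrom)) {
    idx <- which(freqs$chrom == ch)
    haps[, idx] <- sample_mosaic(templates[, idx, drop = FALSE],
                                 freqs$pos_morgan[idx],
                                 n_hap, template_tract_mean)
  }
  haps
}
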