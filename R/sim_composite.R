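#' Simulate composite (admixed) haplotypes with known ancestry
#'
#' Each composite haplotype is a mosaic of ancestry tracts copied from the
#' two founder-pool panels. Tract lengths are exponential with mean
#' `1/admix_generations` Morgans (the renewal scale of recombination
#' `admix_generations` meioses after admixture); each tract's source pool is
#' drawn independently with probability `admix_proportion` of being indicine,
#' so the expected genome-wide indicine fraction equals `admix_proportion`.
#' Within a tract, alleles are copied from one uniformly chosen haplotype of
#' the source pool, so composite segment haplotypes recur in the reference
#' panels.
#'
#' Within a tract, alleles are copied either from a fresh template mosaic of
#' the source pool (when `templates` is supplied — a draw from the founder
#' population process, so composite haplotypes are relatives, not copies, of
#' the reference animals) or verbatim from one uniformly chosen haplotype of
#' the source panel (when `templates` is NULL).
#'
#' @param taurus_pool,indicus_pool `hap_panel` objects for the founder pools
#'   (identical SNP maps).
#' @param config A [sim_config()]; uses `n_composite`, `admix_generations`,
#'   `admix_proportion`, and the template fields when `templates` is given.
#' @param templates Optional [draw_pool_templates()] output.
#' @return A list with `panel` (a [hap_panel()] of composites), `truth`
#'   (integer matrix `n_hap x n_snp`; 0 = taurine, 1 = indicine origin) and
#'   `tracts` (tibble of the generator's recombination tracts per haplotype:
#'   `hap`, `chrom`, `start_m`, `end_m`, `ancestry`, `interior` — interior
#'   tracts are uncensored draws from the exponential tract-length law).
#' @export
simulate_composite_haplotypes <- function(taurus_pool, indicus_pool, config,
                                          templates = NULL) {
  stopifnot(inherits(taurus_pool, "hap_panel"), inherits(indicus_pool, "hap_panel"))
  if (nrow(taurus_pool$haps) == 0 || nrow(indicus_pool$haps) == 0) {
    stop("founder pools must be non-empty")
  }
  if (!identical(taurus_pool$map$pos_bp, indicus_pool$map$pos_bp)) {
    stop("founder pools must share a SNP map")
  }
  map <- taurus_pool$map
  n_hap <- 2L * config$n_composite
  n_snp <- nrow(map)
  haps <- matrix(0L, n_hap, n_snp)
  truth <- matrix(0L, n_hap, n_snp)
  tract_mean <- 1 / config$admix_generations
  if (is.null(templates)) {
    pools <- list(taurus_pool$haps, indicus_pool$haps)
  } else {
    # one latent pool haplotype per composite haplotype per pool: fresh
    # mosaics from the founder population process
    fr <- map
    fr$pos_morgan <- fr$pos_morgan %||% bp_to_morgans(fr$pos_bp)
    pools <- list(
      mosaic_panel(fr, n_hap, NULL, NULL, config$template_tract_mean,
                   templates$taurus),
      mosaic_panel(fr, n_hap, NULL, NULL, config$template_tract_mean,
                   templates$indicus)
    )
  }
  fresh <- !is.null(templates)

  tract_log <- vector("list", length(unique(map$chrom)) * n_hap)
  k <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- (map$pos_morgan %||% bp_to_morgans(map$pos_bp))[idx]
    L <- pos[length(pos)]
    for (h in seq_len(n_hap)) {
      bks <- exp_breakpoints(pos[1], L, tract_mean)
      tract <- findInterval(pos, bks) + 1L
      n_tr <- length(bks) + 1L
      anc <- stats::rbinom(n_tr, 1L, config$admix_proportion)  # 1 = indicine
      src <- if (fresh) rep(h, n_tr) else
        vapply(anc, function(a) sample.int(nrow(pools[[a + 1L]]), 1L),
               integer(1))
      for (t in seq_len(n_tr)) {
        cols <- idx[tract == t]
        if (length(cols) == 0) next
        haps[h, cols] <- pools[[anc[t] + 1L]][src[t], cols]
        truth[h, cols] <- anc[t]
      }
      k <- k + 1L
      edges <- c(pos[1], bks, L)
      tract_log[[k]] <- tibble::tibble(
        hap = h, chrom = ch,
        start_m = edges[-length(edges)], end_m = edges[-1],
        ancestry = ifelse(anc == 1L, "indicine", "taurine"),
        interior = seq_len(n_tr) > 1 & seq_len(n_tr) < n_tr
      )
    }
  }
  tracts <- dplyr::bind_rows(tract_log)
  panel <- hap_panel(
    haps, map,
    animals = sprintf("com%04d", seq_len(config$n_composite)),
    group = rep("composite", config$n_composite)
  )
  rownames(truth) <- rownames(panel$haps)
  list(panel = panel, truth = truth, tracts = tracts)
}

#' True ancestry tracts in BED-like form
#'
#' Converts a per-SNP truth matrix to 0-based half-open tracts per haplotype,
#' using midpoints between adjacent SNPs as tract boundaries.
#'
#' @param truth Integer matrix as returned by
#'   [simulate_composite_haplotypes()].
#' @param map SNP map tibble (`chrom`, `pos_bp`).
#' @return Tibble `chrom`, `hap_id`, `start_bp`, `end_bp`, `origin`.
#' @export
truth_tracts <- function(truth, map) {
  purrr::map_dfr(rownames(truth), function(h) {
    purrr::map_dfr(unique(map$chrom), function(ch) {
      idx <- which(map$chrom == ch)
      lab <- truth[h, idx]
      pos <- map$pos_bp[idx]
      runs <- rle(lab)
      ends_i <- cumsum(runs$lengths)
      starts_i <- ends_i - runs$lengths + 1
      # boundaries at midpoints; first tract starts at 0
      bound <- c(0, floor((pos[-length(pos)] + pos[-1]) / 2), pos[length(pos)] + 1)
      tibble::tibble(
        chrom = ch, hap_id = h,
        start_bp = bound[starts_i], end_bp = bound[ends_i + 1],
        origin = ifelse(runs$values == 1L, "indicine", "taurine")
      )
    })
  })
}
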