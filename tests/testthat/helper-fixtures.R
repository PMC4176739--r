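# Small fixtures built in code, shared across test files.

# minimal map: one chromosome, evenly spaced
toy_map <- function(n_snp, chrom = 1L, spacing_bp = 1000L) {
  tibble::tibble(
    chrom = chrom,
    pos_bp = spacing_bp * seq_len(n_snp),
    snp_id = sprintf("chr%d_snp%d", chrom, seq_len(n_snp)),
    pos_morgan = bp_to_morgans(spacing_bp * seq_len(n_snp))
  )
}

# panel from an explicit haplotype matrix
toy_panel <- function(haps, group = "taurus", map = NULL) {
  haps <- as.matrix(haps)
  n <- nrow(haps) / 2
  hap_panel(
    haps,
    map = map %||% toy_map(ncol(haps)),
    animals = sprintf("an%02d", seq_len(n)),
    group = rep(group, length.out = n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# allele_origin with a hand-set origin matrix (bypasses classification)
toy_allele_origin <- function(panel, origin) {
  origin <- matrix(as.integer(origin), nrow(panel$haps), ncol(panel$haps))
  rownames(origin) <- rownames(panel$haps)
  segs <- define_segments(panel$map, target_size = ncol(panel$haps))
  structure(list(panel = panel, origin = origin, segments = segs),
            class = "allele_origin")
}

# founder-frequency table for direct haplotype simulation
toy_freqs <- function(p_taurus, p_indicus = p_taurus, chrom_length = 0.05) {
  n <- length(p_taurus)
  tibble::tibble(
    chrom = 1L,
    pos_morgan = (seq_len(n) - 0.5) / n * chrom_length,
    pos_bp = as.integer(round(morgans_to_bp(pos_morgan))),
    snp_id = paste0("s", seq_len(n)),
    p_taurus = p_taurus,
    p_indicus = p_indicus
  )
}

# quick simulated dataset for association tests
quick_sim <- function(seed, qtl = NULL, h2 = 0.3, n_t = 150, n_i = 150,
                      n_c = 100, n_chr = 2, m = 300, ...) {
  simulate_population(sim_config(
    n_chromosomes = n_chr, snps_per_chromosome = m,
    n_taurus = n_t, n_indicus = n_i, n_composite = n_c,
    heritability_polygenic = h2, qtl_specs = qtl, seed = seed, ...))
}

# classification pass: segments, frequencies, origins, allele origins
classify_sim <- function(sim, window = 7) {
  segs <- define_segments(sim$panel$map)
  ft <- tabulate_haplotype_frequencies(
    subset_panel(sim$panel, "taurus"), subset_panel(sim$panel, "indicus"), segs)
  org <- segment_origins(sim$panel, ft, segs, window = window)
  assign_allele_origins(sim$panel, org, segs)
}
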