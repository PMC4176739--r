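#' Partition a SNP map into consecutive segments
#'
#' Each chromosome is cut into non-overlapping runs of consecutive SNPs of
#' near-`target_size` length (30 or 31 when the count allows). The number of
#' segments per chromosome is `round(n / target_size)` (at least 1) and the
#' remainder is distributed one SNP at a time to the final segments, so a
#' 92-SNP chromosome at target 30 gives sizes 30, 31, 31 and no undersized
#' terminal fragment survives. A chromosome with fewer than 15 SNPs becomes
#' a single undersized segment with a warning.
#'
#' @param snp_map Tibble with `chrom` and `pos_bp` (sorted).
#' @param target_size Target SNPs per segment (default 30).
#' @return Tibble `chrom`, `seg_id` (global ordinal), `start_idx`, `end_idx`
#'   (global SNP indices, inclusive), `n_snps`.
#' @export
define_segments <- function(snp_map, target_size = 30) {
  stopifnot(target_size >= 1)
  offset <- 0L
  seg_id <- 0L
  out <- purrr::map_dfr(unique(snp_map$chrom), function(ch) {
    n <- sum(snp_map$chrom == ch)
    if (n < target_size) {
      warning(sprintf("chromosome %s has only %d SNPs; single undersized segment",
                      as.character(ch), n))
    }
    k <- max(1L, as.integer(round(n / target_size)))
    base <- n %/% k
    extra <- n - base * k
    sizes <- c(rep(base, k - extra), rep(base + 1L, extra))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    res <- tibble::tibble(
      chrom = ch,
      seg_id = seg_id + seq_len(k),
      start_idx = offset + starts,
      end_idx = offset + ends,
      n_snps = sizes
    )
    offset <<- offset + n
    seg_id <<- seg_id + k
    res
  })
  out
}

# per-haplotype allele strings for one segment (exact string match is the
# haplotype identity; missing alleles make the string NA)
segment_strings <- function(haps, start_idx, end_idx) {
  sub <- haps[, start_idx:end_idx, drop = FALSE]
  s <- do.call(paste0, as.data.frame(sub))
  s[rowSums(is.na(sub)) > 0] <- NA_character_
  s
}

#' Tabulate segment haplotype frequencies in the two reference panels
#'
#' For every segment, every distinct allele string observed in either
#' reference panel gets a frequency pair (share of taurine-panel haplotypes,
#' share of indicine-panel haplotypes); strings absent from one panel get
#' frequency 0 there.
#'
#' @param panel_taurus,panel_indicus Reference [hap_panel()]s (same map).
#' @param segments Segment table from [define_segments()].
#' @return Tibble `seg_id`, `hap_str`, `p_taurus`, `p_indicus`, with
#'   attribute `n_ref = c(taurus, indicus)` haplotype counts.
#' @export
tabulate_haplotype_frequencies <- function(panel_taurus, panel_indicus, segments) {
  stopifnot(nrow(panel_taurus$haps) > 0, nrow(panel_indicus$haps) > 0)
  nt <- nrow(panel_taurus$haps)
  ni <- nrow(panel_indicus$haps)
  tab <- purrr::map_dfr(seq_len(nrow(segments)), function(s) {
    st <- segments$start_idx[s]; en <- segments$end_idx[s]
    str_t <- segment_strings(panel_taurus$haps, st, en)
    str_i <- segment_strings(panel_indicus$haps, st, en)
    ct <- table(str_t[!is.na(str_t)])
    ci <- table(str_i[!is.na(str_i)])
    all_str <- union(names(ct), names(ci))
    tibble::tibble(
      seg_id = segments$seg_id[s],
      hap_str = all_str,
      p_taurus = as.numeric(ct[all_str] %0% 0) / nt,
      p_indicus = as.numeric(ci[all_str] %0% 0) / ni
    )
  })
  attr(tab, "n_ref") <- c(taurus = nt, indicus = ni)
  tab
}

# table lookup returning 0 for absent names
`%0%` <- function(tab, zero) {
  x <- unname(tab)
  x[is.na(x)] <- zero
  x
}

#' Raw probability of indicine origin for one segment haplotype
#'
#' b = p_indicus / (p_indicus + p_taurus), the share of the haplotype's
#' reference-panel occurrences that are indicine. NA when the string is
#' absent from both panels (b undefined).
#'
#' @param freq_table Output of [tabulate_haplotype_frequencies()].
#' @param segment A `seg_id` present in `freq_table`, with segment length
#'   checked against `nchar(haplotype_string)` via the table's strings.
#' @param haplotype_string Allele string ("0"/"1" characters) of the
#'   segment's haplotype.
#' @return b in [0, 1], or NA.
#' @export
raw_origin_probability <- function(freq_table, segment, haplotype_string) {
  rows <- freq_table[freq_table$seg_id == segment, ]
  if (nrow(rows) == 0) stop("unknown segment id: ", segment)
  if (nchar(haplotype_string) != nchar(rows$hap_str[1])) {
    stop("haplotype string length does not match segment length")
  }
  i <- match(haplotype_string, rows$hap_str)
  if (is.na(i)) return(NA_real_)
  b_from_freqs(rows$p_taurus[i], rows$p_indicus[i])
}

b_from_freqs <- function(p_t, p_i) {
  tot <- p_t + p_i
  ifelse(tot > 0, p_i / tot, NA_real_)
}

#' Smooth raw origin probabilities along a chromosome
#'
#' Centred rolling mean over `window` segments (default 7), truncated at
#' chromosome ends; missing raw values are skipped; a position whose whole
#' window is missing gets 0.5 (uninformative).
#'
#' @param raw_b Numeric vector of raw b values for consecutive segments of
#'   one chromosome for one haplotype (NA allowed).
#' @param window Odd window size (default 7).
#' @return Numeric vector of smoothed b, no NAs.
#' @export
smooth_origin_probability <- function(raw_b, window = 7) {
  sm <- rolling_mean_na(raw_b, window)
  sm[is.nan(sm)] <- 0.5
  sm
}

#' Hard origin call from a smoothed b value
#'
#' Indicine iff b > `threshold` (default 0.6), taurine otherwise; the
#' boundary value itself is taurine, reading the classification rule as a
#' strict inequality.
#'
#' @param smoothed_b Numeric vector in [0, 1].
#' @param threshold Classification threshold (default 0.6).
#' @return Character vector "indicine"/"taurine".
#' @export
classify_origin <- function(smoothed_b, threshold = 0.6) {
  stopifnot(all(smoothed_b >= 0 & smoothed_b <= 1))
  ifelse(smoothed_b > threshold, "indicine", "taurine")
}

#' Classify every haplotype segment of a panel by subspecies origin
#'
#' The full local-ancestry pass: per haplotype and segment, look up the
#' segment's allele string in the reference frequency table, compute raw
#' b = p_indicus / (p_indicus + p_taurus), smooth along the chromosome, and
#' call the origin.
#'
#' @param panel [hap_panel()] of the animals to classify.
#' @param freq_table Reference table from [tabulate_haplotype_frequencies()].
#' @param segments Segment table from [define_segments()].
#' @param window Smoothing window (segments, default 7).
#' @param threshold Origin call threshold (default 0.6).
#' @return Tibble `hap_id`, `animal_id`, `chrom`, `seg_id`, `raw_b`,
#'   `smoothed_b`, `label`.
#' @export
segment_origins <- function(panel, freq_table, segments,
                            window = 7, threshold = 0.6) {
  n_hap <- nrow(panel$haps)
  hap_ids <- rownames(panel$haps)
  animal_ids <- rep(panel$animals, each = 2)
  # raw b matrix: haplotypes x segments
  raw <- matrix(NA_real_, n_hap, nrow(segments))
  freq_split <- split(freq_table, freq_table$seg_id)
  for (s in seq_len(nrow(segments))) {
    strs <- segment_strings(panel$haps, segments$start_idx[s], segments$end_idx[s])
    rows <- freq_split[[as.character(segments$seg_id[s])]]
    i <- match(strs, rows$hap_str)
    raw[, s] <- b_from_freqs(rows$p_taurus[i], rows$p_indicus[i])
  }
  sm <- raw
  for (ch in unique(segments$chrom)) {
    cols <- which(segments$chrom == ch)
    for (h in seq_len(n_hap)) {
      sm[h, cols] <- smooth_origin_probability(raw[h, cols], window)
    }
  }
  tibble::tibble(
    hap_id = rep(hap_ids, times = nrow(segments)),
    animal_id = rep(animal_ids, times = nrow(segments)),
    chrom = rep(segments$chrom, each = n_hap),
    seg_id = rep(segments$seg_id, each = n_hap),
    raw_b = as.vector(raw),
    smoothed_b = as.vector(sm),
    label = classify_origin(as.vector(sm), threshold)
  )
}

#' Assign the four origin-by-allele classes to every allele
#'
#' Expands per-segment origin labels to per-SNP, per-haplotype origins and
#' combines them with the allele calls, yielding for every allele one of
#' taurine_A, taurine_B, indicine_A, indicine_B.
#'
#' @param panel [hap_panel()].
#' @param origins Output of [segment_origins()] for this panel.
#' @param segments Segment table used to compute `origins`.
#' @return An `allele_origin` object: list with `panel`, `origin` (matrix
#'   `n_hap x n_snp`, 0 taurine / 1 indicine) and `segments`.
#' @export
assign_allele_origins <- function(panel, origins, segments) {
  n_hap <- nrow(panel$haps)
  lab <- matrix(origins$label, n_hap, nrow(segments))
  stopifnot(identical(origins$hap_id[seq_len(n_hap)], rownames(panel$haps)))
  origin <- matrix(0L, n_hap, ncol(panel$haps))
  for (s in seq_len(nrow(segments))) {
    origin[, segments$start_idx[s]:segments$end_idx[s]] <-
      as.integer(lab[, s] == "indicine")
  }
  rownames(origin) <- rownames(panel$haps)
  structure(list(panel = panel, origin = origin, segments = segments),
            class = "allele_origin")
}

#' @export
print.allele_origin <- function(x, ...) {
  cat(sprintf("<allele_origin> %d haplotypes x %d SNPs; indicine fraction %.3f\n",
              nrow(x$origin), ncol(x$origin), mean(x$origin)))
  invisible(x)
}

#' Tidy per-allele class table
#'
#' @param x An `allele_origin` object.
#' @param ... Unused.
#' @return Tibble `animal_id`, `slot` (paternal/maternal), `snp_id`,
#'   `class` in {taurine_A, taurine_B, indicine_A, indicine_B}. Large for
#'   big panels; meant for inspection and small exports.
#' @export
as_tibble_allele_origin <- function(x, ...) {
  classes <- matrix(
    paste0(ifelse(x$origin == 1L, "indicine_", "taurine_"),
           ifelse(x$panel$haps == 1L, "B", "A")),
    nrow(x$origin))
  classes[is.na(x$panel$haps)] <- NA_character_
  tibble::tibble(
    animal_id = rep(rep(x$panel$animals, each = 2), times = ncol(classes)),
    slot = rep(rep(c("paternal", "maternal"), length(x$panel$animals)),
               times = ncol(classes)),
    snp_id = rep(x$panel$map$snp_id, each = nrow(classes)),
    class = as.vector(classes)
  )
}

#' Per-group indicine fraction and b distribution
#'
#' Summarises classification output the way admixture composition is usually
#' reported: per animal and per group, the fraction of segments labelled
#' indicine, plus a binned histogram of smoothed b values.
#'
#' @param origins Output of [segment_origins()].
#' @param grouping Named character: group per animal id (e.g.
#'   `setNames(panel$group, panel$animals)`).
#' @param bins Number of histogram bins for smoothed b (default 20).
#' @return List with tibbles `per_animal` (`animal_id`, `group`,
#'   `indicine_fraction`), `per_group` (`group`, `indicine_fraction`), and
#'   `b_histogram` (`group`, `bin_mid`, `count`).
#' @export
ancestry_fraction_report <- function(origins, grouping, bins = 20) {
  dat <- dplyr::mutate(origins, group = unname(grouping[animal_id]))
  per_animal <- dat |>
    dplyr::group_by(animal_id, group) |>
    dplyr::summarise(indicine_fraction = mean(label == "indicine"),
                     .groups = "drop")
  per_group <- per_animal |>
    dplyr::group_by(group) |>
    dplyr::summarise(indicine_fraction = mean(indicine_fraction),
                     .groups = "drop")
  brk <- seq(0, 1, length.out = bins + 1)
  b_hist <- dat |>
    dplyr::mutate(bin = cut(smoothed_b, brk, include.lowest = TRUE)) |>
    dplyr::count(group, bin, name = "count") |>
    dplyr::mutate(bin_mid = (brk[as.integer(bin)] + brk[as.integer(bin) + 1]) / 2) |>
    dplyr::select(group, bin_mid, count)
  list(per_animal = per_animal, per_group = per_group, b_histogram = b_hist)
}
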