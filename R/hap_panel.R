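#' Phased haplotype panel
#'
#' The central container of the pipeline: a set of phased diploid genomes over
#' a shared biallelic SNP map. Alleles are stored as a 0/1 integer matrix with
#' one row per haplotype (two consecutive rows per animal: paternal slot then
#' maternal slot) and one column per SNP; 0 is the A allele, 1 the B allele,
#' NA a missing call. The map is a tibble sorted by (chrom, pos_bp) with
#' strictly increasing positions within a chromosome.
#'
#' @param haps Integer/numeric matrix of 0/1/NA calls, `2 * n_animals` rows.
#' @param map Data frame with columns `chrom`, `pos_bp` and optionally
#'   `snp_id` and `pos_morgan`.
#' @param animals Character vector of animal ids (length `nrow(haps) / 2`).
#' @param group Character vector of group labels per animal (e.g. "taurus",
#'   "indicus", "composite").
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, map, animals, group) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  map <- tibble::as_tibble(map)
  if (is.null(map$snp_id)) map$snp_id <- paste0("snp", seq_len(nrow(map)))
  stopifnot(
    nrow(haps) %% 2 == 0,
    length(animals) == nrow(haps) / 2,
    length(group) == length(animals),
    ncol(haps) == nrow(map),
    all(haps %in% c(0L, 1L, NA_integer_))
  )
  ord <- order(map$chrom, map$pos_bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    stop("SNP map must be sorted by (chrom, pos_bp)")
  }
  dup <- unlist(lapply(split(map$pos_bp, map$chrom), function(p) any(diff(p) <= 0)))
  if (any(dup)) stop("positions must be strictly increasing within a chromosome")
  rownames(haps) <- paste0(rep(animals, each = 2), c("_p", "_m"))
  structure(
    list(haps = haps, map = map, animals = as.character(animals),
         group = as.character(group)),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "<hap_panel> %d animals (%d haplotypes) x %d SNPs on %d chromosome(s)\n",
    length(x$animals), nrow(x$haps), ncol(x$haps),
    length(unique(x$map$chrom))
  ))
  tab <- table(x$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) c(length(x$animals), ncol(x$haps))

#' Number of animals / SNPs in a panel
#' @param panel A `hap_panel`.
#' @return Integer count.
#' @export
n_animals <- function(panel) length(panel$animals)

#' @rdname n_animals
#' @export
n_snps <- function(panel) ncol(panel$haps)

#' Combine panels over the same SNP map
#'
#' @param ... `hap_panel` objects sharing an identical map.
#' @return A single `hap_panel` with animals concatenated.
#' @export
bind_panels <- function(...) {
  panels <- list(...)
  stopifnot(length(panels) >= 1)
  map <- panels[[1]]$map
  for (p in panels[-1]) {
    if (!identical(p$map$chrom, map$chrom) || !identical(p$map$pos_bp, map$pos_bp)) {
      stop("panels must share an identical SNP map")
    }
  }
  hap_panel(
    haps = do.call(rbind, lapply(panels, `[[`, "haps")),
    map = map,
    animals = unlist(lapply(panels, `[[`, "animals")),
    group = unlist(lapply(panels, `[[`, "group"))
  )
}

#' Subset a panel by animals
#'
#' @param panel A `hap_panel`.
#' @param keep Logical or integer index over animals, or a group name.
#' @return A `hap_panel` restricted to the selected animals.
#' @export
subset_panel <- function(panel, keep) {
  if (is.character(keep) && length(keep) == 1 && keep %in% panel$group) {
    keep <- panel$group == keep
  }
  idx <- seq_along(panel$animals)[keep]
  hap_rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap_panel(panel$haps[hap_rows, , drop = FALSE], panel$map,
            panel$animals[idx], panel$group[idx])
}

#' Diploid allele counts (number of B alleles per animal per SNP)
#'
#' @param panel A `hap_panel`.
#' @return Integer matrix `n_animals x n_snps` of 0/1/2 counts (NA where
#'   either allele is missing).
#' @export
allele_counts <- function(panel) {
  n <- length(panel$animals)
  pat <- panel$haps[2L * seq_len(n) - 1L, , drop = FALSE]
  mat <- panel$haps[2L * seq_len(n), , drop = FALSE]
  counts <- pat + mat
  rownames(counts) <- panel$animals
  counts
}

#' Tidy view of a panel's SNP map
#' @param panel A `hap_panel`.
#' @return The map tibble with per-SNP B-allele frequency added.
#' @export
snp_info <- function(panel) {
  dplyr::mutate(panel$map, freq_B = colMeans(panel$haps, na.rm = TRUE))
}
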