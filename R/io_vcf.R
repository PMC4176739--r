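# Readers and writers. Coordinate conventions: VCF positions are 1-based;
# internal SNP indices are 1-based columns of the haplotype matrix; tract
# output is 0-based half-open (BED-like).

#' Write a panel as a phased VCF
#'
#' Biallelic sites with REF = A allele, ALT = B allele, GT phased with '|'.
#' Missing alleles become '.'. Plain text (not bgzipped) so files stay
#' inspectable.
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  n <- length(panel$animals)
  pat <- panel$haps[2L * seq_len(n) - 1L, , drop = FALSE]
  mat <- panel$haps[2L * seq_len(n), , drop = FALSE]
  gt_chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(gt_chr(t(pat)), "|", gt_chr(t(mat))), ncol = n)
  body <- cbind(
    as.character(panel$map$chrom), panel$map$pos_bp, panel$map$snp_id,
    "A", "B", ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=origwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$animals), collapse = "\t")
  ), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read phased genotypes into a panel
#'
#' Accepts a VCF with fully phased GT on biallelic records (parsed with
#' vcfR), or the sidecar haplotype-matrix TSV written by
#' [write_hap_matrix_tsv()]. Any unphased genotype ('/') is an error naming
#' the record; multiallelic records are an error; a record duplicating an
#' earlier position is dropped with a warning.
#'
#' @param path Input path (`.vcf` or `.tsv`).
#' @param group Optional named character vector mapping animal id to group;
#'   animals without an entry get group "unknown".
#' @return A [hap_panel()].
#' @export
read_phased_genotypes <- function(path, group = NULL) {
  if (grepl("\\.tsv$", path)) return(read_hap_matrix_tsv(path, group))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {   # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop("multiallelic record at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  unph <- matrix(grepl("/", gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", rownames(gt)[w[1]] %||% w[1],
         " sample ", colnames(gt)[w[2]])
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    warning(sum(dup), " record(s) at duplicated positions dropped")
    gt <- gt[!dup, , drop = FALSE]
    chrom <- chrom[!dup]; pos <- pos[!dup]
    fix <- fix[!dup, , drop = FALSE]
  }
  alle <- function(x, slot) {
    a <- substr(x, c(1, 3)[slot], c(1, 3)[slot])
    suppressWarnings(as.integer(ifelse(a == ".", NA, a)))
  }
  n_snp <- nrow(gt); n_an <- ncol(gt)
  haps <- matrix(NA_integer_, 2L * n_an, n_snp)
  for (i in seq_len(n_an)) {
    haps[2L * i - 1L, ] <- alle(gt[, i], 1L)
    haps[2L * i, ] <- alle(gt[, i], 2L)
  }
  animals <- colnames(gt)
  chrom_num <- suppressWarnings(as.integer(chrom))
  hap_panel(
    haps,
    map = tibble::tibble(
      chrom = if (all(!is.na(chrom_num))) chrom_num else chrom,
      pos_bp = pos, snp_id = fix[, "ID"]),
    animals = animals,
    group = if (is.null(group)) rep("unknown", n_an)
            else unname(group[animals]) %NA% "unknown"
  )
}

`%NA%` <- function(x, fill) { x[is.na(x)] <- fill; x }

#' Write / read the haplotype-matrix sidecar TSV
#'
#' Long-lived plain-text alternative to VCF: map columns (`chrom`, `pos_bp`,
#' `snp_id`) followed by one 0/1 column per haplotype (named
#' `<animal>_p` / `<animal>_m`), with a `#group:` header line carrying the
#' animal-to-group assignment.
#'
#' @param panel A [hap_panel()].
#' @param path File path.
#' @return `path` invisibly (writer); a [hap_panel()] (reader).
#' @export
write_hap_matrix_tsv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#group: ",
                    paste(panel$animals, panel$group, sep = "=", collapse = ",")),
             con)
  df <- cbind(panel$map[, c("chrom", "pos_bp", "snp_id")],
              as.data.frame(t(panel$haps)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_matrix_tsv
#' @param group Optional animal-to-group mapping overriding the header.
#' @export
read_hap_matrix_tsv <- function(path, group = NULL) {
  first <- readLines(path, n = 1)
  header_group <- NULL
  skip <- 0L
  if (startsWith(first, "#group: ")) {
    kv <- strsplit(strsplit(sub("^#group: ", "", first), ",")[[1]], "=")
    header_group <- stats::setNames(vapply(kv, `[`, "", 2),
                                    vapply(kv, `[`, "", 1))
    skip <- 1L
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE)
  hap_cols <- setdiff(names(df), c("chrom", "pos_bp", "snp_id"))
  animals <- unique(sub("_[pm]$", "", hap_cols))
  group <- group %||% header_group
  hap_panel(
    t(as.matrix(df[, hap_cols])),
    map = tibble::as_tibble(df[, c("chrom", "pos_bp", "snp_id")]),
    animals = animals,
    group = if (is.null(group)) rep("unknown", length(animals))
            else unname(group[animals]) %NA% "unknown"
  )
}

#' Write a phenotype table as TSV
#' @param phenotypes Tibble (`animal_id`, `group`, `y`, covariates).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write ancestry tracts as BED-like TSV (0-based half-open)
#' @param tracts Tibble from [truth_tracts()] or equivalent.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tracts_tsv <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# generic TSV writer used by the pipeline
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
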