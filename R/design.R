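# The contrast coding of a single classified allele. Rows are the four
# origin-by-allele classes; columns the seven 0/1 variables:
#   x1 B-allele; x2 indicine-origin; x3 indicine-B (interaction);
#   x4 taurine-A; x5 indicine-A; x6 taurine-B; x7 indicine-B.
CONTRAST_TABLE <- matrix(
  c(0, 0, 0, 1, 0, 0, 0,   # taurine  A
    1, 0, 0, 0, 0, 1, 0,   # taurine  B
    0, 1, 0, 0, 1, 0, 0,   # indicine A
    1, 1, 1, 0, 0, 0, 1),  # indicine B
  nrow = 4, byrow = TRUE,
  dimnames = list(c("taurine_A", "taurine_B", "indicine_A", "indicine_B"),
                  paste0("x", 1:7))
)

#' Contrast coding of one classified allele
#'
#' Maps an (origin, allele) class to the seven 0/1 contrast variables:
#' x1 = B allele, x2 = indicine origin, x3 = indicine B (their product),
#' x4..x7 = one-hot over {taurine A, indicine A, taurine B, indicine B}.
#' By construction x1 = x6 + x7, x2 = x5 + x7, x3 = x7, and exactly one of
#' x4..x7 is 1.
#'
#' @param origin "taurine" or "indicine" (vectorised).
#' @param allele "A" or "B" (vectorised).
#' @return Tibble with columns x1..x7, one row per input allele.
#' @export
encode_allele <- function(origin, allele) {
  key <- paste0(origin, "_", allele)
  bad <- !key %in% rownames(CONTRAST_TABLE)
  if (any(bad)) stop("unknown allele class: ", paste(unique(key[bad]), collapse = ", "))
  tibble::as_tibble(CONTRAST_TABLE[key, , drop = FALSE])
}

#' Contrast coding of a diploid genotype
#'
#' Sums the paternal and maternal allele codings, so each variable counts
#' 0, 1 or 2 alleles of its class in the genotype. Order of the two alleles
#' does not matter.
#'
#' @param origins Character vector of length 2 (origin of each allele).
#' @param alleles Character vector of length 2 ("A"/"B").
#' @return Named numeric vector x1..x7 of summed codes.
#' @export
encode_genotype <- function(origins, alleles) {
  stopifnot(length(origins) == 2, length(alleles) == 2)
  colSums(as.matrix(encode_allele(origins, alleles)))
}

# Per-animal summed contrast counts for every SNP at once. Returns a list of
# six n_animal x n_snp matrices (x3 equals x7 and is not duplicated).
contrast_counts <- function(ao) {
  H <- ao$panel$haps      # 0 = A, 1 = B
  O <- ao$origin          # 0 = taurine, 1 = indicine
  n <- length(ao$panel$animals)
  ip <- 2L * seq_len(n) - 1L
  im <- 2L * seq_len(n)
  sum2 <- function(M) M[ip, , drop = FALSE] + M[im, , drop = FALSE]
  out <- list(
    x1 = sum2(H),
    x2 = sum2(O),
    x4 = sum2((1L - H) * (1L - O)),
    x5 = sum2((1L - H) * O),
    x6 = sum2(H * (1L - O)),
    x7 = sum2(H * O)
  )
  lapply(out, function(M) { rownames(M) <- ao$panel$animals; M })
}

#' Build the per-SNP design matrix for one association model
#'
#' Assembles intercept + covariates + the model's SNP columns, each SNP
#' column being the per-animal sum of the paternal and maternal contrast
#' codes (values 0/1/2). SNP columns that are constant, or collinear with
#' the covariates or earlier SNP columns, are flagged untestable and
#' dropped; a SNP with no testable column is marked untestable as a whole.
#'
#' Model tags: `"conventional"` fits {x1}; `"interaction"` fits {x1,x2,x3};
#' `"reparam"` fits {x2,x6,x7} (same column space as interaction);
#' `"single:xk"` fits one variable xk alone (x3 is identical to x7).
#'
#' @param ao An `allele_origin` object from [assign_allele_origins()].
#' @param snp_index Global SNP column index.
#' @param model_tag Model tag (see above).
#' @param covariates Covariate matrix (n x c) or NULL; an intercept is always
#'   added.
#' @return List: `X` (design matrix), `snp_cols` (names of retained SNP
#'   columns), `dropped` (names dropped), `untestable` (logical).
#' @export
build_design <- function(ao, snp_index, model_tag, covariates = NULL) {
  counts <- contrast_counts(ao)
  vars <- model_variables(model_tag)
  n <- length(ao$panel$animals)
  base <- cbind(`(Intercept)` = rep(1, n), covariates)
  snp_mat <- vapply(vars, function(v) {
    counts[[canonical_variable(v)]][, snp_index]
  }, numeric(n))
  colnames(snp_mat) <- vars
  assemble_design(base, snp_mat)
}

model_variables <- function(model_tag) {
  if (model_tag == "conventional") return("x1")
  if (model_tag == "interaction") return(c("x1", "x2", "x3"))
  if (model_tag == "reparam") return(c("x2", "x6", "x7"))
  if (grepl("^single:x[1-7]$", model_tag)) return(sub("^single:", "", model_tag))
  stop("unknown model tag: ", model_tag)
}

# x3 (indicine-B interaction count) is numerically identical to x7
canonical_variable <- function(v) if (v == "x3") "x7" else v

# drop constant/collinear SNP columns relative to the base columns
assemble_design <- function(base, snp_mat) {
  keep <- logical(ncol(snp_mat))
  X <- base
  for (j in seq_len(ncol(snp_mat))) {
    cand <- cbind(X, snp_mat[, j])
    if (qr(cand)$rank > qr(X)$rank) {
      X <- cand
      colnames(X)[ncol(X)] <- colnames(snp_mat)[j]
      keep[j] <- TRUE
    }
  }
  list(
    X = X,
    snp_cols = colnames(snp_mat)[keep],
    dropped = colnames(snp_mat)[!keep],
    untestable = !any(keep)
  )
}
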