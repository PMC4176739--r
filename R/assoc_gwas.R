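# Shared scan machinery -------------------------------------------------
#
# All three GWAS flavours reduce to generalized least squares with the
# covariance fixed at its null-model REML estimate: whiten the phenotype,
# the covariate block and the per-SNP contrast-count columns, project out
# the covariates once, and solve a small system per SNP. Wald chi-square
# tests (marginal 1 df per coefficient; joint df = number of testable SNP
# columns).

P_FLOOR <- 1e-300  # keep p-values strictly positive

# subset the (allele-origin, phenotype, grm) bundle by breed group
subset_bundle <- function(ao, phenotypes, grm, subset) {
  subset <- match.arg(subset, c("all", "taurus", "indicus", "composite"))
  if (subset == "all") return(list(ao = ao, phenotypes = phenotypes, grm = grm))
  keep <- ao$panel$group == subset
  if (!any(keep)) stop("no animals in subset '", subset, "'")
  idx <- which(keep)
  hap_rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  ao2 <- structure(list(
    panel = subset_panel(ao$panel, idx),
    origin = ao$origin[hap_rows, , drop = FALSE],
    segments = ao$segments
  ), class = "allele_origin")
  ph2 <- phenotypes[match(ao2$panel$animals, phenotypes$animal_id), , drop = FALSE]
  g2 <- if (is.null(grm)) NULL else grm[idx, idx, drop = FALSE]
  list(ao = ao2, phenotypes = ph2, grm = g2)
}

# whitened, covariate-residualized scan context
scan_context <- function(ao, phenotypes, grm, covariates, vars, snp_subset,
                         null_fit = NULL) {
  stopifnot(identical(phenotypes$animal_id, ao$panel$animals))
  null_fit <- null_fit %||% fit_null_model(phenotypes, covariates, grm)
  counts <- contrast_counts(ao)
  snp_subset <- snp_subset %||% seq_len(ncol(ao$panel$haps))
  Bw <- whiten(null_fit, null_fit$X)
  qrB <- qr(Bw)
  Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  yw <- drop(whiten(null_fit, matrix(null_fit$y)))
  yr <- yw - Q %*% crossprod(Q, yw)
  Wv <- lapply(stats::setNames(nm = vars), function(v) {
    M <- whiten(null_fit, counts[[canonical_variable(v)]][, snp_subset, drop = FALSE])
    M - Q %*% crossprod(Q, M)
  })
  list(null_fit = null_fit, yr = drop(yr), Wv = Wv,
       snp_subset = snp_subset, map = ao$panel$map[snp_subset, , drop = FALSE],
       n = length(yw), n_base = qrB$rank)
}

# single-variable GLS across all SNPs at once (fully vectorized)
single_variable_stats <- function(ctx, var) {
  M <- ctx$Wv[[var]]
  css <- colSums(M^2)
  testable <- css > 1e-10 * ctx$n
  b <- se <- z <- rep(NA_real_, ncol(M))
  b[testable] <- colSums(M[, testable, drop = FALSE] * ctx$yr) / css[testable]
  se[testable] <- 1 / sqrt(css[testable])
  z <- b / se
  p <- pmax(stats::pchisq(z^2, 1, lower.tail = FALSE), P_FLOOR)
  tibble::tibble(term = var, estimate = b, se = se, statistic = z,
                 p_value = ifelse(testable, p, NA_real_),
                 testable = testable)
}

# joint fit of several SNP columns for one SNP (small dense solve);
# collinear/constant columns dropped with df reduced
joint_fit_one <- function(S, yr, vars, n) {
  css <- colSums(S^2)
  keep <- css > 1e-10 * n
  S <- S[, keep, drop = FALSE]
  vars_kept <- vars[keep]
  if (ncol(S) > 1) {
    qrS <- qr(S)
    if (qrS$rank < ncol(S)) {
      sel <- qrS$pivot[seq_len(qrS$rank)]
      sel <- sort(sel)
      S <- S[, sel, drop = FALSE]
      vars_kept <- vars_kept[sel]
    }
  }
  k <- ncol(S)
  if (k == 0) {
    return(list(est = NULL, vars = character(0), joint_stat = NA_real_, df = 0L,
                dropped = vars))
  }
  XtX <- crossprod(S)
  Xty <- crossprod(S, yr)
  V <- solve(XtX)
  b <- unname(drop(V %*% Xty))
  se <- unname(sqrt(diag(V)))
  joint <- drop(crossprod(b, XtX %*% b))
  list(est = tibble::tibble(term = vars_kept, estimate = b, se = se,
                            statistic = b / se,
                            p_value = pmax(stats::pchisq((b / se)^2, 1,
                                                         lower.tail = FALSE), P_FLOOR)),
       vars = vars_kept, joint_stat = joint, df = k,
       dropped = setdiff(vars, vars_kept))
}

joint_scan <- function(ctx, vars) {
  n_snp <- length(ctx$snp_subset)
  purrr::map_dfr(seq_len(n_snp), function(j) {
    S <- vapply(vars, function(v) ctx$Wv[[v]][, j], numeric(ctx$n))
    fit <- joint_fit_one(S, ctx$yr, vars, ctx$n)
    if (fit$df == 0) {
      return(tibble::tibble(
        snp_row = j, term = NA_character_, estimate = NA_real_, se = NA_real_,
        statistic = NA_real_, p_value = NA_real_,
        joint_stat = NA_real_, joint_p = NA_real_, joint_df = 0L,
        untestable = TRUE))
    }
    dplyr::mutate(fit$est,
      snp_row = j,
      joint_stat = fit$joint_stat,
      joint_p = pmax(stats::pchisq(fit$joint_stat, fit$df, lower.tail = FALSE),
                     P_FLOOR),
      joint_df = fit$df,
      untestable = FALSE,
      .before = 1)
  })
}

attach_map <- function(res, ctx, model) {
  info <- ctx$map[res$snp_row, c("chrom", "pos_bp", "snp_id")]
  dplyr::bind_cols(info,
                   dplyr::select(res, -snp_row) |>
                     dplyr::mutate(model = model, .before = 1))
}

# Public scans -----------------------------------------------------------

#' Conventional GWAS: regression on the number of B alleles
#'
#' Tests each SNP's B-allele count (0/1/2) under the polygenic mixed model,
#' ignoring subspecies origin; optionally within one breed group.
#'
#' @param ao An `allele_origin` object (only the haplotype calls are used,
#'   so any panel wrapped in one works).
#' @param phenotypes Tibble `animal_id`, `y`, covariate columns; row order
#'   must match the panel.
#' @param subset One of "all", "taurus", "indicus", "composite".
#' @param grm GRM over all animals (subset automatically), or NULL for OLS.
#' @param covariates Covariate column names (default `group` when present
#'   and more than one group is analysed).
#' @param snp_subset Optional integer vector of global SNP indices to test.
#' @param null_fit Optional pre-fitted [fit_null_model()] for these animals
#'   and covariates, reused instead of refitting (the scans share one REML
#'   fit this way).
#' @return Tibble: `chrom`, `pos_bp`, `snp_id`, `model`, `term` ("x1"),
#'   `estimate`, `se`, `statistic`, `p_value`, `testable`.
#' @export
run_conventional_gwas <- function(ao, phenotypes, subset = "all", grm = NULL,
                                  covariates = NULL, snp_subset = NULL,
                                  null_fit = NULL) {
  bd <- subset_bundle(ao, phenotypes, grm, subset)
  covariates <- covariates %||% default_covariates(bd$phenotypes)
  ctx <- scan_context(bd$ao, bd$phenotypes, bd$grm, covariates, "x1", snp_subset,
                      null_fit)
  res <- single_variable_stats(ctx, "x1")
  dplyr::bind_cols(ctx$map[, c("chrom", "pos_bp", "snp_id")],
                   dplyr::mutate(res, model = paste0("conventional:", subset),
                                 .before = 1))
}

default_covariates <- function(phenotypes) {
  if ("group" %in% names(phenotypes) &&
      length(unique(phenotypes$group)) > 1) "group" else character(0)
}

#' Interaction GWAS: allele, origin, and allele-by-origin
#'
#' Fits the three contrasts simultaneously in both parameterisations —
#' {x1 allele, x2 origin, x3 interaction} and the re-parameterisation
#' {x2 origin, x6 allele within taurine, x7 allele within indicine} — which
#' span the same column space, so the joint 3-df statistic is identical.
#' Marginal Wald tests are conditional on the other fitted terms.
#'
#' @inheritParams run_conventional_gwas
#' @return Tibble with one row per SNP per term (x1, x2, x3 from the first
#'   parameterisation; x6, x7 from the second) plus shared `joint_stat`,
#'   `joint_p`, `joint_df`, and `joint_stat_reparam` for the equivalence
#'   check.
#' @export
run_interaction_gwas <- function(ao, phenotypes, grm = NULL,
                                 covariates = NULL, snp_subset = NULL,
                                 null_fit = NULL) {
  covariates <- covariates %||% default_covariates(phenotypes)
  ctx <- scan_context(ao, phenotypes, grm, covariates,
                      c("x1", "x2", "x3", "x6", "x7"), snp_subset, null_fit)
  res1 <- joint_scan(ctx, c("x1", "x2", "x3"))
  res2 <- joint_scan(ctx, c("x2", "x6", "x7"))
  joint_info <- dplyr::distinct(res1, snp_row, joint_stat, joint_p, joint_df,
                                untestable)
  eq <- res2 |>
    dplyr::distinct(snp_row, joint_stat, joint_p) |>
    dplyr::rename(joint_stat_reparam = joint_stat, joint_p_reparam = joint_p)
  out <- dplyr::bind_rows(
    dplyr::select(res1, snp_row, term, estimate, se, statistic, p_value),
    res2 |>
      dplyr::filter(term %in% c("x6", "x7")) |>
      dplyr::select(snp_row, term, estimate, se, statistic, p_value)
  ) |>
    dplyr::left_join(joint_info, by = "snp_row") |>
    dplyr::left_join(eq, by = "snp_row") |>
    dplyr::arrange(snp_row, term)
  attach_map(out, ctx, "interaction")
}

#' Best-variable GWAS: the single most associated contrast
#'
#' Fits each of x1, x2, x4, x5, x6, x7 one at a time (x3 is identical to x7)
#' with the covariates under the polygenic mixed model, and reports per SNP
#' the variable with the smallest marginal p, together with the B-allele
#' frequency overall and within each assigned origin. Ties are broken by the
#' fixed order x1 < x2 < x4 < x5 < x6 < x7.
#'
#' @inheritParams run_conventional_gwas
#' @return Tibble: map columns, `best_variable`, `estimate`, `se`,
#'   `statistic`, `p_value`, `n_testable`, `freq_B_all`, `freq_B_taurine`,
#'   `freq_B_indicine`.
#' @export
run_best_variable_gwas <- function(ao, phenotypes, grm = NULL,
                                   covariates = NULL, snp_subset = NULL,
                                   null_fit = NULL) {
  vars <- c("x1", "x2", "x4", "x5", "x6", "x7")
  covariates <- covariates %||% default_covariates(phenotypes)
  ctx <- scan_context(ao, phenotypes, grm, covariates, vars, snp_subset,
                      null_fit)
  per_var <- purrr::map_dfr(vars, function(v) {
    dplyr::mutate(single_variable_stats(ctx, v), snp_row = dplyr::row_number())
  })
  best <- per_var |>
    dplyr::filter(testable) |>
    dplyr::group_by(snp_row) |>
    dplyr::slice_min(p_value, n = 1, with_ties = TRUE) |>
    dplyr::slice(1) |>   # fixed variable order breaks exact ties
    dplyr::ungroup()
  n_testable <- per_var |>
    dplyr::group_by(snp_row) |>
    dplyr::summarise(n_testable = sum(testable), .groups = "drop")
  fr <- allele_frequency_by_origin(ao, ctx$snp_subset)
  all_rows <- tibble::tibble(snp_row = seq_along(ctx$snp_subset))
  out <- all_rows |>
    dplyr::left_join(best, by = "snp_row") |>
    dplyr::left_join(n_testable, by = "snp_row") |>
    dplyr::rename(best_variable = term) |>
    dplyr::select(snp_row, best_variable, estimate, se, statistic, p_value,
                  n_testable) |>
    dplyr::bind_cols(fr)
  attach_map(out, ctx, "best_variable")
}

#' Per-SNP B-allele frequencies overall and within assigned origin
#'
#' @param ao An `allele_origin` object.
#' @param snp_subset Optional global SNP indices.
#' @return Tibble `freq_B_all`, `freq_B_taurine`, `freq_B_indicine` (NA
#'   where an origin has no alleles at the SNP).
#' @export
allele_frequency_by_origin <- function(ao, snp_subset = NULL) {
  idx <- snp_subset %||% seq_len(ncol(ao$panel$haps))
  H <- ao$panel$haps[, idx, drop = FALSE]
  O <- ao$origin[, idx, drop = FALSE]
  n_tau <- colSums(O == 0L)
  n_ind <- colSums(O == 1L)
  tibble::tibble(
    freq_B_all = colMeans(H, na.rm = TRUE),
    freq_B_taurine = ifelse(n_tau > 0, colSums(H * (O == 0L)) / n_tau, NA_real_),
    freq_B_indicine = ifelse(n_ind > 0, colSums(H * (O == 1L)) / n_ind, NA_real_)
  )
}

#' GLS test of one SNP under a fitted null model
#'
#' Single-SNP interface over the same engine the scans use: whitens the
#' design's SNP columns with the null model's cached covariance,
#' residualizes against the whitened covariates, and returns marginal and
#' joint Wald statistics.
#'
#' @param null_fit An `origwas_null` from [fit_null_model()].
#' @param design Output of [build_design()] (the covariate block inside it
#'   is ignored; the null model's own covariates are used).
#' @return Tibble with one row per retained SNP column (`term`, `estimate`,
#'   `se`, `statistic`, `p_value`) plus `joint_stat`, `joint_p`, `joint_df`;
#'   zero-row with attribute `untestable = TRUE` when nothing is testable.
#' @export
test_snp <- function(null_fit, design) {
  snp_cols <- c(design$snp_cols, design$dropped)
  X <- design$X
  snp_part <- X[, colnames(X) %in% design$snp_cols, drop = FALSE]
  Bw <- whiten(null_fit, null_fit$X)
  qrB <- qr(Bw)
  Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  yw <- drop(whiten(null_fit, matrix(null_fit$y)))
  yr <- yw - drop(Q %*% crossprod(Q, yw))
  if (ncol(snp_part) == 0) {
    out <- tibble::tibble(term = character(0), estimate = numeric(0),
                          se = numeric(0), statistic = numeric(0),
                          p_value = numeric(0))
    attr(out, "untestable") <- TRUE
    return(out)
  }
  Sw <- whiten(null_fit, snp_part)
  Sr <- Sw - Q %*% crossprod(Q, Sw)
  fit <- joint_fit_one(Sr, yr, colnames(snp_part), length(yr))
  if (fit$df == 0) {
    out <- tibble::tibble(term = character(0), estimate = numeric(0),
                          se = numeric(0), statistic = numeric(0),
                          p_value = numeric(0))
    attr(out, "untestable") <- TRUE
    return(out)
  }
  out <- dplyr::mutate(fit$est,
    joint_stat = fit$joint_stat,
    joint_p = pmax(stats::pchisq(fit$joint_stat, fit$df, lower.tail = FALSE),
                   P_FLOOR),
    joint_df = fit$df)
  attr(out, "untestable") <- FALSE
  attr(out, "dropped") <- fit$dropped
  out
}
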