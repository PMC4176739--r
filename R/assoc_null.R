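#' Fit the no-SNP polygenic null model by REML
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma_g^2 G) and e ~ N(0, sigma_e^2 I),
#' where G is a genomic relationship matrix (scaled to mean diagonal 1), by
#' restricted maximum likelihood. The GRM is eigendecomposed once and the
#' REML criterion profiled over delta = sigma_e^2 / sigma_g^2 in the rotated
#' space, so the fit is a 1-d optimisation. The resulting covariance is
#' cached (rotation + per-component weights) to let every subsequent SNP test
#' run as generalized least squares with known covariance — the two-stage
#' strategy standard in large GWAS.
#'
#' With `grm = NULL` the model degenerates to ordinary least squares
#' (sigma_g^2 = 0) and the cached whitening is a scalar.
#'
#' @param phenotypes Tibble with columns `animal_id`, `y`, and any covariate
#'   columns.
#' @param covariates Character vector of covariate column names (factors get
#'   treatment coding); default uses `group` when present.
#' @param grm GRM over the same animals (matching order), or NULL.
#' @return An `origwas_null` object with elements `sigma_g`, `sigma_e`, `h2`,
#'   `beta`, `loglik_reml`, and cached whitening components.
#' @export
fit_null_model <- function(phenotypes,
                           covariates = intersect("group", names(phenotypes)),
                           grm = NULL) {
  y <- phenotypes$y
  n <- length(y)
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  X <- covariate_matrix(phenotypes, covariates)
  p <- ncol(X)
  if (n < p + 2) stop("more fixed-effect columns than informative records")

  if (is.null(grm)) {
    fit <- stats::lm.fit(X, y)
    sigma_e <- sum(fit$residuals^2) / (n - p)
    obj <- list(
      sigma_g = 0, sigma_e = sigma_e, h2 = 0, delta = Inf,
      beta = stats::setNames(fit$coefficients, colnames(X)),
      loglik_reml = NA_real_,
      U = NULL, d = NULL, wts = rep(sigma_e, n),
      X = X, y = y, animals = phenotypes$animal_id,
      covariates = covariates
    )
    class(obj) <- "origwas_null"
    return(obj)
  }

  stopifnot(nrow(grm) == n, ncol(grm) == n)
  if (max(abs(grm - t(grm))) > 1e-8) stop("GRM must be symmetric")
  G <- grm / mean(diag(grm))
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(eg$values)) {
    stop("GRM must be positive semi-definite")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  reml <- function(log_delta) {
    w <- d + exp(log_delta)
    XtWX <- crossprod(Xs / w, Xs)
    beta <- solve(XtWX, crossprod(Xs / w, ys))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- d + delta
  XtWX <- crossprod(Xs / w, Xs)
  beta <- drop(solve(XtWX, crossprod(Xs / w, ys)))
  r <- ys - Xs %*% beta
  sigma_g <- sum(r^2 / w) / (n - p)
  sigma_e <- delta * sigma_g
  obj <- list(
    sigma_g = sigma_g, sigma_e = sigma_e,
    h2 = sigma_g / (sigma_g + sigma_e), delta = delta,
    beta = stats::setNames(beta, colnames(X)),
    loglik_reml = opt$objective,
    U = U, d = d, wts = sigma_g * d + sigma_e,
    X = X, y = y, animals = phenotypes$animal_id,
    covariates = covariates
  )
  class(obj) <- "origwas_null"
  obj
}

covariate_matrix <- function(phenotypes, covariates) {
  if (length(covariates) == 0) {
    return(matrix(1, nrow(phenotypes), 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  stats::model.matrix(f, data = phenotypes)
}

# whiten columns: multiply by V^{-1/2} using the cached eigendecomposition
whiten <- function(null_fit, M) {
  M <- as.matrix(M)
  if (is.null(null_fit$U)) {
    return(M / sqrt(null_fit$sigma_e))
  }
  crossprod(null_fit$U, M) / sqrt(null_fit$wts)
}

#' @export
print.origwas_null <- function(x, ...) {
  cat(sprintf(
    "<origwas_null> n = %d; sigma_g^2 = %.4f, sigma_e^2 = %.4f, h2 = %.3f\n",
    length(x$y), x$sigma_g, x$sigma_e, x$h2))
  invisible(x)
}

#' Tidy the null-model fixed effects
#' @param x An `origwas_null` fit.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.origwas_null <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of the null model
#' @param x An `origwas_null` fit.
#' @param ... Unused.
#' @return Tibble with `n`, `sigma_g`, `sigma_e`, `h2`, `loglik_reml`.
#' @export
glance.origwas_null <- function(x, ...) {
  tibble::tibble(n = length(x$y), sigma_g = x$sigma_g, sigma_e = x$sigma_e,
                 h2 = x$h2, loglik_reml = as.numeric(x$loglik_reml))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
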