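#' REML fit of the single-kernel additive mixed model
#'
#' Fits `y = mu + Z a + e` with `a ~ N(0, K sigma_a^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood, where K is a
#' genomic (GBLUP) or pedigree (PBLUP) relationship matrix. The restricted
#' likelihood is profiled over delta = sigma_e^2 / sigma_a^2 using the
#' spectral decomposition of the recorded-subset kernel: after rotating by
#' the eigenvectors the likelihood is a cheap 1-D function of delta,
#' maximised on a 61-point grid over log(delta) in [-10, 10] followed by
#' golden-section refinement. Breeding values for every kernel individual
#' are the BLUP
#' `a_hat = K[all, obs] (K[obs, obs] + delta I)^-1 (y - mu_hat)`.
#'
#' @param y named numeric vector of phenotypes (names = ids); `NA` entries
#'   are treated as unrecorded
#' @param kernel a `relationship_matrix` (or plain symmetric matrix with
#'   dimnames) containing every recorded id
#' @return a `mixed_model_fit`: list with `kind`, `mu`, `sigma_a2`,
#'   `sigma_e2`, `delta`, `h2`, `loglik` (restricted, up to a constant),
#'   `blup` (named vector over all kernel ids), `trained_ids`,
#'   `boundary` flag
#' @export
reml_fit <- function(y, kernel) {
  Kv <- if (inherits(kernel, "relationship_matrix")) kernel$values else kernel
  kind <- if (inherits(kernel, "relationship_matrix")) kernel$kind else "genomic"
  ids <- rownames(Kv)
  if (is.null(ids)) stop("kernel must carry sample ids as dimnames")
  y <- y[!is.na(y)]
  obs <- names(y)
  if (length(obs) < 10) stop("reml_fit requires at least 10 recorded individuals")
  if (!all(obs %in% ids)) stop("recorded ids missing from the kernel")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  Koo <- Kv[obs, obs]
  n <- length(obs)

  eg <- eigen(Koo, symmetric = TRUE)
  lam <- eg$values
  min_lam <- min(lam)
  if (min_lam < -1e-6 * max(abs(lam)))
    stop(sprintf("kernel is not positive semi-definite (min eigenvalue %.3g)",
                 min_lam))
  if (min_lam < 1e-8) lam <- lam + (1e-8 - min_lam)  # tiny ridge repair
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  xr <- drop(crossprod(U, rep(1, n)))

  negloglik <- function(ldelta) {
    delta <- exp(ldelta)
    w <- lam + delta
    xtvx <- sum(xr^2 / w)
    mu <- sum(xr * yr / w) / xtvx
    r <- yr - xr * mu
    s2 <- sum(r^2 / w) / (n - 1)
    if (!is.finite(s2) || s2 <= 0) return(Inf)
    (n - 1) * log(s2) + sum(log(w)) + log(xtvx)
  }
  grid <- seq(-10, 10, length.out = 61)
  vals <- vapply(grid, negloglik, numeric(1))
  if (all(!is.finite(vals))) stop("restricted likelihood is non-finite everywhere")
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(negloglik, c(lo, hi), tol = 1e-8)
  ldelta <- opt$minimum
  boundary <- i0 == 1 || i0 == length(grid)

  delta <- exp(ldelta)
  w <- lam + delta
  xtvx <- sum(xr^2 / w)
  mu <- sum(xr * yr / w) / xtvx
  r <- yr - xr * mu
  sigma_a2 <- sum(r^2 / w) / (n - 1)
  sigma_e2 <- delta * sigma_a2
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  # BLUP for all kernel individuals
  alpha <- U %*% (r / w)                     # (Koo + delta I)^-1 (y - mu)
  blup <- drop(Kv[, obs, drop = FALSE] %*% alpha)
  names(blup) <- ids
  structure(list(kind = kind, mu = mu, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2, delta = delta, h2 = h2,
                 loglik = -0.5 * (opt$objective + (n - 1)),
                 blup = blup, trained_ids = obs, boundary = boundary),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("%s mixed-model REML fit: n = %d\n", x$kind, length(x$trained_ids)))
  cat(sprintf("  mu = %.4f, sigma_a2 = %.4f, sigma_e2 = %.4f, h2 = %.4f%s\n",
              x$mu, x$sigma_a2, x$sigma_e2, x$h2,
              if (x$boundary) " (boundary solution)" else ""))
  invisible(x)
}

#' Narrow-sense heritability of a fit
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`.
#' @param fit a `mixed_model_fit`
#' @return numeric scalar in `[0, 1]`
#' @export
heritability <- function(fit) {
  if (fit$sigma_a2 + fit$sigma_e2 == 0)
    stop("both variance components are zero; heritability is undefined")
  fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2)
}

#' Predict breeding values for individuals with masked phenotypes
#'
#' Refits the REML model on the training records (recorded ids not in
#' `masked_ids`) and returns the BLUP predictions for the masked ids.
#'
#' @param y named phenotype vector (`NA` = unrecorded)
#' @param kernel relationship matrix covering all ids
#' @param masked_ids ids whose phenotypes are withheld
#' @return named numeric vector of predictions for `masked_ids` (attribute
#'   `"fit"` carries the training fit)
#' @export
predict_masked <- function(y, kernel, masked_ids) {
  ids_k <- if (inherits(kernel, "relationship_matrix")) kernel$ids else rownames(kernel)
  if (!all(masked_ids %in% ids_k)) stop("masked ids missing from the kernel")
  y_train <- y
  y_train[names(y_train) %in% masked_ids] <- NA_real_
  if (all(is.na(y_train))) stop("masking removed every recorded phenotype")
  fit <- reml_fit(y_train, kernel)
  out <- if (length(masked_ids) == 0) fit$blup[fit$trained_ids]
         else fit$blup[masked_ids]
  attr(out, "fit") <- fit
  out
}
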