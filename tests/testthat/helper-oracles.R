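# Independent brute-force REML oracle: evaluates the restricted
# -2 log-likelihood by explicit matrix inversion on a dense heritability
# grid, then refines locally. Shares no code with reml_fit (no spectral
# decomposition).
oracle_reml_h2 <- function(y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  nll <- function(h2) {
    delta <- (1 - h2) / h2
    H <- K + diag(delta, n)
    Hi <- solve(H)
    xtx <- drop(t(X) %*% Hi %*% X)
    mu <- drop(t(X) %*% Hi %*% y) / xtx
    r <- y - mu
    s2 <- drop(t(r) %*% Hi %*% r) / (n - 1)
    (n - 1) * log(s2) + as.numeric(determinant(H)$modulus) + log(xtx)
  }
  hs <- seq(0.001, 0.999, by = 0.002)
  v <- vapply(hs, nll, numeric(1))
  i <- which.min(v)
  stats::optimize(nll, c(hs[max(1, i - 1)], hs[min(length(hs), i + 1)]),
                  tol = 1e-9)$minimum
}

# per-site modal imputation baseline
mode_impute <- function(d) {
  modes <- apply(d, 2, function(x) {
    tb <- tabulate(x + 1L, 3L)
    which.max(tb) - 1L
  })
  out <- d
  for (j in seq_len(ncol(d))) out[is.na(d[, j]), j] <- modes[j]
  out
}
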