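#' Genomic relationship matrix (VanRaden method 1)
#'
#' With dosage matrix M (n x m) and sample allele frequencies p_k, the
#' centered matrix is Z = M - 2p (column-wise) and
#' G = Z Z' / c with c = 2 * sum_k p_k (1 - p_k).
#' Monomorphic columns contribute zero to both the numerator and c.
#'
#' @param g a complete [geno_matrix()] (impute first) or a dosage matrix
#' @return a `relationship_matrix`: list with `values` (symmetric n x n),
#'   `ids`, `kind = "genomic"` and the normalisation constant `c`
#' @export
compute_grm <- function(g) {
  M <- if (inherits(g, "geno_matrix")) g$dosages else g
  if (anyNA(M)) stop("compute_grm requires complete genotypes; impute first")
  if (nrow(M) < 2) stop("compute_grm requires at least two samples")
  storage.mode(M) <- "double"
  p <- colMeans(M) / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc == 0)
    stop("all SNPs are monomorphic; the GRM is undefined (c = 0)")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / cc
  relationship_matrix(G, rownames(M), kind = "genomic", c = cc)
}

relationship_matrix <- function(values, ids, kind, c = NA_real_) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, kind = kind, c = c),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals, mean diagonal %.3f\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular recursion in topological order:
#' a_ii = 1 + 0.5 * a(sire_i, dam_i) (the inbreeding term is 0 if either
#' parent is unknown) and a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i)) for j
#' earlier in the order. Founders are unrelated and non-inbred unless prior
#' founder relationships are supplied.
#'
#' @param ped a [pedigree()]
#' @param founder_relationships optional data.frame (`id1`, `id2`, `a`)
#'   of prior additive relationships among founders
#' @return a `relationship_matrix` of kind `"pedigree"`
#' @export
compute_amatrix <- function(ped, founder_relationships = NULL) {
  ord <- ped_topological_order(ped)
  ids <- ped$id[ord]
  sire <- ped$sire[ord]; dam <- ped$dam[ord]
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  A <- matrix(0, n, n)
  diag(A) <- 1
  if (!is.null(founder_relationships)) {
    # founders precede all non-founders in topological order, so priors can
    # be seeded before the recursion reaches any offspring
    fr <- as.data.frame(founder_relationships)
    for (r in seq_len(nrow(fr))) {
      i <- pos[[as.character(fr$id1[r])]]
      j <- pos[[as.character(fr$id2[r])]]
      if (!is.na(sire[i]) || !is.na(dam[i]) ||
          !is.na(sire[j]) || !is.na(dam[j]))
        stop("founder_relationships may only involve founders")
      A[i, j] <- A[j, i] <- fr$a[r]
    }
  }
  for (i in seq_len(n)) {
    si <- if (is.na(sire[i])) 0L else pos[[sire[i]]]
    di <- if (is.na(dam[i])) 0L else pos[[dam[i]]]
    if (si == 0 && di == 0) next   # founder row already seeded
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (si > 0) A[j, si] else rep(0, i - 1)) +
                   (if (di > 0) A[j, di] else rep(0, i - 1)))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  # return in the original pedigree order
  back <- match(ped$id, ids)
  relationship_matrix(A[back, back, drop = FALSE], ped$id, kind = "pedigree")
}

#' KING-robust pairwise kinship
#'
#' For each pair (i, j), over sites where both calls are observed, let
#' N_Aa(i) and N_Aa(j) be the heterozygote counts, N_AaAa the count of
#' sites where both are heterozygous and N_AAaa the count of opposite
#' homozygotes. The between-family KING-robust estimator is
#' phi = (N_AaAa - 2 N_AAaa) / (2 min(N_Aa(i), N_Aa(j)))
#'       + 1/2 - (N_Aa(i) + N_Aa(j)) / (4 min(N_Aa(i), N_Aa(j))).
#' Pairs where the smaller heterozygote count is zero get `phi = NA`
#' (undefined) rather than an error.
#'
#' @param g a [geno_matrix()] (missing calls allowed; sites missing in
#'   either member of a pair are ignored for that pair)
#' @param pairs optional two-column matrix/data.frame of sample ids; by
#'   default all unordered pairs are returned
#' @return data.frame: `id1`, `id2`, `n_sites` (co-observed), `n_het1`,
#'   `n_het2`, `n_hethet`, `n_opphom`, `phi`, `degree`
#' @export
king_kinship <- function(g, pairs = NULL) {
  d <- g$dosages
  n <- nrow(d)
  if (n < 2) stop("king_kinship requires at least two samples")
  obs <- !is.na(d)
  Het <- matrix(0, n, ncol(d)); Het[obs & d == 1L] <- 1
  Hom0 <- matrix(0, n, ncol(d)); Hom0[obs & d == 0L] <- 1
  Hom2 <- matrix(0, n, ncol(d)); Hom2[obs & d == 2L] <- 1
  Obs <- matrix(0, n, ncol(d)); Obs[obs] <- 1
  N_hethet <- tcrossprod(Het)
  N_opphom <- tcrossprod(Hom0, Hom2) + tcrossprod(Hom2, Hom0)
  N_het_i <- tcrossprod(Het, Obs)     # i het, j observed
  N_co <- tcrossprod(Obs)
  ids <- rownames(d)
  if (is.null(pairs)) {
    idx <- which(upper.tri(N_co), arr.ind = TRUE)
    i1 <- idx[, 1]; i2 <- idx[, 2]
  } else {
    pairs <- as.matrix(pairs)
    i1 <- match(pairs[, 1], ids); i2 <- match(pairs[, 2], ids)
    if (anyNA(i1) || anyNA(i2)) stop("pairs reference unknown sample ids")
  }
  lin <- cbind(i1, i2)
  ni <- N_het_i[lin]; nj <- N_het_i[cbind(i2, i1)]
  hh <- N_hethet[lin]; oh <- N_opphom[lin]
  mn <- pmin(ni, nj)
  phi <- ifelse(mn > 0,
                (hh - 2 * oh) / (2 * mn) + 0.5 - (ni + nj) / (4 * mn),
                NA_real_)
  data.frame(id1 = ids[i1], id2 = ids[i2],
             n_sites = N_co[lin],
             n_het1 = ni, n_het2 = nj, n_hethet = hh, n_opphom = oh,
             phi = phi, degree = classify_degree(phi),
             stringsAsFactors = FALSE)
}

#' Classify a kinship coefficient into relationship degrees
#'
#' Half-open bands, closed below: phi >= 0.354 is `"duplicate"` (or self),
#' [0.177, 0.354) `"1st"`, [0.0884, 0.177) `"2nd"`,
#' [0.0442, 0.0884) `"3rd"`, below `"unrelated"`. `NA` stays `NA`.
#'
#' @param phi numeric vector of kinship coefficients
#' @return character vector of degree labels
#' @export
classify_degree <- function(phi) {
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi)
  out[ok & phi >= 0.354] <- "duplicate"
  out[ok & phi >= 0.177 & phi < 0.354] <- "1st"
  out[ok & phi >= 0.0884 & phi < 0.177] <- "2nd"
  out[ok & phi >= 0.0442 & phi < 0.0884] <- "3rd"
  out[ok & phi < 0.0442] <- "unrelated"
  out
}

#' Mantel test between two relationship matrices
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries (diagonal excluded); significance is assessed by simultaneous
#' row/column permutation of the second matrix, with the add-one p-value
#' convention, delegated to [vegan::mantel()].
#'
#' @param m1,m2 `relationship_matrix` objects (or plain symmetric matrices)
#'   over the same individuals in the same order
#' @param n_perm number of permutations (default 999); 0 skips the
#'   permutation test and returns `p = NA`
#' @param seed RNG seed for the permutations
#' @return list with `r` (the Mantel statistic), `n_perm` and `p`
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1L) {
  v1 <- if (inherits(m1, "relationship_matrix")) m1$values else m1
  v2 <- if (inherits(m2, "relationship_matrix")) m2$values else m2
  if (!all(dim(v1) == dim(v2))) stop("matrices must have the same dimension")
  if (nrow(v1) < 3) stop("mantel_test requires at least 3 individuals")
  if (!is.null(rownames(v1)) && !is.null(rownames(v2)) &&
      !identical(rownames(v1), rownames(v2)))
    stop("matrices must cover the same individuals in the same order")
  lt1 <- v1[lower.tri(v1)]; lt2 <- v2[lower.tri(v2)]
  if (stats::sd(lt1) == 0 || stats::sd(lt2) == 0)
    stop("a matrix has a constant lower triangle; correlation is undefined")
  if (n_perm == 0) {
    return(list(r = stats::cor(lt1, lt2), n_perm = 0L, p = NA_real_))
  }
  set.seed(as.integer(seed))
  fit <- vegan::mantel(stats::as.dist(v1), stats::as.dist(v2),
                       method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), n_perm = as.integer(n_perm),
       p = unname(fit$signif))
}
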