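#' SNP quality-control filter
#'
#' Applies the panel QC used for two-generation amplicon data, in this
#' order: (1) minor allele frequency must lie strictly inside
#' `(maf_low, maf_high)` within every generation (MAF computed on
#' non-missing calls only, once, before the call-rate filters);
#' (2) call rate >= `min_call_rate` in the first generation (F0);
#' (3) the survivors are extracted from the second generation (F1) and the
#' call-rate filter applied there. With a single group, the MAF window and
#' call-rate filter apply to that group. Each removed SNP is attributed to
#' the first rule that rejects it.
#'
#' @param g a [geno_matrix()]
#' @param maf_low,maf_high strict MAF bounds (defaults 0.01 and 0.4)
#' @param min_call_rate minimum fraction of non-missing calls (default 0.6)
#' @param generation_labels character vector over samples (e.g. `"F0"` /
#'   `"F1"`), or `NULL` for a single group; the first level in order of
#'   appearance is treated as the parental generation
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (a `qc_report`: per-rule removal counts summing, with `retained`, to
#'   the input variant count)
#' @export
qc_filter <- function(g, maf_low = 0.01, maf_high = 0.4,
                      min_call_rate = 0.6, generation_labels = NULL) {
  d <- g$dosages
  m <- ncol(d)
  n_multi <- attr(g, "n_non_biallelic")
  if (is.null(n_multi)) n_multi <- 0L
  if (is.null(generation_labels)) generation_labels <- rep("all", nrow(d))
  if (length(generation_labels) != nrow(d))
    stop("generation_labels must have one entry per sample")
  gens <- unique(generation_labels)

  maf_of <- function(rows) {
    sub <- d[rows, , drop = FALSE]
    p <- colMeans(sub, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0   # no calls at all: treat as monomorphic
    pmin(p, 1 - p)
  }
  call_rate_of <- function(rows) colMeans(!is.na(d[rows, , drop = FALSE]))

  status <- rep("retained", m)
  for (gen in gens) {
    maf <- maf_of(generation_labels == gen)
    status[status == "retained" & maf <= maf_low] <- "maf_low"
    status[status == "retained" & maf >= maf_high] <- "maf_high"
  }
  cr0 <- call_rate_of(generation_labels == gens[1])
  status[status == "retained" & cr0 < min_call_rate] <- "call_rate_f0"
  if (length(gens) > 1) {
    cr1 <- call_rate_of(generation_labels == gens[2])
    status[status == "retained" & cr1 < min_call_rate] <- "call_rate_f1"
  }
  keep <- which(status == "retained")
  if (length(keep) == 0)
    stop("QC removed every SNP; downstream analyses require a non-empty panel")
  report <- structure(list(
    n_input = m + n_multi,
    non_biallelic = as.integer(n_multi),
    maf_low = sum(status == "maf_low"),
    maf_high = sum(status == "maf_high"),
    call_rate_f0 = sum(status == "call_rate_f0"),
    call_rate_f1 = sum(status == "call_rate_f1"),
    retained = length(keep)
  ), class = "qc_report")
  list(genotypes = subset_geno(g, variants = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat(sprintf("  input variants:   %d\n", x$n_input))
  cat(sprintf("  non-biallelic:    %d\n", x$non_biallelic))
  cat(sprintf("  MAF too low:      %d\n", x$maf_low))
  cat(sprintf("  MAF too high:     %d\n", x$maf_high))
  cat(sprintf("  call rate (F0):   %d\n", x$call_rate_f0))
  cat(sprintf("  call rate (F1):   %d\n", x$call_rate_f1))
  cat(sprintf("  retained:         %d\n", x$retained))
  invisible(x)
}

# Pairwise-complete squared dosage correlation of a block of target sites
# against all sites, via masked cross-products (missing calls in either
# column are dropped pair-by-pair). X: dosages with 0 at missing entries;
# W: 0/1 observation indicator; block: target column indices.
# Returns |block| x m matrix of r^2.
masked_r2_block <- function(X, W, block) {
  Xb <- X[, block, drop = FALSE]
  Wb <- W[, block, drop = FALSE]
  N11 <- crossprod(Wb, W)                 # co-observed counts
  Sx <- crossprod(Xb, W)                  # sum of x_s over co-observed
  Sy <- crossprod(Wb, X)                  # sum of x_t over co-observed
  Sxy <- crossprod(Xb, X)
  Sxx <- crossprod(Xb * Xb, W)
  Syy <- crossprod(Wb, X * X)
  cv <- Sxy - Sx * Sy / N11
  vx <- Sxx - Sx * Sx / N11
  vy <- Syy - Sy * Sy / N11
  r2 <- cv * cv / (vx * vy)
  r2[!is.finite(r2)] <- 0
  r2
}

#' LD-kNNi genotype imputation
#'
#' Imputes every missing call from the k nearest neighbours measured over
#' the sites in strongest linkage disequilibrium with the target site. For
#' a missing call (individual i, site s): the `n_ld_sites` other sites with
#' the highest dosage r-squared with s (pairwise-complete) are selected;
#' the distance from i to each candidate neighbour j (those with an
#' observed call at s) is the Manhattan distance over those sites, skipping
#' coordinates missing in either individual, plus a pseudo-count of 1; the
#' imputed dosage is the value maximising the sum of 1/distance over the k
#' nearest neighbours carrying it. Observed calls are never altered.
#'
#' @param g a [geno_matrix()]
#' @param n_ld_sites number of high-LD sites used for the distance (default
#'   30, the published LD-kNNi default)
#' @param k number of neighbours (default 5, the published default); if
#'   fewer neighbours are available all of them are used
#' @return a complete [geno_matrix()] (no missing calls)
#' @export
ld_knni_impute <- function(g, n_ld_sites = 30, k = 5) {
  d <- g$dosages
  if (!anyNA(d)) return(g)
  n <- nrow(d); m <- ncol(d)
  obs <- !is.na(d)
  zero_sites <- which(colSums(obs) == 0)
  if (length(zero_sites) > 0)
    stop("site(s) with no non-missing calls cannot be imputed: ",
         paste(g$variants$id[utils::head(zero_sites, 5)], collapse = ", "),
         "; drop them (e.g. with qc_filter) first")
  X <- d; X[!obs] <- 0L
  storage.mode(X) <- "double"
  W <- matrix(0, n, m); W[obs] <- 1
  out <- d
  todo_sites <- which(colSums(!obs) > 0)
  L <- min(n_ld_sites, m - 1)

  # top-L LD partners per site needing imputation, computed in blocks
  ld_of <- vector("list", m)
  block_size <- 256L
  for (bs in split(todo_sites, ceiling(seq_along(todo_sites) / block_size))) {
    r2 <- masked_r2_block(X, W, bs)
    for (j in seq_along(bs)) {
      row <- r2[j, ]
      row[bs[j]] <- -Inf
      ld_of[[bs[j]]] <- order(row, decreasing = TRUE)[seq_len(L)]
    }
  }

  for (s in todo_sites) {
    Xl <- d[, ld_of[[s]], drop = FALSE]    # keeps NA for skip-if-missing
    miss_i <- which(!obs[, s])
    cand <- which(obs[, s])
    Xl_cand <- Xl[cand, , drop = FALSE]
    dos_cand <- d[cand, s]
    kk <- min(k, length(cand))
    for (i in miss_i) {
      diffs <- abs(Xl_cand - rep(Xl[i, ], each = length(cand)))
      dist <- rowSums(diffs, na.rm = TRUE) + 1
      nb <- order(dist)[seq_len(kk)]
      w0 <- sum(1 / dist[nb][dos_cand[nb] == 0L])
      w1 <- sum(1 / dist[nb][dos_cand[nb] == 1L])
      w2 <- sum(1 / dist[nb][dos_cand[nb] == 2L])
      out[i, s] <- c(0L, 1L, 2L)[which.max(c(w0, w1, w2))]
    }
  }
  res <- geno_matrix(out, g$variants)
  attr(res, "n_non_biallelic") <- attr(g, "n_non_biallelic")
  res
}

#' Draw replicated random SNP subsets
#'
#' For each requested size, `replicates` independent subsets are drawn
#' uniformly without replacement from the `m_total` variant indices; the
#' whole collection is reproducible from `seed`.
#'
#' @param m_total total number of variants in the parent panel
#' @param sizes vector of subset sizes
#' @param replicates subsets per size (default 10)
#' @param seed RNG seed
#' @return list of `snp_subset` objects: each a list with `size`,
#'   `replicate`, `indices` (sorted, unique) and `seed`
#' @export
sample_snp_subsets <- function(m_total, sizes, replicates = 10, seed = 1L) {
  if (any(sizes > m_total))
    stop("subset size exceeds the number of available SNPs (", m_total, ")")
  if (any(sizes < 1)) stop("subset sizes must be positive")
  set.seed(as.integer(seed))
  out <- list()
  for (sz in sizes) {
    for (r in seq_len(replicates)) {
      out[[length(out) + 1]] <- structure(
        list(size = as.integer(sz), replicate = as.integer(r),
             indices = sort(sample.int(m_total, sz)), seed = as.integer(seed)),
        class = "snp_subset")
    }
  }
  out
}
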