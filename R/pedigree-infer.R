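#' Admixture-model clustering by EM
#'
#' Maximises the binomial admixture likelihood
#' `L = sum_i sum_s [ g_is log(p_is) + (2 - g_is) log(1 - p_is) ]` with
#' `p_is = sum_k q_ik f_ks`, over admixture proportions Q (rows on the
#' simplex) and cluster allele frequencies F (entries in (0, 1)), using
#' multiplicative EM updates from random Dirichlet/uniform starts; several
#' short restarts are run and the best continued to convergence. Entries of
#' `g` that are `NA` are ignored by every update (used for held-out
#' cross-validation masks).
#'
#' @param g a [geno_matrix()] or dosage matrix; `NA` entries are excluded
#'   from the likelihood
#' @param K number of clusters, `2 <= K <= n`
#' @param max_iter maximum EM iterations for the final run
#' @param tol stop when the log-likelihood gain per iteration falls below
#'   this value
#' @param seed RNG seed
#' @param n_restarts random restarts (each run `burn_iter` iterations; the
#'   best is continued)
#' @param burn_iter iterations per restart before selection
#' @param accelerate use squared-extrapolation (SQUAREM-type) acceleration;
#'   a fallback to the plain EM step whenever the extrapolated point does
#'   not improve the likelihood preserves the EM ascent property
#' @param init optional warm start: list with `Q` and `F`
#' @return an `admixture_fit`: list with `K`, `Q` (n x K), `F` (K x m),
#'   `loglik_trace`, `loglik`, `converged`
#' @export
admixture_em <- function(g, K, max_iter = 500, tol = 1e-3, seed = 1L,
                         n_restarts = 3, burn_iter = 25, accelerate = TRUE,
                         init = NULL) {
  G <- if (inherits(g, "geno_matrix")) g$dosages else g
  n <- nrow(G); m <- ncol(G)
  if (K < 2 || K > n) stop("K must satisfy 2 <= K <= n")
  storage.mode(G) <- "double"
  W <- matrix(1, n, m); W[is.na(G)] <- 0
  Gz <- G; Gz[is.na(Gz)] <- 0
  rsw2 <- 2 * rowSums(W)

  clamp <- function(x, lo = 1e-6) pmin(pmax(x, lo), 1 - lo)
  loglik_of <- function(st) {
    P <- clamp(st$Q %*% st$F)
    sum(W * (Gz * log(P) + (2 - Gz) * log(1 - P)))
  }
  em_step <- function(st) {
    P <- clamp(st$Q %*% st$F)
    A <- W * Gz / P
    B <- W * (2 - Gz) / (1 - P)
    QtA <- crossprod(st$Q, A); QtB <- crossprod(st$Q, B)
    Fn <- clamp(st$F * QtA / (st$F * QtA + (1 - st$F) * QtB))
    Qn <- st$Q * (A %*% t(st$F) + B %*% t(1 - st$F)) / rsw2
    Qn <- Qn / rowSums(Qn)
    list(Q = Qn, F = Fn)
  }
  project <- function(st) {
    st$F <- clamp(st$F)
    st$Q <- pmax(st$Q, 1e-9)
    st$Q <- st$Q / rowSums(st$Q)
    st
  }
  # one accelerated cycle (two EM steps + squared extrapolation); returns
  # a state with likelihood >= that of two plain EM steps or falls back
  sq_step <- function(st, ll_old) {
    s1 <- em_step(st)
    s2 <- em_step(s1)
    r_q <- s1$Q - st$Q; r_f <- s1$F - st$F
    v_q <- s2$Q - s1$Q - r_q; v_f <- s2$F - s1$F - r_f
    nr <- sqrt(sum(r_q^2) + sum(r_f^2)); nv <- sqrt(sum(v_q^2) + sum(v_f^2))
    if (nv == 0) return(list(st = s2, ll = loglik_of(s2)))
    alpha <- max(1, nr / nv)
    ex <- project(list(Q = st$Q + 2 * alpha * r_q + alpha^2 * v_q,
                       F = st$F + 2 * alpha * r_f + alpha^2 * v_f))
    ex <- em_step(ex)  # stabilising EM step after extrapolation
    ll_ex <- loglik_of(ex)
    ll_s2 <- loglik_of(s2)
    if (is.finite(ll_ex) && ll_ex >= ll_s2) list(st = ex, ll = ll_ex)
    else list(st = s2, ll = ll_s2)
  }
  random_init <- function() {
    # Dirichlet(1) rows for Q; F around per-site frequencies with noise
    E <- matrix(stats::rexp(n * K), n, K)
    Q <- E / rowSums(E)
    p <- colSums(Gz) / pmax(2 * colSums(W), 1)
    F_ <- clamp(matrix(rep(p, each = K), K, m) +
                  matrix(stats::runif(K * m, -0.2, 0.2), K, m))
    list(Q = Q, F = F_)
  }

  set.seed(as.integer(seed))
  if (is.null(init)) {
    best <- NULL; best_ll <- -Inf
    for (r in seq_len(max(1, n_restarts))) {
      st <- random_init()
      for (it in seq_len(burn_iter)) st <- em_step(st)
      ll <- loglik_of(st)
      if (ll > best_ll) { best <- st; best_ll <- ll }
    }
    st <- best
  } else {
    st <- project(list(Q = init$Q, F = init$F))
  }
  trace <- loglik_of(st)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll_prev <- trace[length(trace)]
    if (accelerate) {
      res <- sq_step(st, ll_prev)
      st <- res$st; ll <- res$ll
    } else {
      st <- em_step(st)
      ll <- loglik_of(st)
    }
    gain <- ll - ll_prev
    trace <- c(trace, ll)
    if (gain < tol && gain > -1e-6) { converged <- TRUE; break }
  }
  rownames(st$Q) <- rownames(G)
  structure(list(K = as.integer(K), Q = st$Q, F = st$F,
                 loglik_trace = trace, loglik = trace[length(trace)],
                 converged = converged),
            class = "admixture_fit")
}

#' Choose the number of admixture clusters by cross-validation
#'
#' Genotype entries are partitioned at random into `folds` masks; for each
#' fold the masked entries are held out (treated as missing during EM) and
#' the held-out error is the mean squared deviation between the masked
#' dosage and its fitted expectation `2 * sum_k q_ik f_ks`. The K with the
#' smallest mean error across folds is selected.
#'
#' @param g a complete [geno_matrix()] or dosage matrix
#' @param K_range candidate cluster counts
#' @param folds number of entry-wise CV folds (default 5)
#' @param seed RNG seed
#' @param ... passed to [admixture_em()]
#' @return list with `K_star` and `cv_error` (named per K)
#' @export
select_K <- function(g, K_range, folds = 5, seed = 1L, ...) {
  G <- if (inherits(g, "geno_matrix")) g$dosages else g
  if (length(K_range) == 0) stop("K_range must be non-empty")
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(G); m <- ncol(G)
  set.seed(as.integer(seed))
  fold_of <- matrix(sample(rep_len(seq_len(folds), n * m)), n, m)
  cv <- stats::setNames(numeric(length(K_range)), K_range)
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      Gm <- G
      mask <- fold_of == f
      Gm[mask] <- NA
      fit <- admixture_em(Gm, K, seed = seed + f, ...)
      pred <- 2 * (fit$Q %*% fit$F)
      errs[f] <- mean((G[mask] - pred[mask])^2, na.rm = TRUE)
    }
    cv[ki] <- mean(errs)
  }
  list(K_star = K_range[which.min(cv)], cv_error = cv)
}

#' Assign offspring to parent pairs from admixture proportions
#'
#' Scores every (dam, sire) pair for each offspring by the Euclidean
#' distance between the offspring's admixture proportions and the midpoint
#' of the two parents' proportions; the best-scoring pair is assigned, and
#' the assignment is flagged ambiguous when the gap to the second-best pair
#' falls below `gap_threshold`.
#'
#' @param fit an `admixture_fit` whose Q covers offspring and parents
#' @param offspring_ids,parent_ids character vectors of ids in `fit$Q`
#' @param parent_sexes named vector (`"M"`/`"F"`) over `parent_ids`
#' @param gap_threshold ambiguity threshold on the L2 score gap
#'   (default 0.05)
#' @return data.frame: `offspring`, `dam`, `sire`, `score`, `second_best`,
#'   `ambiguous`
#' @export
assign_parent_pairs <- function(fit, offspring_ids, parent_ids, parent_sexes,
                                gap_threshold = 0.05) {
  Q <- fit$Q
  miss <- setdiff(c(offspring_ids, parent_ids), rownames(Q))
  if (length(miss) > 0)
    stop("ids missing from the admixture fit: ", paste(utils::head(miss, 5), collapse = ", "))
  sexes <- parent_sexes[parent_ids]
  dams <- parent_ids[sexes == "F"]
  sires <- parent_ids[sexes == "M"]
  if (length(dams) == 0 || length(sires) == 0)
    stop("need at least one dam and one sire")
  pairs <- expand.grid(dam = dams, sire = sires, stringsAsFactors = FALSE)
  Mid <- (Q[pairs$dam, , drop = FALSE] + Q[pairs$sire, , drop = FALSE]) / 2
  Qo <- Q[offspring_ids, , drop = FALSE]
  # squared distances offspring x pairs via expansion
  cross <- Qo %*% t(Mid)
  d2 <- outer(rowSums(Qo^2), rowSums(Mid^2), "+") - 2 * cross
  d <- sqrt(pmax(d2, 0))
  best_i <- apply(d, 1, which.min)
  best <- d[cbind(seq_len(nrow(d)), best_i)]
  second <- vapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]; row[best_i[i]] <- Inf; min(row)
  }, numeric(1))
  data.frame(
    offspring = offspring_ids,
    dam = pairs$dam[best_i],
    sire = pairs$sire[best_i],
    score = best,
    second_best = second,
    ambiguous = (second - best) < gap_threshold,
    stringsAsFactors = FALSE
  )
}

#' Assemble a pedigree from parent kinship and parentage assignments
#'
#' Founders are emitted with unknown parents (optionally grouped into sib
#' families by single-linkage clustering over 1st/2nd-degree kinship
#' calls, reported as an attribute); unambiguous offspring assignments
#' become offspring records. Ambiguous offspring are excluded and listed in
#' the `"excluded"` attribute.
#'
#' @param parent_kinships data.frame from [king_kinship()] over the parents
#' @param assignments data.frame from [assign_parent_pairs()]
#' @param parent_sexes named vector (`"M"`/`"F"`) over all parent ids
#' @param offspring_sexes optional named vector over offspring ids
#'   (default: unknown, recorded as `NA`)
#' @return a [pedigree()] with attributes `"excluded"` (ambiguous offspring
#'   ids) and `"founder_groups"` (named integer vector of sib-group labels)
#' @export
reconstruct_pedigree <- function(parent_kinships, assignments, parent_sexes,
                                 offspring_sexes = NULL) {
  parents <- names(parent_sexes)
  used <- unique(c(assignments$dam, assignments$sire))
  if (!all(used %in% parents))
    stop("assignments reference unknown parent id(s): ",
         paste(setdiff(used, parents), collapse = ", "))
  keep <- !assignments$ambiguous
  excluded <- assignments$offspring[!keep]
  asg <- assignments[keep, , drop = FALSE]
  off_sex <- if (is.null(offspring_sexes)) rep(NA_character_, nrow(asg))
             else unname(offspring_sexes[asg$offspring])
  ped <- pedigree(
    id = c(parents, asg$offspring),
    sire = c(rep(NA, length(parents)), asg$sire),
    dam = c(rep(NA, length(parents)), asg$dam),
    sex = c(unname(parent_sexes), off_sex),
    generation = c(rep("F0", length(parents)), rep("F1", nrow(asg)))
  )
  # single-linkage sib groups among founders from close-kin calls
  close <- parent_kinships[!is.na(parent_kinships$phi) &
                             parent_kinships$degree %in% c("1st", "2nd"), ,
                           drop = FALSE]
  grp <- stats::setNames(seq_along(parents), parents)
  for (r in seq_len(nrow(close))) {
    gi <- grp[[close$id1[r]]]; gj <- grp[[close$id2[r]]]
    if (gi != gj) grp[grp == gj] <- gi
  }
  attr(ped, "excluded") <- excluded
  attr(ped, "founder_groups") <- stats::setNames(match(grp, unique(grp)), parents)
  ped
}
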