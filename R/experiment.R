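#' Replicated k-fold cross-validation scheme
#'
#' Assigns each id to a fold per replicate; folds partition the ids and
#' their sizes differ by at most one.
#'
#' @param ids character vector of recorded ids
#' @param folds folds per replicate (default 10)
#' @param replicates number of independent replicates (default 10)
#' @param seed RNG seed
#' @return a `cv_scheme`: list with `ids`, `folds`, `replicates`, `seed`
#'   and `assignment` (ids x replicates integer matrix of fold indices)
#' @export
cv_scheme <- function(ids, folds = 10, replicates = 10, seed = 1L) {
  if (length(ids) < folds) stop("fewer ids than folds")
  set.seed(as.integer(seed))
  assignment <- vapply(seq_len(replicates), function(r)
    sample(rep_len(seq_len(folds), length(ids))), integer(length(ids)))
  rownames(assignment) <- ids
  structure(list(ids = ids, folds = as.integer(folds),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 assignment = assignment), class = "cv_scheme")
}

#' Cross-validated predictive ability and accuracy
#'
#' Per replicate, the folds rotate as validation sets whose phenotypes are
#' masked; variance components are re-estimated on each training set (see
#' `refit_per_fold`), validation predictions are pooled across the folds,
#' and predictive ability is the Pearson correlation between observed
#' phenotypes and pooled predictions. Prediction accuracy divides ability
#' by the square root of `h2_reference` (the full-data heritability
#' estimate for the same kernel).
#'
#' @param y named phenotype vector (`NA` = unrecorded)
#' @param kernel relationship matrix covering the recorded ids
#' @param scheme a [cv_scheme()] over the recorded ids
#' @param h2_reference heritability used for the accuracy denominator
#' @param refit_per_fold if `FALSE`, variance components are estimated once
#'   on the full data and only the BLUP is recomputed per fold
#' @param per_fold_correlation if `TRUE`, ability is averaged over per-fold
#'   correlations instead of pooled predictions
#' @return list with `ability` (mean), `ability_se`, `accuracy`,
#'   `accuracy_se`, `per_replicate` (data.frame), `predictions` (pooled
#'   predictions of the first replicate)
#' @export
cross_validate <- function(y, kernel, scheme, h2_reference,
                           refit_per_fold = TRUE,
                           per_fold_correlation = FALSE) {
  if (!(h2_reference > 0 && h2_reference <= 1))
    stop("h2_reference must lie in (0, 1]")
  rec <- scheme$ids
  if (!all(rec %in% names(y)) || anyNA(y[rec]))
    stop("cv scheme ids must all be recorded in y")
  fixed_delta_fit <- NULL
  if (!refit_per_fold) fixed_delta_fit <- reml_fit(y[rec], kernel)
  abilities <- numeric(scheme$replicates)
  first_preds <- NULL
  for (r in seq_len(scheme$replicates)) {
    fold <- scheme$assignment[, r]
    preds <- stats::setNames(rep(NA_real_, length(rec)), rec)
    fold_r <- numeric(scheme$folds)
    for (f in seq_len(scheme$folds)) {
      val_ids <- rec[fold == f]
      if (refit_per_fold) {
        preds[val_ids] <- predict_masked(y[rec], kernel, val_ids)
      } else {
        # reuse full-data delta; recompute GLS mean and BLUP on training set
        preds[val_ids] <- blup_with_delta(y[rec], kernel, val_ids,
                                          fixed_delta_fit$delta)
      }
      fold_r[f] <- suppressWarnings(stats::cor(y[val_ids], preds[val_ids]))
    }
    if (stats::sd(preds) == 0) {
      # undefined correlation for this replicate: report NA, keep going
      warning("constant predictions in replicate ", r,
              "; correlation undefined")
      abilities[r] <- NA_real_
    } else {
      abilities[r] <- if (per_fold_correlation) mean(fold_r, na.rm = TRUE)
                      else stats::cor(y[rec], preds)
    }
    if (r == 1) first_preds <- preds
  }
  if (all(is.na(abilities)))
    stop("predictions were constant in every replicate; ability undefined")
  abilities_mean <- mean(abilities, na.rm = TRUE)
  se <- stats::sd(abilities[!is.na(abilities)]) /
    sqrt(sum(!is.na(abilities)))
  list(ability = abilities_mean, ability_se = se,
       accuracy = abilities_mean / sqrt(h2_reference),
       accuracy_se = se / sqrt(h2_reference),
       per_replicate = data.frame(replicate = seq_len(scheme$replicates),
                                  ability = abilities,
                                  accuracy = abilities / sqrt(h2_reference)),
       predictions = first_preds)
}

# BLUP of masked ids at a fixed variance ratio delta (no re-estimation).
blup_with_delta <- function(y, kernel, masked_ids, delta) {
  Kv <- if (inherits(kernel, "relationship_matrix")) kernel$values else kernel
  train <- setdiff(names(y)[!is.na(y)], masked_ids)
  Koo <- Kv[train, train]
  H <- Koo + diag(delta, length(train))
  ones <- rep(1, length(train))
  Hi <- solve(H)
  mu <- drop(crossprod(ones, Hi %*% y[train]) / crossprod(ones, Hi %*% ones))
  drop(Kv[masked_ids, train, drop = FALSE] %*% (Hi %*% (y[train] - mu)))
}

#' Family-mean breeding-value correlation
#'
#' Averages each set of breeding values within full-sib families (identical
#' dam and sire) and returns the Pearson correlation of the family means.
#'
#' @param gebv_a,gebv_b named numeric vectors covering the pedigree's
#'   offspring
#' @param ped a [pedigree()]; individuals with both parents known define
#'   the families
#' @return numeric scalar
#' @export
family_mean_gebv_correlation <- function(gebv_a, gebv_b, ped) {
  off <- ped$id[!is.na(ped$sire) & !is.na(ped$dam)]
  off <- intersect(off, intersect(names(gebv_a), names(gebv_b)))
  fam <- paste(ped$dam[match(off, ped$id)], ped$sire[match(off, ped$id)],
               sep = "x")
  if (length(unique(fam)) < 3)
    stop("family-mean correlation requires at least 3 families")
  ma <- tapply(gebv_a[off], fam, mean)
  mb <- tapply(gebv_b[off], fam, mean)
  stats::cor(ma, mb)
}

#' SNP-density downsampling experiment
#'
#' For the full panel and for `replicates` random subsets at each requested
#' size: builds the GRM, estimates heritability per trait by REML, runs
#' replicated cross-validation (ability; accuracy uses the per-subset
#' full-data heritability as reference), and compares the subset against
#' the full panel via the Pearson correlation of GEBVs, the correlation of
#' family-mean GEBVs (when a pedigree is given) and the Mantel statistic of
#' the two GRMs.
#'
#' @param genotypes complete [geno_matrix()] (full panel)
#' @param phenotypes data.frame `id` + one column per trait (`NA` =
#'   unrecorded)
#' @param traits character vector of trait columns to analyse
#' @param ped optional [pedigree()] for family-mean correlations
#' @param sizes subset sizes (default the 11 sizes 200..4000)
#' @param replicates subsets per size (default 10)
#' @param cv_folds,cv_replicates cross-validation layout (default 10 x 10)
#' @param seed root seed
#' @param n_perm Mantel permutations (0 = statistic only)
#' @return a `density_experiment_result`: list with `rows` (one row per
#'   trait x size x replicate), `aggregates` (mean/sd/se per trait x size)
#'   and `full` (per-trait full-panel fits and CV)
#' @export
run_density_experiment <- function(genotypes, phenotypes, traits,
                                   ped = NULL,
                                   sizes = c(200, 400, 800, 1200, 1600, 2000,
                                             2400, 2800, 3200, 3600, 4000),
                                   replicates = 10,
                                   cv_folds = 10, cv_replicates = 10,
                                   seed = 1L, n_perm = 0) {
  m_total <- ncol(genotypes$dosages)
  if (any(sizes > m_total)) stop("subset size exceeds the panel size")
  G_full <- compute_grm(genotypes)
  y_all <- lapply(traits, function(tr)
    stats::setNames(phenotypes[[tr]], phenotypes$id))
  names(y_all) <- traits

  full_fits <- list(); full_cv <- list(); schemes <- list()
  for (tr in traits) {
    y <- y_all[[tr]]
    rec <- names(y)[!is.na(y)]
    rec <- intersect(rec, G_full$ids)
    schemes[[tr]] <- cv_scheme(rec, cv_folds, cv_replicates,
                               seed = substream_seed(seed, paste0("cv_", tr)))
    fit <- reml_fit(y, G_full)
    full_fits[[tr]] <- fit
    full_cv[[tr]] <- cross_validate(y, G_full, schemes[[tr]], fit$h2)
  }

  subsets <- sample_snp_subsets(m_total, sizes, replicates,
                                seed = substream_seed(seed, "subsets"))
  rows <- list()
  for (ss in subsets) {
    g_sub <- subset_geno(genotypes, variants = ss$indices)
    G_sub <- compute_grm(g_sub)
    mr <- mantel_test(G_sub, G_full, n_perm = n_perm,
                      seed = substream_seed(seed, sprintf("mantel_%d_%d",
                                                          ss$size, ss$replicate)))
    for (tr in traits) {
      y <- y_all[[tr]]
      fit <- reml_fit(y, G_sub)
      cv <- cross_validate(y, G_sub, schemes[[tr]], fit$h2)
      gcor <- stats::cor(fit$blup[G_full$ids], full_fits[[tr]]$blup[G_full$ids])
      fcor <- if (!is.null(ped))
        family_mean_gebv_correlation(fit$blup, full_fits[[tr]]$blup, ped)
      else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, subset_size = ss$size, replicate = ss$replicate,
        h2 = fit$h2,
        predictive_ability = cv$ability,
        prediction_accuracy = cv$accuracy,
        gebv_correlation_vs_full = gcor,
        family_mean_gebv_correlation_vs_full = fcor,
        mantel_r_vs_full = mr$r,
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- do.call(rbind, rows)
  num_cols <- setdiff(names(rows), c("trait", "subset_size", "replicate"))
  key <- rows[, c("trait", "subset_size")]
  agg <- stats::aggregate(rows[num_cols], by = key, FUN = mean)
  sds <- stats::aggregate(rows[num_cols], by = key, FUN = stats::sd)
  ses <- stats::aggregate(rows[num_cols], by = key,
                          FUN = function(v) stats::sd(v) / sqrt(length(v)))
  names(sds)[-(1:2)] <- paste0(num_cols, "_sd")
  names(ses)[-(1:2)] <- paste0(num_cols, "_se")
  aggregates <- merge(merge(agg, sds, by = c("trait", "subset_size")),
                      ses, by = c("trait", "subset_size"))
  aggregates <- aggregates[order(aggregates$trait, aggregates$subset_size), ]
  structure(list(rows = rows, aggregates = aggregates,
                 full = list(fits = full_fits, cv = full_cv),
                 sizes = sizes, replicates = replicates, seed = seed),
            class = "density_experiment_result")
}

#' @export
print.density_experiment_result <- function(x, ...) {
  cat(sprintf("SNP-density experiment: %d sizes x %d replicates x %d trait(s)\n",
              length(x$sizes), x$replicates, length(unique(x$rows$trait))))
  print(utils::head(x$aggregates))
  invisible(x)
}

#' Run the complete analysis pipeline on a synthetic population
#'
#' Chains the stages of a marker-based genomic-selection study: simulate a
#' family-structured population, add genotyping noise, apply SNP QC, impute
#' missing calls by LD-kNNi, reconstruct the pedigree from the markers
#' (KING kinship among parents, admixture-based parentage assignment),
#' estimate heritability and cross-validated predictive ability under both
#' the genomic (GBLUP) and the reconstructed-pedigree (PBLUP) kernel, and
#' optionally run the SNP-density downsampling experiment.
#'
#' @param config a [sim_config()]
#' @param density_sizes subset sizes for the density experiment (`NULL`
#'   skips it)
#' @param density_replicates subsets per size
#' @param cv_folds,cv_replicates cross-validation layout
#' @param admixture_K clusters for parentage assignment. The default,
#'   `round(1.2 * n_parents)`, uses slightly more clusters than parents:
#'   parents drawn from full-sib groups share haplotype lineages, and a few
#'   extra clusters are needed before every parent separates cleanly on its
#'   own axes. Set to a range to select by [select_K()] instead.
#' @param reconstruct if `FALSE`, the true simulated pedigree is used for
#'   PBLUP and family definitions (faster; skips the admixture stage)
#' @param admixture_max_iter EM iteration budget for the parentage stage
#'   (default 60 accelerated cycles; parent separation stabilises well
#'   before full likelihood convergence)
#' @param n_perm Mantel permutations inside the density experiment
#' @return list with all stage outputs and a tidy `summary` data.frame
#' @export
run_full_pipeline <- function(config = sim_config(),
                              density_sizes = NULL,
                              density_replicates = 3,
                              cv_folds = 10, cv_replicates = 2,
                              admixture_K = NULL,
                              reconstruct = TRUE,
                              admixture_max_iter = 60,
                              n_perm = 0) {
  pop <- simulate_population(config)
  gen_labels <- pop$pedigree$generation[match(sample_ids(pop$noisy_genotypes),
                                              pop$pedigree$id)]
  qc <- qc_filter(pop$noisy_genotypes, generation_labels = gen_labels)
  imputed <- ld_knni_impute(qc$genotypes)

  parents <- pop$pedigree$id[pop$pedigree$generation == "F0"]
  offspring <- pop$pedigree$id[pop$pedigree$generation == "F1"]
  parent_sexes <- stats::setNames(pop$pedigree$sex, pop$pedigree$id)[parents]

  if (reconstruct) {
    kin <- king_kinship(subset_geno(imputed, samples = parents))
    K <- if (is.null(admixture_K)) round(1.2 * length(parents)) else admixture_K
    if (length(K) > 1) K <- select_K(imputed, K)$K_star
    # parentage is sensitive to local optima (a poor optimum shows up
    # directly as spurious ambiguity), so this stage uses more random
    # restarts than the admixture_em default
    fit_adm <- admixture_em(imputed, K, max_iter = admixture_max_iter,
                            n_restarts = 6, burn_iter = 30,
                            seed = substream_seed(config$seed, "admixture"))
    asg <- assign_parent_pairs(fit_adm, offspring, parents, parent_sexes)
    off_sexes <- stats::setNames(pop$pedigree$sex, pop$pedigree$id)[offspring]
    ped_used <- reconstruct_pedigree(kin, asg, parent_sexes, off_sexes)
    assignment_rate <- mean(
      asg$dam == pop$pedigree$dam[match(asg$offspring, pop$pedigree$id)] &
      asg$sire == pop$pedigree$sire[match(asg$offspring, pop$pedigree$id)] &
      !asg$ambiguous)
  } else {
    kin <- NULL; asg <- NULL
    ped_used <- pop$pedigree
    assignment_rate <- NA_real_
  }

  G <- compute_grm(imputed)
  A <- compute_amatrix(ped_used)
  traits <- vapply(config$traits, `[[`, character(1), "name")
  summary_rows <- list()
  fits <- list()
  for (tr in traits) {
    y <- stats::setNames(pop$phenotypes[[tr]], pop$phenotypes$id)
    y <- y[names(y) %in% G$ids]
    for (model in c("GBLUP", "PBLUP")) {
      kern <- if (model == "GBLUP") G else A
      y_m <- y[names(y) %in% kern$ids]
      rec <- names(y_m)[!is.na(y_m)]
      if (length(rec) < cv_folds) next
      fit <- reml_fit(y_m, kern)
      sch <- cv_scheme(rec, cv_folds, cv_replicates,
                       seed = substream_seed(config$seed, paste0("cv", tr, model)))
      cv <- cross_validate(y_m, kern, sch, fit$h2)
      fits[[paste(tr, model, sep = "_")]] <- fit
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        trait = tr, model = model, n_recorded = length(rec),
        h2 = fit$h2, ability = cv$ability, ability_se = cv$ability_se,
        accuracy = cv$accuracy, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)

  density <- NULL
  if (!is.null(density_sizes)) {
    density <- run_density_experiment(
      imputed, pop$phenotypes, traits, ped = ped_used,
      sizes = density_sizes, replicates = density_replicates,
      cv_folds = cv_folds, cv_replicates = cv_replicates,
      seed = substream_seed(config$seed, "density"), n_perm = n_perm)
  }
  list(population = pop, qc_report = qc$report, imputed = imputed,
       parent_kinship = kin, assignments = asg, pedigree_used = ped_used,
       assignment_rate = assignment_rate,
       grm = G, amatrix = A, fits = fits, summary = summary,
       density = density, config = config)
}
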