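test_that("sim_config validates its invariants", {
  expect_error(sim_config(maf_low = 0, maf_high = 0.4), "maf_low")
  expect_error(sim_config(maf_low = 0.4, maf_high = 0.1), "maf_low")
  expect_error(sim_config(traits = list(list(name = "X", h2 = 1))),
               "open interval")
  expect_error(sim_config(traits = list(list(name = "X", h2 = 0))),
               "open interval")
  expect_error(sim_config(n_dams = 2, n_sires = 2, n_families = 5,
                          founder_design = data.frame(type = "fullsib", n = 4)),
               "mating grid")
  expect_error(sim_config(offspring_total = 10), "at least n_families")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(genotype_error_rate = -0.1), "genotype_error_rate")
})

test_that("simulation is bit-identical under the same seed", {
  a <- simulate_population(tiny_config(seed = 42))
  b <- simulate_population(tiny_config(seed = 42))
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$noisy_genotypes$dosages, b$noisy_genotypes$dosages)
  expect_identical(as.data.frame(a$pedigree), as.data.frame(b$pedigree))
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("founder generation matches the configured design", {
  fo <- cached("founders_1", simulate_founders(sim_config(n_snps = 1200,
                                                          seed = 1)))
  ped <- fo$pedigree
  expect_equal(nrow(ped), 28)
  expect_true(all(is.na(ped$sire) & is.na(ped$dam)))
  expect_equal(sum(ped$sex == "F"), 9)
  expect_equal(sum(ped$sex == "M"), 19)
  # within-group KING kinship sits in the 1st-degree band for full sibs
  kin <- king_kinship(fo$genotypes)
  grp <- attr(fo$genotypes, "founder_group")
  names(grp) <- ped$id
  same <- grp[kin$id1] == grp[kin$id2]
  design <- sim_config()$founder_design
  fs_groups <- which(design$type == "fullsib")
  fs_pairs <- same & grp[kin$id1] %in% fs_groups
  expect_gt(mean(kin$phi[fs_pairs]), 0.177)
  expect_lt(mean(kin$phi[fs_pairs]), 0.354)
  # half-sib pairs: 2nd-degree band
  hs_groups <- which(design$type == "halfsib")
  hs_pairs <- same & grp[kin$id1] %in% hs_groups
  expect_true(all(kin$phi[hs_pairs] > 0.0442 & kin$phi[hs_pairs] < 0.177))
  # unrelated founders (different full-sib groups) near zero
  diff_fs <- !same & grp[kin$id1] %in% fs_groups & grp[kin$id2] %in% fs_groups
  expect_lt(abs(mean(kin$phi[diff_fs])), 0.05)
})

test_that("degenerate allele-frequency window concentrates realized MAF", {
  cfg <- sim_config(n_snps = 400, n_chromosomes = 4, maf_low = 0.3 - 1e-9,
                    maf_high = 0.3, seed = 5,
                    founder_design = data.frame(type = "fullsib", n = 28))
  fo <- simulate_founders(cfg)
  p <- colMeans(fo$genotypes$dosages) / 2
  maf <- pmin(p, 1 - p)
  # 28 founders from a handful of grandparents: allow 3 binomial SDs on the
  # effective number of independent grandparent haplotypes (4 per group)
  se <- sqrt(0.3 * 0.7 / 4)
  expect_gt(mean(abs(maf - 0.3) <= 3 * se), 0.99)
})

test_that("offspring generation realizes the mating design", {
  pop <- tiny_pop(1)
  off <- pop$pedigree[pop$pedigree$generation == "F1", ]
  expect_equal(nrow(off), 60)
  expect_equal(length(unique(paste(off$dam, off$sire))), 10)
  expect_true(all(table(paste(off$dam, off$sire)) >= 1))
  # study-scale counts
  pop2 <- study_pop(1)
  off2 <- pop2$pedigree[pop2$pedigree$generation == "F1", ]
  expect_equal(nrow(off2), 712)
  expect_equal(length(unique(paste(off2$dam, off2$sire))), 129)
})

test_that("pedigrees are acyclic and sex-consistent by construction", {
  pop <- tiny_pop(1)
  expect_silent(ped_topological_order(pop$pedigree))
  sx <- setNames(pop$pedigree$sex, pop$pedigree$id)
  off <- pop$pedigree[!is.na(pop$pedigree$sire), ]
  expect_true(all(sx[off$sire] == "M"))
  expect_true(all(sx[off$dam] == "F"))
})

test_that("a zero-length chromosome transmits unrecombined haplotypes", {
  cfg <- sim_config(n_snps = 200, n_chromosomes = 1,
                    chromosome_length_cM = 0, n_families = 4,
                    offspring_total = 20,
                    traits = list(list(name = "T", h2 = 0.5, sex = NA,
                                       n_recorded = NA)),
                    seed = 3)
  fo <- simulate_founders(cfg)
  off <- simulate_offspring(fo, cfg)
  Hf <- attr(fo$genotypes, "haplotypes")
  Ho <- attr(off$genotypes, "haplotypes")
  ped <- off$pedigree[off$pedigree$generation == "F1", ]
  fidx <- setNames(seq_len(28), fo$pedigree$id)
  for (i in seq_len(nrow(ped))) {
    for (parent in c(ped$dam[i], ped$sire[i])) {
      pr <- fidx[[parent]]
      gam_rows <- Ho[c(2 * i - 1, 2 * i), , drop = FALSE]
      par_haps <- Hf[c(2 * pr - 1, 2 * pr), , drop = FALSE]
      match_one <- apply(gam_rows, 1, function(gm)
        identical(gm, par_haps[1, ]) || identical(gm, par_haps[2, ]))
      expect_true(any(match_one))
    }
  }
})

test_that("offspring allele frequencies track parental frequencies", {
  pop <- study_pop(1)
  founders <- parent_ids(pop)
  off <- offspring_ids(pop)
  ped <- pop$pedigree
  # parental pooled frequency weighted by per-parent usage
  usage <- table(c(ped$dam[ped$generation == "F1"],
                   ped$sire[ped$generation == "F1"]))
  w <- as.numeric(usage[founders]); w[is.na(w)] <- 0
  pf <- colSums(pop$genotypes$dosages[founders, ] * w) / (2 * sum(w))
  po <- colMeans(pop$genotypes$dosages[off, ]) / 2
  se <- sqrt(pmax(pf * (1 - pf), 1e-4) / (2 * length(off)))
  # Mendelian sampling: parental gametes are drawn once per offspring; the
  # binomial SE bound holds marker-wise
  expect_gt(mean(abs(po - pf) <= 4 * se), 0.95)
})

test_that("trait simulation recovers the configured h2 and slope", {
  r2s <- numeric(6); slopes <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(n_snps = 800, n_chromosomes = 8, seed = s,
                      n_families = 40, offspring_total = 300,
                      traits = list(list(name = "TW", h2 = 0.686, sex = NA,
                                         n_recorded = NA)))
    pop <- simulate_population(cfg)
    y <- pheno_vec(pop, "TW")
    tbv <- pop$true_values$TW$tbv
    rec <- names(y)[!is.na(y)]
    fitlm <- stats::lm(y[rec] ~ tbv[rec])
    slopes[s] <- stats::coef(fitlm)[2]
    r2s[s] <- summary(fitlm)$r.squared
  }
  expect_lt(abs(mean(slopes) - 1), 0.1)
  expect_lt(abs(mean(r2s) - 0.686), 0.08)
})

test_that("trait boundary and null architectures are handled", {
  cfg <- tiny_config()
  cfg$traits <- list(list(name = "X", h2 = 1, sex = NA, n_recorded = NA))
  fo <- simulate_founders(tiny_config())
  off <- simulate_offspring(fo, tiny_config())
  expect_error(simulate_traits(off$genotypes, off$pedigree, cfg),
               "open interval")
  cfg$traits <- list(list(name = "X", h2 = 0.5, sex = NA, n_recorded = NA,
                          n_causal = 0))
  tr <- simulate_traits(off$genotypes, off$pedigree, cfg)
  expect_true(all(tr$true_values$X$tbv == 0))
  expect_false(anyNA(tr$phenotypes$X))
})

test_that("sex-restricted traits are recorded only in the allowed sex", {
  pop <- study_pop(1)
  ped <- pop$pedigree
  y <- pheno_vec(pop, "TW")
  rec <- names(y)[!is.na(y)]
  expect_equal(length(rec), 246)
  expect_true(all(ped$sex[match(rec, ped$id)] == "M"))
})

test_that("genotyping noise has the configured rates and leaves input alone", {
  pop <- tiny_pop(1)
  cfg0 <- tiny_config(seed = 8)
  cfg0$missing_rate <- 0; cfg0$genotype_error_rate <- 0
  clean <- apply_genotyping_noise(pop$genotypes, cfg0)
  expect_identical(clean$dosages, pop$genotypes$dosages)

  cfg1 <- sim_config(n_snps = 4075, missing_rate = 0.1,
                     genotype_error_rate = 0, seed = 4)
  big <- cached("noise_big", {
    fo <- simulate_founders(sim_config(n_snps = 4075, seed = 4,
                                       founder_design = data.frame(
                                         type = "fullsib", n = 28)))
    fo$genotypes
  })
  noisy <- apply_genotyping_noise(big, cfg1)
  expect_lt(abs(mean(is.na(noisy$dosages)) - 0.1), 0.005)
  # original untouched
  expect_false(anyNA(big$dosages))
  cfg_bad <- cfg1; cfg_bad$genotype_error_rate <- 1
  expect_error(apply_genotyping_noise(big, cfg_bad), "genotype_error_rate")
})
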