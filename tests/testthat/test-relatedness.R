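test_that("GRM matches the hand-computed VanRaden toy example", {
  M <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  G <- compute_grm(M)
  expect_equal(G$c, 1)
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2, 2))
})

test_that("duplicate samples give equal diagonal and off-diagonal entries", {
  set.seed(3)
  M <- matrix(sample(0:2, 60, replace = TRUE), 3, 20)
  M <- rbind(M, M[1, ])
  rownames(M) <- c("a", "b", "c", "a_dup")
  storage.mode(M) <- "integer"
  G <- compute_grm(M)$values
  expect_equal(G["a", "a"], G["a_dup", "a_dup"])
  expect_equal(G["a", "a_dup"], G["a", "a"])
})

test_that("GRM rejects degenerate input", {
  expect_error(compute_grm(matrix(1L, 1, 5)), "two samples")
  M <- matrix(2L, 4, 5, dimnames = list(letters[1:4], NULL))
  expect_error(compute_grm(M), "monomorphic")
  M2 <- matrix(c(0L, NA, 1L, 2L), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(compute_grm(M2), "complete")
})

test_that("GRM is PSD with diagonal near 1 + inbreeding on simulated data", {
  pop <- study_pop(1)
  G <- offspring_grm(pop, "study_1")
  ev <- eigen(G$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_lt(abs(mean(diag(G$values)) - 1), 0.05)
})

test_that("full-sib GRM entries centre on the pedigree expectation", {
  # unrelated founders so the pedigree expectation for full sibs is exactly
  # the A-matrix value 0.5; G should agree on average, with strictly
  # positive Mendelian-sampling variance around it
  pop <- cached("unrel_pop", simulate_population(sim_config(
    n_snps = 2000, n_families = 20, offspring_total = 400,
    founder_design = data.frame(type = rep("singleton", 28), n = 1),
    traits = list(list(name = "T", h2 = 0.5, sex = NA, n_recorded = NA)),
    seed = 23)))
  G <- compute_grm(subset_geno(pop$genotypes,
                               samples = offspring_ids(pop)))$values
  A <- compute_amatrix(pop$pedigree)$values
  ped <- pop$pedigree[pop$pedigree$generation == "F1", ]
  fam <- split(ped$id, paste(ped$dam, ped$sire))
  fam <- fam[lengths(fam) >= 2]
  pick <- function(M) unlist(lapply(fam, function(ids) {
    g <- M[ids, ids]; g[upper.tri(g)]
  }))
  g_vals <- pick(G); a_vals <- pick(A)
  expect_equal(mean(a_vals), 0.5, tolerance = 1e-12)
  # with base-population (ancestral) frequencies the Mendelian expectation
  # is exact: full-sib mean relationship 0.5
  p <- pop$founders$ancestral_freq
  M <- pop$genotypes$dosages[offspring_ids(pop), ]
  Zb <- sweep(M, 2, 2 * p)
  Gb <- tcrossprod(Zb) / (2 * sum(p * (1 - p)))
  expect_lt(abs(mean(pick(Gb)) - 0.5), 0.03)
  # in-sample frequencies shift the centring (few, structured founders);
  # the sample-frequency GRM still tracks the pedigree expectation closely
  expect_lt(abs(mean(g_vals) - mean(a_vals)), 0.08)
  expect_gt(stats::var(g_vals), 0)  # Mendelian sampling variance is real
})

test_that("A matrix reproduces hand-worked pedigree relationships", {
  # two unrelated founders
  p0 <- pedigree(c("f1", "f2"), c(NA, NA), c(NA, NA), c("M", "F"),
                 c("F0", "F0"))
  expect_equal(unname(compute_amatrix(p0)$values), diag(2))
  # full sibs: a = 0.5; parent-offspring: a = 0.5
  p1 <- pedigree(c("s", "d", "o1", "o2"), c(NA, NA, "s", "s"),
                 c(NA, NA, "d", "d"), c("M", "F", "M", "F"),
                 c("F0", "F0", "F1", "F1"))
  A <- compute_amatrix(p1)$values
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["s", "o1"], 0.5)
  expect_equal(A["o1", "o1"], 1)
  # offspring of a full-sib mating: diagonal 1 + F = 1.25
  p2 <- pedigree(c("s", "d", "o1", "o2", "x"),
                 c(NA, NA, "s", "s", "o1"),
                 c(NA, NA, "d", "d", "o2"),
                 c("M", "F", "M", "F", "M"),
                 c("F0", "F0", "F1", "F1", "F2"))
  A2 <- compute_amatrix(p2)$values
  expect_equal(A2["x", "x"], 1.25)
})

test_that("A matrix propagates founder relationship priors", {
  p1 <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"),
                 c("M", "F", "M"), c("F0", "F0", "F1"))
  A <- compute_amatrix(p1, founder_relationships = data.frame(
    id1 = "s", id2 = "d", a = 0.5))$values
  expect_equal(A["o", "o"], 1.25)
  expect_equal(A["s", "o"], 0.75)
})

test_that("pedigree cycles are rejected with the offending ids", {
  df <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                   dam = c(NA, NA), sex = c("M", "M"),
                   generation = c("F0", "F0"))
  class(df) <- c("pedigree", "data.frame")
  expect_error(ped_topological_order(df), "cycle")
})

test_that("A is PSD for a simulated multi-generation pedigree", {
  pop <- study_pop(1)
  A <- compute_amatrix(pop$pedigree)$values
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("KING-robust kinship matches direct count substitution", {
  # counts N_Aa(1)=2, N_Aa(2)=4, N_AaAa=2, N_AAaa=0 -> phi = 0.25
  d <- rbind(
    c(1L, 1L, 0L, 0L, 0L, 0L),
    c(1L, 1L, 1L, 1L, 0L, 0L)
  )
  rownames(d) <- c("i", "j")
  # pad with a third sample so the matrix is generic
  d <- rbind(d, c(0L, 0L, 0L, 0L, 0L, 2L))
  rownames(d)[3] <- "k"
  kin <- king_kinship(geno_matrix(d), pairs = cbind("i", "j"))
  expect_equal(kin$n_het1, 2)
  expect_equal(kin$n_het2, 4)
  expect_equal(kin$n_hethet, 2)
  expect_equal(kin$n_opphom, 0)
  expect_equal(kin$phi, 2 / 4 + 1 / 2 - 6 / 8)
  expect_equal(kin$degree, "1st")
})

test_that("phi is exactly 0.5 for duplicate genotypes with hets", {
  set.seed(5)
  x <- sample(0:2, 50, replace = TRUE)
  d <- rbind(a = x, b = x, c = sample(0:2, 50, replace = TRUE))
  storage.mode(d) <- "integer"
  kin <- king_kinship(geno_matrix(d), pairs = cbind("a", "b"))
  expect_equal(kin$phi, 0.5)
  expect_equal(kin$degree, "duplicate")
})

test_that("a pair with zero hets is flagged undefined, not an error", {
  d <- rbind(a = c(0L, 0L, 2L), b = c(0L, 2L, 2L), c = c(1L, 1L, 1L))
  kin <- king_kinship(geno_matrix(d), pairs = cbind("a", "b"))
  expect_true(is.na(kin$phi))
})

test_that("degree classification bands are half-open and total", {
  expect_equal(classify_degree(c(0.5, 0.25, 0.09, 0.05, 0)),
               c("duplicate", "1st", "2nd", "3rd", "unrelated"))
  expect_equal(classify_degree(0.354), "duplicate")
  expect_equal(classify_degree(0.177), "1st")
  expect_equal(classify_degree(0.0884), "2nd")
  expect_equal(classify_degree(0.0442), "3rd")
  expect_true(is.na(classify_degree(NA_real_)))
})

test_that("mantel statistic is 1 against itself and -1 against its negation", {
  set.seed(7)
  m <- matrix(rnorm(36), 6, 6); m <- m + t(m)
  dimnames(m) <- list(letters[1:6], letters[1:6])
  expect_equal(mantel_test(m, m, n_perm = 99)$r, 1)
  expect_equal(mantel_test(m, -m, n_perm = 0)$r, -1)
  expect_error(mantel_test(m, matrix(1, 6, 6)), "constant")
})

test_that("mantel permutation p-values are super-uniform under the null", {
  set.seed(11)
  n <- 12
  rejections <- 0
  n_draws <- 200
  for (i in seq_len(n_draws)) {
    a <- matrix(rnorm(n * n), n, n); a <- a + t(a)
    b <- matrix(rnorm(n * n), n, n); b <- b + t(b)
    p <- mantel_test(a, b, n_perm = 99, seed = i)$p
    if (p <= 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_draws, 0.07)
})

test_that("subset-GRM Mantel correlation grows with SNP count", {
  pop <- study_pop(1)
  g_off <- subset_geno(pop$genotypes, samples = offspring_ids(pop))
  G_full <- offspring_grm(pop, "study_1")
  wins <- 0
  for (r in 1:5) {
    s200 <- sample_snp_subsets(4000, 200, 1, seed = 100 + r)[[1]]
    s4000 <- sample_snp_subsets(4000, 3500, 1, seed = 200 + r)[[1]]
    r200 <- mantel_test(compute_grm(subset_geno(g_off, variants = s200$indices)),
                        G_full, n_perm = 0)$r
    r3500 <- mantel_test(compute_grm(subset_geno(g_off, variants = s4000$indices)),
                         G_full, n_perm = 0)$r
    if (r3500 > r200) wins <- wins + 1
  }
  expect_gte(wins, 5)
})
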