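#' Simulation configuration for a family-structured breeding population
#'
#' Defaults mirror a typical medium-density amplicon genotyping design for a
#' cultured fish population: 28 founders (9 dams, 19 sires) whose internal
#' structure is six full-sib families, two half-sib pairs and one weakly
#' related female; 129 full-sib F1 families totalling 712 offspring; 4075
#' biallelic SNPs with ancestral minor allele frequencies in (0.01, 0.4)
#' spread over 22 chromosomes of 100 cM each; and three polygenic traits --
#' standard length (SL, h2 = 0.538), body weight (BW, h2 = 0.557) and testes
#' weight (TW, h2 = 0.686, males only, 246 recorded).
#'
#' @param n_snps number of SNPs
#' @param n_chromosomes number of chromosomes; SNPs are spread uniformly
#' @param chromosome_length_cM genetic length per chromosome (recycled)
#' @param maf_low,maf_high bounds of the ancestral allele-frequency window;
#'   must satisfy `0 < maf_low < maf_high <= 0.5`
#' @param founder_design data.frame with columns `type`
#'   (`"fullsib"`, `"halfsib"` or `"singleton"`) and `n` (group size)
#'   describing the founder relatedness structure
#' @param n_dams,n_sires founder sex totals used in mating
#' @param n_families number of distinct (dam, sire) full-sib families
#' @param offspring_total total F1 offspring (each family gets at least one)
#' @param traits list of trait specs: each a list with `name`, `h2`
#'   (narrow-sense heritability in (0,1)), `sex` (`"M"`, `"F"` or `NA` for
#'   both), `n_recorded` (number of phenotyped individuals, `NA` = all
#'   eligible), optional `mean`, `n_causal` and `c2` (fraction of the
#'   phenotypic variance contributed by a full-sib-family common
#'   environmental effect; default 0, must satisfy `c2 <= 1 - h2`)
#' @param missing_rate per-call probability a genotype is set missing
#' @param genotype_error_rate per-call probability a non-missing genotype is
#'   replaced by a different value
#' @param seed root RNG seed; every stage derives a named substream from it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_snps = 4075,
                       n_chromosomes = 22,
                       chromosome_length_cM = 100,
                       maf_low = 0.01,
                       maf_high = 0.4,
                       founder_design = default_founder_design(),
                       n_dams = 9,
                       n_sires = 19,
                       n_families = 129,
                       offspring_total = 712,
                       traits = default_traits(),
                       missing_rate = 0.05,
                       genotype_error_rate = 0.005,
                       seed = 1L) {
  if (!(maf_low > 0 && maf_low < maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low < maf_high <= 0.5")
  for (tr in traits) {
    if (!(tr$h2 > 0 && tr$h2 < 1))
      stop("trait '", tr$name, "': h2 must lie in the open interval (0, 1)")
  }
  if (n_families > n_dams * n_sires)
    stop("n_families exceeds the n_dams x n_sires mating grid")
  if (offspring_total < n_families)
    stop("offspring_total must be at least n_families")
  if (!(missing_rate >= 0 && missing_rate < 1))
    stop("missing_rate must lie in [0, 1)")
  if (!(genotype_error_rate >= 0 && genotype_error_rate < 1))
    stop("genotype_error_rate must lie in [0, 1)")
  founder_design <- as.data.frame(founder_design, stringsAsFactors = FALSE)
  if (!all(founder_design$type %in% c("fullsib", "halfsib", "singleton")))
    stop("founder_design types must be fullsib/halfsib/singleton")
  if (any(founder_design$type == "halfsib" & founder_design$n != 2))
    stop("halfsib founder groups must have size 2")
  if (any(founder_design$type == "singleton" & founder_design$n != 1))
    stop("singleton founder groups must have size 1")
  n_founders <- sum(founder_design$n)
  if (n_founders != n_dams + n_sires)
    stop("founder_design totals ", n_founders, " individuals but n_dams + n_sires = ",
         n_dams + n_sires)
  structure(list(
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_cM = rep_len(chromosome_length_cM, n_chromosomes),
    maf_low = maf_low, maf_high = maf_high,
    founder_design = founder_design,
    n_dams = as.integer(n_dams), n_sires = as.integer(n_sires),
    n_families = as.integer(n_families),
    offspring_total = as.integer(offspring_total),
    traits = traits,
    missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_founder_design <- function() {
  data.frame(
    type = c(rep("fullsib", 6), rep("halfsib", 2), "singleton"),
    n = c(4, 4, 4, 4, 4, 3, 2, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_traits <- function() {
  list(
    list(name = "SL", h2 = 0.538, sex = NA, n_recorded = 695, mean = 0, n_causal = NA),
    list(name = "BW", h2 = 0.557, sex = NA, n_recorded = 695, mean = 0, n_causal = NA),
    list(name = "TW", h2 = 0.686, sex = "M", n_recorded = 246, mean = 0, n_causal = NA)
  )
}

# Genetic map: SNPs spread uniformly over chromosomes, positions strictly
# increasing. Physical position is genetic position scaled to ~25 kb/cM.
build_map <- function(config) {
  m <- config$n_snps
  nchr <- config$n_chromosomes
  per_chr <- diff(floor(seq(0, m, length.out = nchr + 1)))
  chrom <- rep(seq_len(nchr), per_chr)
  cM <- unlist(lapply(seq_len(nchr), function(ch) {
    k <- per_chr[ch]
    if (k == 0) return(numeric(0))
    L <- config$chromosome_length_cM[ch]
    seq(0, L, length.out = k + 2)[2:(k + 1)]
  }))
  within_chr <- unlist(lapply(per_chr, seq_len))
  data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(chrom),
    # strictly increasing within a chromosome even for 0-cM maps
    pos = as.integer(round(cM * 25000) + within_chr),
    cM = cM,
    ref = rep(c("A", "C", "G", "T"), length.out = m),
    alt = rep(c("G", "T", "A", "C"), length.out = m),
    stringsAsFactors = FALSE
  )
}

# One meiosis: recombine the two haplotypes of a parent into a gamete.
# Crossover count per chromosome is Poisson(length_cM / 100), positions
# uniform on the chromosome (Haldane, no interference); the starting
# haplotype of each chromosome is chosen at random.
make_gamete <- function(h1, h2, chr_idx, chr_pos, chr_len) {
  gam <- h1
  for (ch in seq_along(chr_idx)) {
    idx <- chr_idx[[ch]]
    if (length(idx) == 0) next
    L <- chr_len[ch]
    k <- stats::rpois(1, L / 100)
    start <- sample.int(2L, 1L)
    if (k == 0) {
      seg <- rep(0L, length(idx))
    } else {
      cx <- sort(stats::runif(k, 0, L))
      seg <- findInterval(chr_pos[[ch]], cx)
    }
    use2 <- ((start + seg) %% 2L) == 0L
    g <- h1[idx]
    g[use2] <- h2[idx][use2]
    gam[idx] <- g
  }
  gam
}

# Random diploid from ancestral frequencies p (linkage equilibrium): two
# independent haplotypes.
hwe_haplotypes <- function(p) {
  rbind(as.integer(stats::runif(length(p)) < p),
        as.integer(stats::runif(length(p)) < p))
}

#' Simulate the founder generation
#'
#' Per-SNP ancestral allele frequencies are drawn uniformly on
#' `(maf_low, maf_high)`; unobserved grandparents are drawn in linkage
#' equilibrium from those frequencies, and the founder groups of
#' `founder_design` are produced from them by Mendelian transmission with
#' recombination, so founder full-sib and half-sib relationships are genuine
#' (grandparents are not emitted). The singleton founder, if present, is
#' made a third-degree relative of the first half-sib pair (its hidden
#' parent is a half-sib of that pair). Sexes are assigned at random subject
#' to the configured dam/sire totals, with the singleton female when the
#' totals allow.
#'
#' @param config a [sim_config()]
#' @return list with elements `genotypes` (a [geno_matrix()] carrying the
#'   phased founder haplotypes as attribute `"haplotypes"`), `pedigree`
#'   (founders with unknown parents), and `ancestral_freq`
#' @export
simulate_founders <- function(config) {
  set.seed(substream_seed(config$seed, "founders"))
  map <- build_map(config)
  m <- config$n_snps
  chr_levels <- unique(map$chrom)
  chr_idx <- lapply(chr_levels, function(ch) which(map$chrom == ch))
  chr_pos <- lapply(chr_idx, function(ix) map$cM[ix])
  chr_len <- config$chromosome_length_cM

  p <- stats::runif(m, config$maf_low, config$maf_high)
  design <- config$founder_design
  n_f <- sum(design$n)

  child_of <- function(hapA, hapB) {
    rbind(make_gamete(hapA[1, ], hapA[2, ], chr_idx, chr_pos, chr_len),
          make_gamete(hapB[1, ], hapB[2, ], chr_idx, chr_pos, chr_len))
  }

  haps <- vector("list", n_f)
  group <- integer(n_f)
  k <- 0L
  first_halfsib_shared <- NULL
  for (gi in seq_len(nrow(design))) {
    ty <- design$type[gi]; ng <- design$n[gi]
    if (ty == "fullsib") {
      gpA <- hwe_haplotypes(p); gpB <- hwe_haplotypes(p)
      for (j in seq_len(ng)) {
        k <- k + 1L; haps[[k]] <- child_of(gpA, gpB); group[k] <- gi
      }
    } else if (ty == "halfsib") {
      shared <- hwe_haplotypes(p)
      if (is.null(first_halfsib_shared)) first_halfsib_shared <- shared
      for (j in seq_len(ng)) {
        other <- hwe_haplotypes(p)
        k <- k + 1L; haps[[k]] <- child_of(shared, other); group[k] <- gi
      }
    } else { # singleton, weakly related to the first half-sib pair
      if (is.null(first_halfsib_shared)) {
        parent1 <- hwe_haplotypes(p)
      } else {
        parent1 <- child_of(first_halfsib_shared, hwe_haplotypes(p))
      }
      parent2 <- hwe_haplotypes(p)
      k <- k + 1L; haps[[k]] <- child_of(parent1, parent2); group[k] <- gi
    }
  }

  # sexes: singleton female (if dam slots remain), remainder a random
  # permutation meeting the configured totals
  sex <- rep(NA_character_, n_f)
  singleton_idx <- which(design$type[group] == "singleton")
  n_d <- config$n_dams; n_s <- config$n_sires
  pool <- c(rep("F", n_d), rep("M", n_s))
  if (length(singleton_idx) > 0 && n_d >= length(singleton_idx)) {
    sex[singleton_idx] <- "F"
    pool <- c(rep("F", n_d - length(singleton_idx)), rep("M", n_s))
  }
  open <- which(is.na(sex))
  sex[open] <- sample(pool)
  if (sum(sex == "F") != n_d || sum(sex == "M") != n_s)
    stop("founder_design cannot satisfy the requested dam/sire totals")

  ids <- sprintf("F0_%02d", seq_len(n_f))
  H <- do.call(rbind, haps)            # (2 n_f) x m phased haplotypes
  dos <- H[seq(1, 2 * n_f, 2), , drop = FALSE] +
         H[seq(2, 2 * n_f, 2), , drop = FALSE]
  rownames(dos) <- ids
  g <- geno_matrix(dos, map)
  attr(g, "haplotypes") <- H
  attr(g, "founder_group") <- group
  ped <- pedigree(ids, NA, NA, sex, "F0")
  list(genotypes = g, pedigree = ped, ancestral_freq = p)
}

#' Simulate the F1 generation by factorial mating of founders
#'
#' `n_families` distinct (dam, sire) pairs are drawn uniformly without
#' replacement from the dam x sire grid; every family receives at least one
#' offspring and the remainder are allocated multinomial-uniform across
#' families. Each offspring is produced by one meiosis per parent
#' (Poisson-Haldane recombination); sex is assigned independently 1:1.
#'
#' @param founders result of [simulate_founders()] (or a list with elements
#'   `genotypes` carrying a `"haplotypes"` attribute and `pedigree`)
#' @param config a [sim_config()]
#' @return list with `genotypes` (offspring only, haplotypes attached) and
#'   `pedigree` (founders plus offspring)
#' @export
simulate_offspring <- function(founders, config) {
  set.seed(substream_seed(config$seed, "meiosis"))
  fped <- founders$pedigree
  H <- attr(founders$genotypes, "haplotypes")
  if (is.null(H)) stop("founder genotypes carry no phased haplotypes")
  map <- founders$genotypes$variants
  chr_levels <- unique(map$chrom)
  chr_idx <- lapply(chr_levels, function(ch) which(map$chrom == ch))
  chr_pos <- lapply(chr_idx, function(ix) map$cM[ix])
  chr_len <- config$chromosome_length_cM

  dams <- fped$id[fped$sex == "F"]
  sires <- fped$id[fped$sex == "M"]
  if (config$n_families > length(dams) * length(sires))
    stop("n_families exceeds the available mating grid")
  grid <- expand.grid(dam = dams, sire = sires, stringsAsFactors = FALSE)
  fam <- grid[sample.int(nrow(grid), config$n_families), , drop = FALSE]
  # at least one offspring per family, remainder multinomial-uniform
  extra <- config$offspring_total - config$n_families
  sizes <- rep(1L, config$n_families)
  if (extra > 0)
    sizes <- sizes + as.integer(stats::rmultinom(
      1, extra, rep(1 / config$n_families, config$n_families)))

  n_off <- config$offspring_total
  m <- nrow(map)
  Hoff <- matrix(0L, 2 * n_off, m)
  off_dam <- character(n_off); off_sire <- character(n_off)
  hap_row <- stats::setNames(seq_len(nrow(fped)), fped$id)
  o <- 0L
  for (f in seq_len(nrow(fam))) {
    di <- hap_row[[fam$dam[f]]]; si <- hap_row[[fam$sire[f]]]
    Hd <- H[c(2 * di - 1, 2 * di), , drop = FALSE]
    Hs <- H[c(2 * si - 1, 2 * si), , drop = FALSE]
    for (j in seq_len(sizes[f])) {
      o <- o + 1L
      Hoff[2 * o - 1, ] <- make_gamete(Hd[1, ], Hd[2, ], chr_idx, chr_pos, chr_len)
      Hoff[2 * o, ]     <- make_gamete(Hs[1, ], Hs[2, ], chr_idx, chr_pos, chr_len)
      off_dam[o] <- fam$dam[f]; off_sire[o] <- fam$sire[f]
    }
  }
  ids <- sprintf("F1_%04d", seq_len(n_off))
  sex <- sample(c("M", "F"), n_off, replace = TRUE)
  dos <- Hoff[seq(1, 2 * n_off, 2), , drop = FALSE] +
         Hoff[seq(2, 2 * n_off, 2), , drop = FALSE]
  rownames(dos) <- ids
  g <- geno_matrix(dos, map)
  attr(g, "haplotypes") <- Hoff
  ped <- pedigree(c(fped$id, ids),
                  c(fped$sire, off_sire),
                  c(fped$dam, off_dam),
                  c(fped$sex, sex),
                  c(fped$generation, rep("F1", n_off)))
  list(genotypes = g, pedigree = ped)
}

#' Simulate polygenic additive traits
#'
#' Implements the generative counterpart of the additive mixed model
#' `y = mu + Z a + e`: per trait, SNP effects are drawn i.i.d. normal on the
#' causal SNPs (default: all SNPs), the true breeding value (TBV) is the
#' centered dosage times the effects, and the residual variance is set from
#' the realized TBV variance so that var(TBV) / var(y) equals the configured
#' h2 in expectation. Sex-restricted traits are recorded only in the allowed
#' sex; when `n_recorded` is set, that many eligible individuals are sampled
#' as phenotyped.
#'
#' @param genotypes a complete (no missing calls) [geno_matrix()]
#' @param ped pedigree providing the sex of each genotyped individual
#' @param config a [sim_config()]
#' @return list with `phenotypes` (data.frame `id` + one column per trait,
#'   `NA` = unrecorded) and `true_values` (list per trait: `tbv` named
#'   vector, `effects`, `mean`, `var_e`)
#' @export
simulate_traits <- function(genotypes, ped, config) {
  set.seed(substream_seed(config$seed, "traits"))
  M <- genotypes$dosages
  if (anyNA(M)) stop("simulate_traits requires complete genotypes")
  ids <- rownames(M)
  sex <- stats::setNames(ped$sex, ped$id)[ids]
  pheno <- data.frame(id = ids, stringsAsFactors = FALSE)
  truth <- list()
  Z <- sweep(M, 2, colMeans(M))
  for (tr in config$traits) {
    if (!(tr$h2 > 0 && tr$h2 < 1))
      stop("trait '", tr$name, "': h2 must lie in the open interval (0, 1)")
    m <- ncol(M)
    n_causal <- if (is.null(tr$n_causal) || is.na(tr$n_causal)) m else tr$n_causal
    eff <- numeric(m)
    if (n_causal > 0) {
      causal <- if (n_causal >= m) seq_len(m) else sort(sample.int(m, n_causal))
      eff[causal] <- stats::rnorm(length(causal))
    }
    tbv <- drop(Z %*% eff)
    v_tbv <- stats::var(tbv)
    mu <- if (is.null(tr$mean)) 0 else tr$mean
    if (n_causal == 0 || v_tbv == 0) {
      var_e <- 1
      tbv <- rep(0, length(tbv))
    } else {
      var_e <- v_tbv * (1 - tr$h2) / tr$h2
    }
    c2 <- if (is.null(tr$c2) || is.na(tr$c2)) 0 else tr$c2
    env <- stats::rnorm(length(tbv), 0, sqrt(var_e))
    if (c2 > 0) {
      # split the environmental variance into a full-sib-family common
      # effect (c2 of the phenotypic variance) and individual noise
      var_p <- v_tbv + var_e
      var_fam <- c2 * var_p
      if (var_fam >= var_e)
        stop("trait '", tr$name, "': c2 must not exceed 1 - h2")
      fam <- paste(ped$dam[match(ids, ped$id)], ped$sire[match(ids, ped$id)])
      fam_eff <- stats::setNames(
        stats::rnorm(length(unique(fam)), 0, sqrt(var_fam)), unique(fam))
      env <- fam_eff[fam] + stats::rnorm(length(tbv), 0, sqrt(var_e - var_fam))
    }
    y <- mu + tbv + env
    eligible <- if (is.null(tr$sex) || is.na(tr$sex)) rep(TRUE, length(ids))
                else sex == tr$sex
    recorded <- eligible
    nr <- tr$n_recorded
    if (!is.null(nr) && !is.na(nr) && nr < sum(eligible)) {
      keep <- sample(which(eligible), nr)
      recorded <- rep(FALSE, length(ids)); recorded[keep] <- TRUE
    }
    y[!recorded] <- NA_real_
    pheno[[tr$name]] <- y
    truth[[tr$name]] <- list(tbv = stats::setNames(tbv, ids), effects = eff,
                             mean = mu, var_e = var_e)
  }
  list(phenotypes = pheno, true_values = truth)
}

#' Add missing calls and genotyping errors
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving call is independently replaced by a random draw from the
#' other two dosage values with probability `genotype_error_rate`. The input
#' object is not modified.
#'
#' @param genotypes a [geno_matrix()]
#' @param config a [sim_config()] supplying the rates and seed
#' @return a new [geno_matrix()]
#' @export
apply_genotyping_noise <- function(genotypes, config) {
  if (!(config$missing_rate >= 0 && config$missing_rate < 1))
    stop("missing_rate must lie in [0, 1)")
  if (!(config$genotype_error_rate >= 0 && config$genotype_error_rate < 1))
    stop("genotype_error_rate must lie in [0, 1)")
  set.seed(substream_seed(config$seed, "noise"))
  d <- genotypes$dosages
  n <- length(d)
  if (config$genotype_error_rate > 0) {
    err <- which(stats::runif(n) < config$genotype_error_rate & !is.na(d))
    if (length(err) > 0) {
      shift <- sample.int(2L, length(err), replace = TRUE)
      d[err] <- (d[err] + shift) %% 3L
    }
  }
  if (config$missing_rate > 0) {
    d[stats::runif(n) < config$missing_rate] <- NA_integer_
  }
  out <- geno_matrix(d, genotypes$variants)
  out
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_founders()],
#' [simulate_offspring()] and [simulate_traits()] (on the clean genotypes),
#' then [apply_genotyping_noise()].
#'
#' @param config a [sim_config()]
#' @return list with `founders`, `genotypes` (clean, founders + offspring),
#'   `noisy_genotypes`, `pedigree`, `phenotypes`, `true_values`
#' @export
simulate_population <- function(config = sim_config()) {
  fo <- simulate_founders(config)
  off <- simulate_offspring(fo, config)
  all_dos <- rbind(fo$genotypes$dosages, off$genotypes$dosages)
  g_all <- geno_matrix(all_dos, fo$genotypes$variants)
  attr(g_all, "haplotypes") <- rbind(attr(fo$genotypes, "haplotypes"),
                                     attr(off$genotypes, "haplotypes"))
  tr <- simulate_traits(off$genotypes, off$pedigree, config)
  noisy <- apply_genotyping_noise(g_all, config)
  list(founders = fo, genotypes = g_all, noisy_genotypes = noisy,
       pedigree = off$pedigree, phenotypes = tr$phenotypes,
       true_values = tr$true_values)
}
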