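# Shared simulated populations, memoised so expensive simulations are run
# once per test session.

.pop_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pop_cache)) assign(key, expr, envir = .pop_cache)
  get(key, envir = .pop_cache)
}

# small fast population for unit tests
tiny_config <- function(seed = 1, ...) {
  sim_config(n_snps = 300, n_chromosomes = 6, n_families = 10,
             offspring_total = 60,
             traits = list(list(name = "T", h2 = 0.6, sex = NA,
                                n_recorded = NA)),
             seed = seed, ...)
}

tiny_pop <- function(seed = 1) {
  cached(paste0("tiny_", seed), simulate_population(tiny_config(seed)))
}

# study-scale population: 28 founders, 129 families, 712 offspring, 4000
# SNPs over 22 chromosomes; traits cover the heritability-recovery grid, a
# male-only high-h2 trait (246 recorded) and an unrestricted h2 = 0.6 trait
study_traits <- list(
  list(name = "T3", h2 = 0.3, sex = NA, n_recorded = NA),
  list(name = "T5", h2 = 0.5, sex = NA, n_recorded = NA),
  list(name = "T7", h2 = 0.7, sex = NA, n_recorded = NA),
  list(name = "TW", h2 = 0.686, sex = "M", n_recorded = 246),
  list(name = "T6", h2 = 0.6, sex = NA, n_recorded = NA)
)

study_pop <- function(seed) {
  cached(paste0("study_", seed), {
    simulate_population(sim_config(n_snps = 4000, seed = seed,
                                   traits = study_traits))
  })
}

offspring_ids <- function(pop) pop$pedigree$id[pop$pedigree$generation == "F1"]
parent_ids <- function(pop) pop$pedigree$id[pop$pedigree$generation == "F0"]

offspring_grm <- function(pop, key) {
  cached(paste0("grm_", key),
         compute_grm(subset_geno(pop$genotypes, samples = offspring_ids(pop))))
}

pheno_vec <- function(pop, trait) {
  stats::setNames(pop$phenotypes[[trait]], pop$phenotypes$id)
}
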