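# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 3-animal pedigree: two founders and their offspring
ped3 <- function() as_pedigree(c("1", "2", "3"), c("0", "0", "1"),
                               c("0", "0", "2"))

# adds animal 4 = sire 1 x dam 3 (inbred: F_4 = 0.25)
ped4 <- function() as_pedigree(c("1", "2", "3", "4"),
                               c("0", "0", "1", "1"),
                               c("0", "0", "2", "3"))

# random valid pedigree: founders plus animals whose parents are drawn from
# earlier animals, occasionally unknown
random_pedigree <- function(n, n_founders = max(2L, round(n / 5)),
                            p_unknown = 0.1) {
  animal <- as.character(seq_len(n))
  sire <- dam <- rep("0", n)
  for (j in (n_founders + 1L):n) {
    pool <- as.character(seq_len(j - 1L))
    sire[j] <- if (stats::runif(1) < p_unknown) "0" else sample(pool, 1L)
    dam[j] <- if (stats::runif(1) < p_unknown) "0" else sample(pool, 1L)
    if (sire[j] != "0" && sire[j] == dam[j] && j > n_founders + 1L)
      dam[j] <- sample(setdiff(pool, sire[j]), 1L)
  }
  as_pedigree(animal, sire, dam)
}

# small simulated dataset shared by module tests
small_sim <- function() cached("small_sim", {
  cfg <- simulation_config(n_founders = 20, n_generations = 2,
                           matings_per_generation = 30, m = 100,
                           h2 = 0.3, w = 0.5, seed = 7L)
  simulate_dataset(cfg)
})

# model-equivalence study dataset: 300-animal pedigree, last 150 genotyped,
# 400 markers, h2 = 0.3, unit record weights
eq_sim <- function() cached("eq_sim", {
  cfg <- simulation_config(n_founders = 50, n_generations = 5,
                           matings_per_generation = 50, m = 400,
                           h2 = 0.3, w = 0.5, seed = 2026L)
  simulate_dataset(cfg, n_genotyped = 150)
})

# Monte Carlo convergence study dataset: 100 genotyped, 300 markers
mc_sim <- function() cached("mc_sim", {
  cfg <- simulation_config(n_founders = 40, n_generations = 2,
                           matings_per_generation = 100, m = 300,
                           h2 = 0.3, w = 0.5, seed = 2026L)
  simulate_dataset(cfg, n_genotyped = 100)
})

# convergence sweep shared by the MC-accuracy and inflation checks
mc_sweep <- function() cached("mc_sweep", {
  sim <- mc_sim()
  sweep_scenarios(sim$Zc, sim$L, sim$A22, sim$pheno, h2 = 0.3,
                  w_values = 0.5, n_mc_values = c(2000L, 8000L, 20000L),
                  seeds = 1:5)
})

min_eigen <- function(M) min(eigen(M, symmetric = TRUE,
                                   only.values = TRUE)$values)
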