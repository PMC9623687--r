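#' Configuration for the synthetic-data generator
#'
#' Defines a random-mating population with discrete generations, unlinked
#' biallelic markers gene-dropped through the pedigree, and a single trait
#' with unit phenotypic variance split between a marker-explained component
#' and a residual polygenic component.
#'
#' @param n_founders Number of unrelated, non-inbred founders (>= 2).
#' @param n_generations Number of discrete offspring generations (0 =
#'   founders only).
#' @param matings_per_generation Offspring produced per generation.
#' @param m Number of markers.
#' @param maf_low,maf_high Founder allele-frequency bounds,
#'   \eqn{0 < low \le high \le 0.5}.
#' @param h2 Heritability in (0,1); \eqn{\sigma_u^2 = h^2},
#'   \eqn{\sigma_e^2 = 1 - h^2}.
#' @param w Residual polygenic proportion in \eqn{[0,1]}.
#' @param mu Overall phenotypic mean.
#' @param seed Integer seed for the whole generation pipeline.
#' @return List of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_founders = 50, n_generations = 3,
                              matings_per_generation = 50, m = 300,
                              maf_low = 0.1, maf_high = 0.5, h2 = 0.3,
                              w = 0.5, mu = 0, seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 0,
            matings_per_generation >= 1, m >= 1,
            maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            h2 > 0, h2 < 1, w >= 0, w <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 matings_per_generation = as.integer(matings_per_generation),
                 m = as.integer(m), maf_low = maf_low, maf_high = maf_high,
                 h2 = h2, w = w, mu = mu, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a random-mating pedigree
#'
#' Founders have unknown parents; each subsequent generation draws a sire
#' and a distinct dam uniformly from the previous generation for every
#' offspring. The result is topologically sorted by construction.
#'
#' @param cfg [simulation_config()].
#' @return A \code{"pedigree"} object.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_founders < 2) stop("need at least 2 founders")
  set.seed(cfg$seed)
  animal <- paste0("A", seq_len(cfg$n_founders))
  sire <- rep("0", cfg$n_founders)
  dam <- rep("0", cfg$n_founders)
  prev <- animal
  counter <- cfg$n_founders
  for (g in seq_len(cfg$n_generations)) {
    kids <- paste0("A", counter + seq_len(cfg$matings_per_generation))
    counter <- counter + cfg$matings_per_generation
    for (k in kids) {
      pair <- sample(prev, 2L)        # sire != dam
      animal <- c(animal, k)
      sire <- c(sire, pair[1L])
      dam <- c(dam, pair[2L])
    }
    prev <- kids
  }
  as_pedigree(animal, sire, dam)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly from
#' \eqn{[maf\_low, maf\_high]} per marker; founder haplotypes are
#' independent Bernoulli draws, and each non-founder inherits one uniformly
#' chosen allele from each parent per marker (unlinked loci, Mendelian
#' sampling). Identity by descent is therefore consistent with the
#' pedigree relationship matrix in expectation. An unknown parent's
#' contribution is drawn from the founder frequencies.
#'
#' @param ped A topologically sorted \code{"pedigree"}.
#' @param cfg [simulation_config()].
#' @return A \code{"genotype_matrix"} of allele counts for all pedigree
#'   animals, with attribute \code{"founder_freq"}.
#' @export
gene_drop_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  m <- cfg$m
  p <- stats::runif(m, cfg$maf_low, cfg$maf_high)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  draw_parent <- function(j) {
    pick <- stats::runif(m) < 0.5
    ifelse(pick, H1[j, ], H2[j, ])
  }
  for (j in seq_len(n)) {
    s <- ped$sire[j]; d <- ped$dam[j]
    H1[j, ] <- if (s == "0") stats::rbinom(m, 1L, p) else draw_parent(idx[s])
    H2[j, ] <- if (d == "0") stats::rbinom(m, 1L, p) else draw_parent(idx[d])
  }
  M <- H1 + H2
  storage.mode(M) <- "integer"
  dimnames(M) <- list(ped$animal, paste0("m", seq_len(m)))
  structure(M, founder_freq = p, n_imputed = 0L,
            class = c("genotype_matrix", "matrix", "array"))
}

#' Simulate phenotypes and true breeding values
#'
#' True genetic values follow the marker-plus-polygenic model:
#' \deqn{u = \sigma_u (\sqrt{1-w}\, Z_c g + \sqrt{w}\, L a),}
#' with g, a standard normal, \eqn{\sigma_u^2 = h^2}, and
#' \eqn{y = \mu + u + e}, \eqn{e \sim N(0, (1-h^2) I)} — unit phenotypic
#' variance in expectation.
#'
#' @param Zc Centered/scaled marker matrix of the genotyped animals.
#' @param L Lower Cholesky factor of their \eqn{A_{22}}.
#' @param cfg [simulation_config()].
#' @return List with \code{pheno} ([phenotype_data()], weight 1) and
#'   \code{true_u} (named vector of true genetic values).
#' @export
simulate_phenotypes <- function(Zc, L, cfg) {
  stopifnot(inherits(cfg, "simulation_config"), nrow(Zc) == nrow(L))
  set.seed(cfg$seed + 2L)
  n <- nrow(Zc)
  m <- ncol(Zc)
  g <- stats::rnorm(m)
  a <- stats::rnorm(n)
  u <- sqrt(cfg$h2) *
    as.numeric(sqrt(1 - cfg$w) * unclass(Zc) %*% g +
                 sqrt(cfg$w) * unclass(L) %*% a)
  y <- cfg$mu + u + stats::rnorm(n, sd = sqrt(1 - cfg$h2))
  ids <- rownames(Zc) %||% paste0("A", seq_len(n))
  names(u) <- ids
  list(pheno = phenotype_data(ids, y), true_u = u)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generation pipeline: pedigree, gene-dropped genotypes,
#' pedigree relationship matrix and its genotyped block, centered marker
#' matrix, Cholesky factor, and phenotypes for the genotyped animals.
#'
#' @param cfg [simulation_config()].
#' @param n_genotyped Number of genotyped animals, taken as the last
#'   \code{n_genotyped} animals of the pedigree (the youngest). Default:
#'   the final generation.
#' @param method VanRaden scaling method for [center_scale()].
#' @param dir Optional directory; when given, pedigree/genotype/phenotype
#'   files and a plain-text manifest of the true parameters are written
#'   there (created if missing).
#' @return List with \code{ped}, \code{geno} (genotyped animals only),
#'   \code{A}, \code{A22}, \code{F} (inbreeding, all animals), \code{Zc},
#'   \code{L}, \code{pheno}, \code{true_u}, \code{genotyped_ids},
#'   \code{cfg}, and \code{files} (paths, when \code{dir} is given).
#' @export
simulate_dataset <- function(cfg, n_genotyped = NULL,
                             method = "vanraden1", dir = NULL) {
  ped <- simulate_pedigree(cfg)
  geno_all <- gene_drop_genotypes(ped, cfg)
  if (is.null(n_genotyped))
    n_genotyped <- if (cfg$n_generations > 0) cfg$matings_per_generation
                   else cfg$n_founders
  stopifnot(n_genotyped >= 1, n_genotyped <= nrow(ped))
  genotyped_ids <- utils::tail(ped$animal, n_genotyped)
  geno <- geno_all[genotyped_ids, , drop = FALSE]
  class(geno) <- class(geno_all)
  A <- numerator_relationship_matrix(ped)
  A22 <- subset_A22(A, genotyped_ids)
  Fj <- inbreeding_coefficients(ped)
  Zc <- center_scale(geno, method = method)
  L <- cholesky_factor(A22)
  sim_ph <- simulate_phenotypes(Zc, L, cfg)
  out <- list(ped = ped, geno = geno, A = A, A22 = A22, F = Fj, Zc = Zc,
              L = L, pheno = sim_ph$pheno, true_u = sim_ph$true_u,
              genotyped_ids = genotyped_ids, cfg = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      pedigree = file.path(dir, "pedigree.csv"),
      genotypes = file.path(dir, "genotypes.csv"),
      phenotypes = file.path(dir, "phenotypes.csv"),
      manifest = file.path(dir, "manifest.txt"))
    write_pedigree_csv(ped, files$pedigree)
    write_genotype_csv(geno, files$genotypes)
    write_phenotype_csv(out$pheno, files$phenotypes)
    writeLines(c(
      paste0("seed=", cfg$seed),
      paste0("n_founders=", cfg$n_founders),
      paste0("n_generations=", cfg$n_generations),
      paste0("matings_per_generation=", cfg$matings_per_generation),
      paste0("m=", cfg$m),
      paste0("maf_low=", cfg$maf_low),
      paste0("maf_high=", cfg$maf_high),
      paste0("h2=", cfg$h2),
      paste0("w=", cfg$w),
      paste0("mu=", cfg$mu),
      paste0("n_genotyped=", n_genotyped),
      paste0("scaling=", method)), files$manifest)
    out$files <- files
  }
  out
}
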