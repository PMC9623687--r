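#' Comparison statistics between exact and approximate reliabilities
#'
#' Joins two reliability results on animal ID and computes the performance
#' statistics used to assess a reliability approximation: Pearson
#' correlation, maximum absolute difference, mean squared error, and the
#' ordinary least squares regression of the exact reliability (response) on
#' the approximate reliability (covariate). An unbiased approximation gives
#' intercept 0 and slope 1; a slope above 1 indicates inflated (too high)
#' approximate reliabilities at the low end.
#'
#' @param exact,approx \code{"reliability_result"} data frames over the
#'   same animals (any order; joined by ID).
#' @return A \code{"comparison_stats"} list: \code{r}, \code{max_diff},
#'   \code{mse}, \code{mse_e5} (MSE scaled by 1e5, the conventional display
#'   unit), \code{b0}, \code{b1}, \code{n_animals}.
#' @export
compare_reliabilities <- function(exact, approx) {
  if (!setequal(exact$animal, approx$animal) ||
      nrow(exact) != nrow(approx))
    stop("exact and approx results cover different animal sets")
  if (nrow(exact) < 3L) stop("need at least 3 animals to compare")
  approx <- approx[match(exact$animal, approx$animal), , drop = FALSE]
  x <- approx$r2
  y <- exact$r2
  if (stats::var(x) == 0)
    stop("approximate reliabilities have zero variance; regression ",
         "undefined")
  d <- y - x
  b1 <- stats::cov(x, y) / stats::var(x)
  b0 <- mean(y) - b1 * mean(x)
  structure(list(r = stats::cor(x, y),
                 max_diff = max(abs(d)),
                 mse = mean(d^2),
                 mse_e5 = mean(d^2) * 1e5,
                 b0 = b0, b1 = b1,
                 n_animals = length(d)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  r = %.4f  max = %.4f  MSE(x1e-5) = %.1f  b0 = %.3f  b1 = %.3f\n",
    x$n_animals, x$r, x$max_diff, x$mse_e5, x$b0, x$b1))
  invisible(x)
}

#' Scenario sweep over polygenic proportions and Monte Carlo sample counts
#'
#' For each residual polygenic proportion \code{w}, computes the exact
#' GBLUP reliabilities once, then the full-MC approximation for every
#' \code{(n_mc, seed)} pair, and tabulates the comparison statistics. The
#' result is one row per scenario, the shape of the standard
#' accuracy-versus-sample-count comparison table.
#'
#' Reliabilities depend on the model design (relationships, weights,
#' variance ratio), not on the realized phenotype values, so one phenotype
#' set serves every scenario.
#'
#' @param Zc Centered/scaled marker matrix for the genotyped animals.
#' @param L Lower Cholesky factor of their \eqn{A_{22}}.
#' @param A22 Pedigree relationship matrix of the genotyped animals.
#' @param pheno [phenotype_data()].
#' @param h2 Heritability (unit phenotypic variance).
#' @param w_values Residual polygenic proportions to evaluate.
#' @param n_mc_values Monte Carlo sample counts to evaluate.
#' @param seeds Integer seeds; each (w, n_mc) cell is replicated per seed.
#' @param sigma_mode Denominator mode for the approximation (see
#'   [animal_variance()]).
#' @return Data frame with columns \code{w}, \code{n_mc}, \code{seed},
#'   \code{r}, \code{max_diff}, \code{mse}, \code{mse_e5}, \code{b0},
#'   \code{b1}.
#' @export
sweep_scenarios <- function(Zc, L, A22, pheno, h2, w_values, n_mc_values,
                            seeds = 1L, sigma_mode = "mc") {
  stopifnot(length(w_values) >= 1, length(n_mc_values) >= 1,
            length(seeds) >= 1)
  rows <- list()
  for (w in w_values) {
    params <- model_params(w = w, h2 = h2)
    Gw <- blended_relationship(Zc, A22, w)
    exact <- gblup_reliability(Gw, pheno, params)
    for (n_mc in n_mc_values) {
      for (seed in seeds) {
        approx <- full_mc_run(Zc, L, pheno, params, n_mc = n_mc,
                              seed = seed, sigma_mode = sigma_mode)
        cs <- compare_reliabilities(exact, approx)
        rows[[length(rows) + 1L]] <-
          data.frame(w = w, n_mc = n_mc, seed = seed, r = cs$r,
                     max_diff = cs$max_diff, mse = cs$mse,
                     mse_e5 = cs$mse_e5, b0 = cs$b0, b1 = cs$b1)
      }
    }
  }
  do.call(rbind, rows)
}
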