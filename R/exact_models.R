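#' Model variance parameters
#'
#' Collects the variance components of the single-trait repeatability-free
#' animal model: total genetic variance \eqn{\sigma_u^2}, residual variance
#' \eqn{\sigma_e^2}, their ratio \eqn{\lambda = \sigma_e^2/\sigma_u^2}, and
#' the residual polygenic proportion \eqn{w}. Either the two variances or a
#' heritability may be supplied; with unit phenotypic variance
#' \eqn{\lambda = (1 - h^2)/h^2}.
#'
#' @param w Residual polygenic proportion in \eqn{[0,1]}.
#' @param h2 Heritability in (0,1); sets \code{sigma_u2 = h2},
#'   \code{sigma_e2 = 1 - h2}.
#' @param sigma_u2,sigma_e2 Genetic and residual variances (used when
#'   \code{h2} is missing).
#' @return List of class \code{"model_params"} with elements \code{w},
#'   \code{sigma_u2}, \code{sigma_e2}, \code{lambda}.
#' @export
model_params <- function(w, h2 = NULL, sigma_u2 = NULL, sigma_e2 = NULL) {
  stopifnot(w >= 0, w <= 1)
  if (!is.null(h2)) {
    stopifnot(h2 > 0, h2 < 1)
    sigma_u2 <- h2
    sigma_e2 <- 1 - h2
  }
  stopifnot(!is.null(sigma_u2), !is.null(sigma_e2),
            sigma_u2 > 0, sigma_e2 > 0)
  structure(list(w = w, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 lambda = sigma_e2 / sigma_u2),
            class = "model_params")
}

#' Phenotype records
#'
#' One record per animal with an optional observation weight \eqn{w_i};
#' the residual covariance is \eqn{R = diag(1/w_i) \sigma_e^2}.
#'
#' @param animal Animal IDs.
#' @param y Record values.
#' @param weight Strictly positive per-record weights (default 1).
#' @return Data frame of class \code{"phenotype_data"}.
#' @export
phenotype_data <- function(animal, y, weight = 1) {
  animal <- as.character(animal)
  if (anyDuplicated(animal))
    stop("duplicate animal ID in phenotypes: ",
         animal[duplicated(animal)][1L])
  weight <- rep_len(weight, length(animal))
  stopifnot(length(y) == length(animal), all(weight > 0))
  structure(data.frame(animal = animal, y = y, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("phenotype_data", "data.frame"))
}

# reorder phenotypes to a reference ID order; error on mismatch
align_phenotypes <- function(pheno, ids) {
  if (is.null(ids)) {
    if (nrow(pheno) == 0L) stop("no phenotype records")
    return(pheno)
  }
  if (!setequal(pheno$animal, ids) || nrow(pheno) != length(ids))
    stop("phenotype animal IDs do not match the genotyped-animal set")
  pheno[match(ids, pheno$animal), , drop = FALSE]
}

# symmetric PD inverse with a jitter ladder; returns the inverse.
# A factorization whose pivot ratio signals effective singularity (e.g. a
# column-centered ZcZc', which annihilates the ones vector exactly) is
# rejected so the ladder escalates instead of returning a garbage inverse.
sym_inverse <- function(M, jitter = c(0, 1e-10, 1e-8, 1e-6), what = "matrix") {
  for (j in jitter) {
    R <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(R) && (min(diag(R)) / max(diag(R)))^2 > 1e-10) {
      if (j > 0) message("sym_inverse: used jitter ", j, " for ", what)
      return(chol2inv(R))
    }
  }
  stop(what, " is singular / not positive definite; check lambda and ",
       "consider jitter")
}

reliability_result <- function(ids, pev, sigma_j2, r2, model_tag) {
  structure(data.frame(animal = as.character(ids), pev = pev,
                       sigma_j2 = sigma_j2, r2 = r2, model = model_tag,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("reliability_result", "data.frame"))
}

#' Exact GBLUP reliabilities
#'
#' Fits the animal-level model \eqn{y = 1\mu + u + e} with
#' \eqn{u \sim N(0, G_w \sigma_u^2)} and computes per-animal reliability
#' from the inverse of the mixed model equations:
#' \deqn{r_j^2 = 1 - \lambda PEV_j / (G_w)_{jj},}
#' where \eqn{PEV_j} is the j-th diagonal of the animal block of the MME
#' inverse (in \eqn{\lambda}-scaled units).
#'
#' @param Gw Blended genomic relationship matrix (see
#'   [blended_relationship()]).
#' @param pheno [phenotype_data()] for the same animals.
#' @param params [model_params()].
#' @return A \code{"reliability_result"} data frame with columns
#'   \code{animal}, \code{pev}, \code{sigma_j2}, \code{r2}, \code{model}.
#' @export
gblup_reliability <- function(Gw, pheno, params) {
  ids <- rownames(Gw)
  pheno <- align_phenotypes(pheno, ids)
  n <- nrow(Gw)
  r <- pheno$weight
  lambda <- params$lambda
  Ginv <- sym_inverse(Gw, what = "Gw")
  C <- matrix(0, n + 1L, n + 1L)
  C[1L, 1L] <- sum(r)
  C[1L, -1L] <- r
  C[-1L, 1L] <- r
  C[-1L, -1L] <- diag(r, n) + lambda * Ginv
  Cinv <- sym_inverse(C, what = "GBLUP MME")
  pev <- diag(Cinv)[-1L]
  sigma_j2 <- diag(Gw)
  reliability_result(ids %||% pheno$animal, pev, sigma_j2,
                     1 - lambda * pev / sigma_j2, "gblup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact SNP-BLUP reliabilities with a residual polygenic effect
#'
#' Fits the equivalent marker-level model
#' \eqn{y = 1\mu + Z g_R + e} with
#' \eqn{Z = [\sqrt{1-w}\, Z_c, \sqrt{w}\, L]} and
#' \eqn{g_R \sim N(0, I \sigma_u^2)}, so that
#' \eqn{Var(Z g_R) = G_w \sigma_u^2}. Animal prediction error variances are
#' quadratic forms \eqn{PEV_j = z_j C^{gg} z_j'} in the genetic block of the
#' MME inverse, and \eqn{\sigma_j^2 = (Z Z')_{jj}}.
#'
#' @param Zc Centered/scaled marker matrix.
#' @param L Lower Cholesky factor of \eqn{A_{22}} (see
#'   [cholesky_factor()]).
#' @param pheno [phenotype_data()].
#' @param params [model_params()]; supplies \eqn{w} and \eqn{\lambda}.
#' @return A \code{"reliability_result"} data frame.
#' @export
snpblup_exact_reliability <- function(Zc, L, pheno, params) {
  ids <- rownames(Zc) %||% rownames(L)
  pheno <- align_phenotypes(pheno, ids)
  w <- params$w
  Z <- cbind(sqrt(1 - w) * unclass(Zc), sqrt(w) * unclass(L))
  fit_marker_mme(Z, pheno, params, sigma_j2 = rowSums(Z^2),
                 ids = ids %||% pheno$animal, model_tag = "snpblup_exact")
}

#' Monte Carlo SNP-BLUP reliabilities (MC for the polygenic effect only)
#'
#' The earlier partial-MC comparator: marker effects enter the MME exactly
#' (m equations) while the residual polygenic effect is replaced by an
#' n x n_mc Monte Carlo regression block with columns
#' \eqn{\sqrt{w} L z_i / \sqrt{n_{mc}}}, \eqn{z_i \sim N(0, I)}. The MME has
#' order \eqn{1 + m + n_{mc}}.
#'
#' @inheritParams snpblup_exact_reliability
#' @param n_mc Number of Monte Carlo samples for the polygenic block.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param z_samples Optional n x n_mc matrix replacing the standard normal
#'   draws (deterministic hook; \code{sqrt(n) * diag(n)} with
#'   \code{n_mc = n} reproduces the exact model).
#' @return A \code{"reliability_result"} data frame.
#' @export
mc_rpg_snpblup_reliability <- function(Zc, L, pheno, params, n_mc,
                                       seed = NULL, z_samples = NULL) {
  stopifnot(n_mc >= 1)
  ids <- rownames(Zc) %||% rownames(L)
  pheno <- align_phenotypes(pheno, ids)
  w <- params$w
  n <- nrow(L)
  if (is.null(z_samples)) {
    if (!is.null(seed)) set.seed(seed)
    z_samples <- matrix(stats::rnorm(n * n_mc), n, n_mc)
  }
  stopifnot(nrow(z_samples) == n, ncol(z_samples) == n_mc)
  U_rpg <- sqrt(w / n_mc) * (unclass(L) %*% z_samples)
  Z <- cbind(sqrt(1 - w) * unclass(Zc), U_rpg)
  sigma_j2 <- (1 - w) * rowSums(unclass(Zc)^2) + rowSums(U_rpg^2)
  fit_marker_mme(Z, pheno, params, sigma_j2 = sigma_j2,
                 ids = ids %||% pheno$animal, model_tag = "mc_rpg")
}

# shared MME machinery for models with an explicit genetic design matrix Z:
# C = [[1'R^-1 1, 1'R^-1 Z], [Z'R^-1 1, Z'R^-1 Z + lambda I]]
fit_marker_mme <- function(Z, pheno, params, sigma_j2, ids, model_tag) {
  r <- pheno$weight
  lambda <- params$lambda
  q <- ncol(Z)
  Zr <- Z * r
  C <- matrix(0, q + 1L, q + 1L)
  C[1L, 1L] <- sum(r)
  C[1L, -1L] <- colSums(Zr)
  C[-1L, 1L] <- colSums(Zr)
  C[-1L, -1L] <- crossprod(Z * sqrt(r)) + diag(lambda, q)
  Cinv <- sym_inverse(C, what = paste(model_tag, "MME"))
  Cgg <- Cinv[-1L, -1L, drop = FALSE]
  pev <- rowSums((Z %*% Cgg) * Z)
  reliability_result(ids, pev, sigma_j2, 1 - lambda * pev / sigma_j2,
                     model_tag)
}

#' Write a reliability result to CSV
#'
#' @param res A \code{"reliability_result"}.
#' @param path Output path.
#' @export
write_reliability_csv <- function(res, path) {
  utils::write.csv(as.data.frame(res), path, row.names = FALSE)
  invisible(path)
}

#' Read a reliability CSV written by [write_reliability_csv()]
#'
#' @param path Input path.
#' @return A \code{"reliability_result"} data frame.
#' @export
read_reliability_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(animal = "character"))
  structure(df, class = c("reliability_result", "data.frame"))
}
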