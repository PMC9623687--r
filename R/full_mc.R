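#' Sample the full Monte Carlo regression matrix U
#'
#' Draws \eqn{n_{mc}} pseudo-genetic-effect columns whose empirical
#' cross-product approximates the blended relationship matrix: column i is
#' \deqn{u_i = (Z_c g_i + a_i)/\sqrt{n_{mc}},}
#' with marker effects \eqn{g_i \sim N(0, (1-w) I_m)} and polygenic samples
#' \eqn{a_i = \sqrt{w} L z_i}, \eqn{z_i \sim N(0, I_n)}. Hence each
#' unscaled column is a draw from \eqn{N(0, G_w)} and
#' \eqn{E[U U'] = G_w}. The \eqn{1/\sqrt{n_{mc}}} column scaling makes
#' \eqn{U U'} the Monte Carlo average, so prediction error variances and
#' animal variances are on the relationship-matrix scale.
#'
#' All marker-effect draws are generated first, then all polygenic draws,
#' in one column-major pass of a single seeded stream, so a given seed
#' always yields the same U.
#'
#' @param Zc Centered/scaled marker matrix (n x m).
#' @param L Lower Cholesky factor of \eqn{A_{22}} (n x n).
#' @param w Residual polygenic proportion in \eqn{[0,1]}.
#' @param n_mc Number of Monte Carlo samples (columns).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return An \code{"mc_samples"} matrix (n x n_mc) with attributes
#'   \code{w}, \code{n_mc}, \code{seed}, \code{column_scaled = TRUE} and
#'   animal IDs as rownames.
#' @export
sample_U <- function(Zc, L, w, n_mc, seed = NULL) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  stopifnot(n_mc >= 1, nrow(Zc) == nrow(L))
  n <- nrow(Zc)
  m <- ncol(Zc)
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::rnorm(m * n_mc, sd = sqrt(1 - w)), m, n_mc)
  Zm <- matrix(stats::rnorm(n * n_mc), n, n_mc)
  U <- (unclass(Zc) %*% G + sqrt(w) * (unclass(L) %*% Zm)) / sqrt(n_mc)
  rownames(U) <- rownames(Zc) %||% rownames(L)
  structure(U, w = w, n_mc = n_mc, seed = seed, column_scaled = TRUE,
            class = c("mc_samples", "matrix", "array"))
}

#' Deterministic U from the Cholesky factor of Gw (exact-covariance hook)
#'
#' Substitutes the lower Cholesky factor of \eqn{G_w} for the sampled U, so
#' that \eqn{U U' = G_w} exactly and the downstream Monte Carlo pipeline
#' must reproduce exact GBLUP reliabilities. Used as a deterministic
#' end-to-end oracle for the MME assembly, block inversion, quadratic form
#' and reliability formula.
#'
#' @param Gw Positive definite blended relationship matrix.
#' @return An \code{"mc_samples"} matrix with n columns, no randomness.
#' @export
deterministic_U_from_cholesky <- function(Gw) {
  R <- tryCatch(chol(Gw), error = function(e)
    stop("Gw is not positive definite; cannot build deterministic U"))
  U <- t(R)
  rownames(U) <- rownames(Gw)
  structure(U, w = attr(Gw, "w"), n_mc = ncol(U), seed = NULL,
            column_scaled = TRUE,
            class = c("mc_samples", "matrix", "array"))
}

#' Assemble the full-MC mixed model equations
#'
#' Builds the symmetric coefficient matrix of order \eqn{1 + n_{mc}}:
#' \deqn{C = [[1'R^{-1}1, 1'R^{-1}U], [U'R^{-1}1, U'R^{-1}U + \lambda I]],}
#' with \eqn{R^{-1} = diag(w_i)} the record weights, plus the right-hand
#' side \eqn{[1'R^{-1}y, U'R^{-1}y]}. The system size depends only on the
#' number of Monte Carlo samples, not on the marker or animal counts.
#'
#' @param U An \code{"mc_samples"} matrix (n x n_mc).
#' @param pheno [phenotype_data()] with one record per row of U.
#' @param params [model_params()] supplying \eqn{\lambda}.
#' @return An \code{"mme_system"} list: \code{C}, \code{rhs},
#'   \code{lambda}, \code{n_mc}.
#' @export
build_full_mc_mme <- function(U, pheno, params) {
  pheno <- align_phenotypes(pheno, rownames(U))
  if (nrow(U) != nrow(pheno))
    stop("row count of U (", nrow(U), ") does not match number of records (",
         nrow(pheno), ")")
  r <- pheno$weight
  n_mc <- ncol(U)
  Ur <- crossprod(unclass(U), r)            # U'R^-1 1
  C <- matrix(0, n_mc + 1L, n_mc + 1L)
  C[1L, 1L] <- sum(r)
  C[1L, -1L] <- Ur
  C[-1L, 1L] <- Ur
  C[-1L, -1L] <- crossprod(unclass(U) * sqrt(r)) + diag(params$lambda, n_mc)
  rhs <- c(sum(r * pheno$y), crossprod(unclass(U), r * pheno$y))
  structure(list(C = C, rhs = rhs, lambda = params$lambda, n_mc = n_mc),
            class = "mme_system")
}

#' Genetic block of the MME inverse
#'
#' Inverts the full-MC coefficient matrix by symmetric (Cholesky)
#' factorization and returns the lower-right \eqn{n_{mc} \times n_{mc}}
#' block \eqn{C^{uss}}, the covariance kernel of the prediction error
#' quadratic forms.
#'
#' @param mme An \code{"mme_system"} from [build_full_mc_mme()].
#' @return Symmetric \eqn{n_{mc} \times n_{mc}} matrix \eqn{C^{uss}}.
#' @export
solve_pev_block <- function(mme) {
  stopifnot(inherits(mme, "mme_system"))
  Cinv <- sym_inverse(mme$C, what = "full-MC MME")
  Cinv[-1L, -1L, drop = FALSE]
}

#' Per-animal genetic variances for the reliability denominator
#'
#' Mode \code{"mc"} takes the diagonal of the Monte Carlo relationship
#' matrix, \eqn{\sigma_j^2 = (U U')_{jj}}, computed as row norms without
#' forming \eqn{U U'}. Mode \code{"exact"} uses the model variance
#' \eqn{(1-w)(Z_c Z_c')_{jj} + w(1 + F_j)} (the \eqn{A_{22}} diagonal
#' convention, equal to \eqn{(G_w)_{jj}}); \code{convention =
#' "one-minus-f"} substitutes \eqn{1 - F_j} for the polygenic diagonal.
#'
#' @param U \code{"mc_samples"} matrix (required for mode \code{"mc"}).
#' @param Zc Centered marker matrix (mode \code{"exact"}).
#' @param inbreeding Per-animal inbreeding coefficients F, in the same
#'   animal order (mode \code{"exact"}).
#' @param w Residual polygenic proportion (mode \code{"exact"}).
#' @param mode \code{"mc"} or \code{"exact"}.
#' @param convention Polygenic diagonal convention for mode \code{"exact"}:
#'   \code{"a22"} (1 + F, default) or \code{"one-minus-f"} (1 - F).
#' @return Numeric vector of \eqn{\sigma_j^2}, one per animal.
#' @export
animal_variance <- function(U = NULL, Zc = NULL, inbreeding = NULL, w = NULL,
                            mode = c("mc", "exact"),
                            convention = c("a22", "one-minus-f")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  s2 <- if (mode == "mc") {
    stopifnot(!is.null(U))
    rowSums(unclass(U)^2)
  } else {
    stopifnot(!is.null(Zc), !is.null(inbreeding), !is.null(w))
    Fj <- if (convention == "a22") 1 + inbreeding else 1 - inbreeding
    (1 - w) * rowSums(unclass(Zc)^2) + w * Fj
  }
  if (any(s2 <= 0))
    stop("nonpositive animal genetic variance sigma_j2 (degenerate marker ",
         "row?)")
  s2
}

#' Full-MC reliabilities from an explicit PEV block
#'
#' Computes \eqn{PEV_j = t_j C^{uss} t_j'} with \eqn{t_j} the j-th row of
#' U, evaluated animal-by-animal left-to-right (the row-vector-matrix
#' product first), and
#' \deqn{r_j^2 = 1 - \lambda PEV_j / \sigma_j^2.}
#' Raw values are stored; approximate reliabilities can fall outside
#' \eqn{[0,1]} and clamping is left to reporting.
#'
#' @param U \code{"mc_samples"} matrix.
#' @param pev_block \eqn{C^{uss}} from [solve_pev_block()].
#' @param sigma_j2 Per-animal variances from [animal_variance()].
#' @param params [model_params()].
#' @return A \code{"reliability_result"} data frame with model tag
#'   \code{"full_mc"}.
#' @export
full_mc_reliability <- function(U, pev_block, sigma_j2, params) {
  Um <- unclass(U)
  stopifnot(ncol(Um) == nrow(pev_block), length(sigma_j2) == nrow(Um))
  if (any(sigma_j2 == 0)) stop("sigma_j2 contains zeros")
  n <- nrow(Um)
  pev <- numeric(n)
  for (j in seq_len(n)) {
    tj <- Um[j, ]
    pev[j] <- sum((tj %*% pev_block) * tj)
  }
  reliability_result(rownames(Um) %||% seq_len(n), pev, sigma_j2,
                     1 - params$lambda * pev / sigma_j2, "full_mc")
}

#' One-call full-MC reliability run
#'
#' Samples U and computes the approximate reliabilities. Two algebraically
#' identical solution paths are provided. \code{path = "gram"} (default)
#' exploits the model equivalence between the pseudo-effect regression and
#' an animal-level model with relationship matrix \eqn{U U'}: the MME
#' solved is n x n regardless of \eqn{n_{mc}}, which is the efficient
#' regime when animals are few and Monte Carlo samples are many.
#' \code{path = "mme"} assembles and inverts the literal
#' \eqn{(1 + n_{mc})}-order system.
#'
#' @param Zc Centered/scaled marker matrix.
#' @param L Lower Cholesky factor of \eqn{A_{22}}.
#' @param pheno [phenotype_data()].
#' @param params [model_params()] (supplies \eqn{w} and \eqn{\lambda}).
#' @param n_mc Number of Monte Carlo samples.
#' @param seed Integer seed for [sample_U()].
#' @param sigma_mode Denominator variance mode, \code{"mc"} (default) or
#'   \code{"exact"}; see [animal_variance()].
#' @param path \code{"gram"} or \code{"mme"}.
#' @param inbreeding,convention Passed to [animal_variance()] when
#'   \code{sigma_mode = "exact"}.
#' @param U Optional pre-sampled \code{"mc_samples"} matrix (overrides
#'   \code{n_mc}/\code{seed}), e.g. from
#'   [deterministic_U_from_cholesky()].
#' @return A \code{"reliability_result"} data frame with model tag
#'   \code{"full_mc"}.
#' @export
full_mc_run <- function(Zc, L, pheno, params, n_mc, seed = NULL,
                        sigma_mode = c("mc", "exact"),
                        path = c("gram", "mme"),
                        inbreeding = NULL, convention = "a22", U = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  path <- match.arg(path)
  if (is.null(U))
    U <- sample_U(Zc, L, params$w, n_mc, seed)
  sigma_j2 <- if (sigma_mode == "mc") animal_variance(U = U, mode = "mc")
              else animal_variance(Zc = Zc, inbreeding = inbreeding,
                                   w = params$w, mode = "exact",
                                   convention = convention)
  if (path == "mme") {
    mme <- build_full_mc_mme(U, pheno, params)
    res <- full_mc_reliability(U, solve_pev_block(mme), sigma_j2, params)
  } else {
    res <- full_mc_gram(U, pheno, params, sigma_j2)
  }
  res
}

# n x n equivalent-model path: PEV_j of the pseudo-effect model equals the
# animal-block MME inverse diagonal with relationship matrix UU' (standard
# SNP-BLUP/GBLUP equivalence; requires UU' nonsingular, i.e. n_mc >= n).
full_mc_gram <- function(U, pheno, params, sigma_j2) {
  pheno2 <- align_phenotypes(pheno, rownames(U))
  Gstar <- tcrossprod(unclass(U))
  if (is.null(rownames(Gstar)) && !is.null(rownames(U)))
    dimnames(Gstar) <- list(rownames(U), rownames(U))
  n <- nrow(Gstar)
  r <- pheno2$weight
  lambda <- params$lambda
  Ginv <- sym_inverse(Gstar, what = "UU'")
  C <- matrix(0, n + 1L, n + 1L)
  C[1L, 1L] <- sum(r)
  C[1L, -1L] <- r
  C[-1L, 1L] <- r
  C[-1L, -1L] <- diag(r, n) + lambda * Ginv
  Cinv <- sym_inverse(C, what = "full-MC equivalent MME")
  pev <- diag(Cinv)[-1L]
  reliability_result(rownames(U) %||% pheno2$animal, pev, sigma_j2,
                     1 - lambda * pev / sigma_j2, "full_mc")
}
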