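test_that("sampled U has the blend limits and is reproducible", {
  sim <- small_sim()
  expect_error(sample_U(sim$Zc, sim$L, w = -0.1, n_mc = 10), "\\[0, 1\\]")

  U1 <- sample_U(sim$Zc, sim$L, w = 0.5, n_mc = 200, seed = 3)
  U2 <- sample_U(sim$Zc, sim$L, w = 0.5, n_mc = 200, seed = 3)
  expect_identical(unclass(U1), unclass(U2))
  expect_true(attr(U1, "column_scaled"))
  expect_equal(dim(U1), c(nrow(sim$Zc), 200L))

  # w = 1: no marker component, UU' -> A22; w = 0: UU' -> ZcZc'
  Uw1 <- sample_U(sim$Zc, sim$L, w = 1, n_mc = 30000, seed = 4)
  expect_lt(max(abs(tcrossprod(unclass(Uw1)) - sim$A22)), 0.15)
  Uw0 <- sample_U(sim$Zc, sim$L, w = 0, n_mc = 30000, seed = 4)
  expect_lt(max(abs(tcrossprod(unclass(Uw0)) -
                      tcrossprod(unclass(sim$Zc)))), 0.15)
})

test_that("UU' concentrates around Gw within the Wishart sampling bound", {
  cfg <- simulation_config(n_founders = 25, n_generations = 2,
                           matings_per_generation = 50, m = 200,
                           h2 = 0.3, w = 0.5, seed = 11L)
  sim <- simulate_dataset(cfg, n_genotyped = 50)
  Gw <- blended_relationship(sim$Zc, sim$A22, 0.5)
  n_mc <- 100000
  U <- sample_U(sim$Zc, sim$L, w = 0.5, n_mc = n_mc, seed = 8)
  UU <- tcrossprod(unclass(U))
  se <- sqrt((outer(diag(Gw), diag(Gw)) + unclass(Gw)^2) / n_mc)
  expect_true(all(abs(UU - Gw) <= 5 * se))
})

test_that("deterministic U from chol(Gw) satisfies UU' = Gw exactly", {
  expect_equal(unname(unclass(deterministic_U_from_cholesky(diag(3)))),
               diag(3), ignore_attr = TRUE)
  G2 <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(unname(unclass(deterministic_U_from_cholesky(G2))),
               matrix(c(1, .5, 0, sqrt(.75)), 2), ignore_attr = TRUE)
  expect_error(deterministic_U_from_cholesky(diag(c(1, -1))),
               "positive definite")
})

test_that("full-MC MME assembly matches hand computations and is symmetric", {
  lam <- 2.5
  params <- model_params(w = 0.5, sigma_u2 = 1, sigma_e2 = lam)

  U0 <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  mme0 <- build_full_mc_mme(U0, phenotype_data(c("a", "b", "c"), 1:3),
                            params)
  expect_equal(mme0$C, rbind(c(3, rep(0, 4)),
                             cbind(0, diag(lam, 4))))

  # n = 2, weights (2, 1), U = (1, 1)': 1'R^-1 1 = 3, U'R^-1 U = 3
  U1 <- matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL))
  mme1 <- build_full_mc_mme(U1, phenotype_data(c("a", "b"), c(5, 7),
                                               weight = c(2, 1)), params)
  expect_equal(mme1$C, matrix(c(3, 3, 3, 3 + lam), 2))
  expect_equal(mme1$rhs, c(2 * 5 + 7, 2 * 5 + 7))

  set.seed(1)
  Ur <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  mme <- build_full_mc_mme(Ur, phenotype_data(c("a", "b", "c"), 1:3,
                                              weight = c(1, 2, 3)), params)
  expect_equal(mme$C, t(mme$C))
  expect_equal(dim(mme$C), c(5L, 5L))

  expect_error(build_full_mc_mme(Ur, phenotype_data(c("a", "b"), 1:2),
                                 params))
})

test_that("the MME order is 1 + n_mc whatever the animal and marker counts", {
  for (dims in list(c(6, 9), c(12, 4))) {
    cfg <- simulation_config(n_founders = dims[1], n_generations = 0,
                             m = dims[2], seed = 3L)
    sim <- simulate_dataset(cfg)
    for (n_mc in c(3L, 17L)) {
      U <- sample_U(sim$Zc, sim$L, 0.5, n_mc, seed = 1)
      mme <- build_full_mc_mme(U, sim$pheno,
                               model_params(w = 0.5, h2 = 0.3))
      expect_equal(dim(mme$C), c(1L + n_mc, 1L + n_mc))
    }
  }
})

test_that("PEV block: closed forms and positive definiteness", {
  params <- model_params(w = 0, sigma_u2 = 1, sigma_e2 = 3)
  # C = diag(n, lambda I) -> C_uss = I / lambda
  mme <- structure(list(C = rbind(c(5, 0, 0), cbind(0, diag(3, 2))),
                        lambda = 3, n_mc = 2), class = "mme_system")
  expect_equal(solve_pev_block(mme), diag(1 / 3, 2))

  # 2x2 [[1, 1], [1, 1 + lambda]] -> C_uss = 1/lambda
  mme2 <- structure(list(C = matrix(c(1, 1, 1, 1 + 3), 2), lambda = 3,
                         n_mc = 1), class = "mme_system")
  expect_equal(solve_pev_block(mme2), matrix(1 / 3))

  sim <- small_sim()
  U <- sample_U(sim$Zc, sim$L, 0.5, 40, seed = 2)
  Cuss <- solve_pev_block(build_full_mc_mme(U, sim$pheno,
                                            model_params(w = 0.5, h2 = 0.3)))
  expect_equal(Cuss, t(Cuss))
  expect_gte(min_eigen(Cuss), 0)
})

test_that("animal variance: MC diagonal, exact blend, and Gw identity", {
  U <- structure(diag(4), class = c("mc_samples", "matrix", "array"))
  expect_equal(animal_variance(U = U, mode = "mc"), rep(1, 4))

  sim <- small_sim()
  Fg <- sim$F[sim$genotyped_ids]
  # w = 1, non-inbred animals: sigma_j2 = 1
  nonin <- which(Fg == 0)
  s2w1 <- animal_variance(Zc = sim$Zc, inbreeding = Fg, w = 1,
                          mode = "exact")
  expect_equal(unname(s2w1[nonin]), rep(1, length(nonin)))

  # default convention reproduces diag(Gw) exactly
  Gw <- blended_relationship(sim$Zc, sim$A22, 0.5)
  s2 <- animal_variance(Zc = sim$Zc, inbreeding = Fg, w = 0.5,
                        mode = "exact")
  expect_equal(unname(s2), unname(diag(Gw)))

  # paper-literal convention flips the inbreeding sign
  s2lit <- animal_variance(Zc = sim$Zc, inbreeding = Fg, w = 0.5,
                           mode = "exact", convention = "one-minus-f")
  expect_equal(unname(s2 - s2lit), unname(Fg))
})

test_that("exact-covariance oracle: full-MC pipeline reproduces GBLUP", {
  sim <- small_sim()
  params <- model_params(w = 0.5, h2 = 0.3)
  Gw <- blended_relationship(sim$Zc, sim$A22, 0.5)
  gb <- gblup_reliability(Gw, sim$pheno, params)
  U <- deterministic_U_from_cholesky(Gw)
  # literal path: MME of order 1 + n, block inverse, row-wise quadratic form
  mme <- build_full_mc_mme(U, sim$pheno, params)
  res <- full_mc_reliability(U, solve_pev_block(mme),
                             animal_variance(U = U, mode = "mc"), params)
  expect_lt(max(abs(res$r2 - gb$r2)), 1e-8)
  # gram path through the driver
  res2 <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, U = U)
  expect_lt(max(abs(res2$r2 - gb$r2)), 1e-8)
})

test_that("gram and literal MME paths agree on sampled U", {
  sim <- small_sim()
  params <- model_params(w = 0.5, h2 = 0.3)
  a <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = 300, seed = 9,
                   path = "mme")
  b <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = 300, seed = 9,
                   path = "gram")
  expect_lt(max(abs(a$r2 - b$r2)), 1e-8)
  expect_identical(a$model[1], "full_mc")
})

test_that("no genetic signal limit: huge lambda drives reliabilities to zero", {
  sim <- small_sim()
  params <- model_params(w = 0.5, sigma_u2 = 1, sigma_e2 = 1e8)
  res <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = 100, seed = 1)
  expect_lt(max(abs(res$r2)), 1e-3)
})

test_that("full-MC result is deterministic under a fixed seed", {
  sim <- small_sim()
  params <- model_params(w = 0.2, h2 = 0.3)
  a <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = 150, seed = 77)
  b <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = 150, seed = 77)
  expect_identical(a, b)
})

test_that("approximation error shrinks as the MC sample count grows", {
  sim <- small_sim()
  params <- model_params(w = 0.5, h2 = 0.3)
  Gw <- blended_relationship(sim$Zc, sim$A22, 0.5)
  gb <- gblup_reliability(Gw, sim$pheno, params)
  mse <- sapply(c(200, 1000, 5000), function(n_mc) {
    mean(sapply(1:3, function(s) {
      ap <- full_mc_run(sim$Zc, sim$L, sim$pheno, params, n_mc = n_mc,
                        seed = s)
      compare_reliabilities(gb, ap)$mse
    }))
  })
  expect_true(all(diff(mse) < 0))
})
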