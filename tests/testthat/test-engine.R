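test_that("build_omega implements the six environment-covariance constructions", {
  expect_equal(unclass(build_omega("GBLUP", I = 4))[1:4, 1:4], diag(4),
               ignore_attr = TRUE)
  expect_equal(unclass(build_omega("GBLUP_TRN", I = 3))[1:3, 1:3], diag(3),
               ignore_attr = TRUE)

  mt <- structure(list(
    omega_gen = matrix(c(2, -0.3, -0.3, 1), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))),
    omega_res = matrix(c(4, 0.1, 0.1, 4), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))),
    env_ids = c("a", "b")), class = "multitrait_fit")

  ce <- build_omega("GBLUP_CE", mt)
  expect_equal(ce[1, 2], -0.3, tolerance = 1e-7)
  expect_identical(attr(ce, "method_tag"), "GBLUP_CE")

  ab <- build_omega("GBLUP_CE_Abs", mt)
  expect_equal(ab[1, 2], 0.3, tolerance = 1e-7)

  avg <- build_omega("GBLUP_CE_mean",
                     structure(list(omega_gen = 2 * diag(2), omega_res = 4 * diag(2),
                                    env_ids = c("a", "b")), class = "multitrait_fit"))
  expect_equal(unclass(avg)[1:2, 1:2], 3 * diag(2), tolerance = 1e-7,
               ignore_attr = TRUE)

  rs <- build_omega("GBLUP_CE_Res", mt)
  expect_equal(rs[2, 2], 4, tolerance = 1e-7)

  expect_error(build_omega("GBLUP_XX", I = 2), "unknown method tag")
  expect_error(build_omega("GBLUP_CE"), "multitrait_fit")

  # non-PSD inputs are clipped and the repair recorded
  bad <- structure(list(omega_gen = matrix(c(1, 2, 2, 1), 2),
                        omega_res = diag(2), env_ids = c("a", "b")),
                   class = "multitrait_fit")
  fixed <- build_omega("GBLUP_CE", bad)
  expect_gte(min(eigen(unclass(fixed), symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_false(is.null(attr(fixed, "psd_repair")))
})

test_that("predict_cells adds the posterior-mean effect components", {
  fit <- structure(list(
    mu_hat = 5,
    env_effects = c(E1 = 1, E2 = -1),
    gebv = c(L1 = 0.5, L2 = 0, L3 = -0.5),
    gxe_effects = matrix(0, 3, 2, dimnames = list(paste0("L", 1:3), paste0("E", 1:2))),
    yhat_grid = 5 + outer(c(0.5, 0, -0.5), c(1, -1), "+") +
      matrix(0, 3, 2, dimnames = list(paste0("L", 1:3), paste0("E", 1:2))),
    line_ids = paste0("L", 1:3), env_ids = paste0("E", 1:2)), class = "gblup_fit")
  dimnames(fit$yhat_grid) <- list(fit$line_ids, fit$env_ids)
  cells <- expand.grid(line = paste0("L", 1:3), env = paste0("E", 1:2),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$line, cells$env), ]
  expect_equal(predict_cells(fit, cells), c(6.5, 4.5, 6.0, 4.0, 5.5, 3.5))
  expect_error(predict_cells(fit, data.frame(line = "LX", env = "E1")), "LX")
  expect_error(predict_cells(fit, data.frame(line = "L1", env = "EX")), "EX")
  # across-TPE scores are mu + gebv
  expect_equal(gebv_across_tpe(fit), c(L1 = 5.5, L2 = 5, L3 = 4.5))
})

test_that("the Gibbs sampler matches the closed-form BLUP oracle at fixed variances", {
  tr <- make_small_trial(J = 30, I = 2, p = 300, seed = 13)
  masked <- mask_trial(tr$pheno, tr$g, tr$env_ids, train_frac = 0.5, seed = 14)
  omega <- build_omega("GBLUP", I = 2, env_ids = tr$env_ids)
  v <- list(var_env = 1, var_gen = 1, var_gxe = 0.5, var_res = 0.5)
  fit <- fit_gblup(masked$train, tr$g, omega,
                   mcmc_config(n_iter = 3000, burn_in = 1000, seed = 15),
                   fixed_variances = v)
  or <- oracle_blup(masked$train, tr$g, omega, v)
  expect_gt(cor(fit$gebv, or$gebv), 0.99)
  expect_gt(cor(as.vector(fit$gxe_effects), as.vector(or$gxe)), 0.98)
  expect_lt(abs(fit$mu_hat - or$mu), 0.35)
})

test_that("with no interaction and identity omega the model reduces to environment-plus-GBLUP", {
  tr <- make_small_trial(J = 30, I = 3, p = 300, seed = 20,
                         sigma2_gxe = 0, sigma2_res = 1)
  omega <- build_omega("GBLUP", I = 3, env_ids = tr$env_ids)
  v <- list(var_env = 1, var_gen = 1, var_gxe = 0, var_res = 1)
  fit <- fit_gblup(tr$pheno, tr$g, omega,
                   mcmc_config(n_iter = 3000, burn_in = 1000, seed = 21),
                   fixed_variances = v)
  or <- oracle_blup(tr$pheno, tr$g, omega, v)
  expect_gt(cor(fit$gebv, or$gebv), 0.99)
  expect_equal(unname(fit$var_gxe), 0)
  expect_true(all(abs(fit$gxe_effects) < 1e-12))
})

test_that("chains are reproducible and permutation-equivariant", {
  tr <- make_small_trial(J = 25, I = 2, p = 250, seed = 30)
  omega <- build_omega("GBLUP", I = 2, env_ids = tr$env_ids)
  cfg <- mcmc_config(n_iter = 400, burn_in = 100, seed = 31)
  f1 <- fit_gblup(tr$pheno, tr$g, omega, cfg)
  f2 <- fit_gblup(tr$pheno, tr$g, omega, cfg)
  expect_identical(f1$gebv, f2$gebv)
  expect_identical(f1$var_gen, f2$var_gen)

  # permuting line order permutes the GEBVs (posteriors identical; the
  # finite chains agree up to Monte Carlo error)
  perm <- rev(seq_len(nrow(tr$g)))
  g_p <- tr$g[perm, perm]
  cfg_long <- mcmc_config(n_iter = 3000, burn_in = 1000, seed = 32)
  f_orig <- fit_gblup(tr$pheno, tr$g, omega, cfg_long)
  f_perm <- fit_gblup(tr$pheno, g_p, omega, cfg_long)
  expect_gt(cor(f_perm$gebv[names(f_orig$gebv)], f_orig$gebv), 0.995)
})

test_that("degenerate inputs are handled as contracts state", {
  tr <- make_small_trial(J = 12, I = 2, p = 200, seed = 40)
  omega <- build_omega("GBLUP", I = 2, env_ids = tr$env_ids)
  # constant phenotype: grand mean absorbs everything
  ph <- tr$pheno
  ph$value <- 7
  fit <- fit_gblup(ph, tr$g, omega, mcmc_config(n_iter = 600, burn_in = 200, seed = 41))
  expect_lt(abs(fit$mu_hat - 7), 0.05)
  expect_lt(max(abs(fit$gebv)), 0.05)

  # a line absent from training is an error naming the line
  ph2 <- tr$pheno[tr$pheno$line != "L3", ]
  expect_error(fit_gblup(ph2, tr$g, omega, mcmc_config(400, 100, seed = 1)), "L3")
})

test_that("the first-stage unstructured fit recovers covariance structure", {
  # single environment: Omega + R matches the phenotypic variance
  tr <- make_small_trial(J = 60, I = 1, p = 300, seed = 50,
                         sigma2_env = 0, sigma2_gxe = 0,
                         sigma2_gen = 1, sigma2_res = 1, omega_true = diag(1))
  y1 <- pheno_to_wide(tr$pheno)
  mt1 <- fit_multitrait_unstructured(y1, tr$g,
                                     mcmc_config(n_iter = 1500, burn_in = 500, seed = 51))
  expect_equal(dim(mt1$omega_gen), c(1L, 1L))
  total <- mt1$omega_gen[1, 1] + mt1$omega_res[1, 1]
  expect_lt(abs(total - var(y1[, 1])) / var(y1[, 1]), 0.35)

  # determinism
  mt1b <- fit_multitrait_unstructured(y1, tr$g,
                                      mcmc_config(n_iter = 1500, burn_in = 500, seed = 51))
  expect_identical(mt1$omega_gen, mt1b$omega_gen)

  # an environment with no observations is an error
  y_bad <- cbind(y1, Env2 = NA_real_)
  expect_error(fit_multitrait_unstructured(y_bad, tr$g,
                                           mcmc_config(400, 100, seed = 1)),
               "Env2")
})

test_that("the Hadamard interaction kernel is PSD when both factors are", {
  set.seed(60)
  for (rep in 1:5) {
    J <- sample(5:12, 1); I <- sample(2:5, 1)
    A <- crossprod(matrix(rnorm(J * J), J))
    B <- crossprod(matrix(rnorm(I * I), I))
    Zg <- diag(J)[rep(seq_len(J), I), ]
    Ze <- diag(I)[rep(seq_len(I), each = J), ]
    K <- (Zg %*% A %*% t(Zg)) * (Ze %*% B %*% t(Ze))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})
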