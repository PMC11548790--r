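# Shared fixtures and the independent closed-form oracle used to validate
# the Gibbs sampler.

# small relationship matrix + complete trial, built fresh from the generator
make_small_trial <- function(J = 40, I = 3, p = 400, seed = 7, ...) {
  m <- simulate_markers(J, p, seed = seed)
  g <- grm_vanraden(impute_missing(m, seed = seed))
  met <- simulate_met(g, I, seed = seed + 1, ...)
  list(g = g, pheno = met$pheno, truth = met$truth,
       env_ids = paste0("Env", seq_len(I)))
}

# GLS / mixed-model-equations oracle: with known variance components the
# posterior mean of each random effect is its BLUP
#   u_hat = sigma2_t * K_t[, obs] %*% V^{-1} (y - mu_hat),
# with V the phenotypic covariance of the observed cells and mu_hat the GLS
# grand mean. Direct dense solve; independent of the sampler's eigenbasis
# representation.
oracle_blup <- function(pheno, g, omega, v) {
  lines <- rownames(g); envs <- colnames(omega)
  li <- match(as.character(pheno$line), lines)
  ei <- match(as.character(pheno$env), envs)
  n <- nrow(pheno)
  Kg <- g[li, li]
  Ko <- omega[ei, ei]
  V <- v$var_gen * Kg + v$var_env * Ko + v$var_gxe * (Kg * Ko) +
    v$var_res * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% pheno$value) / crossprod(one, Vi %*% one))
  a <- Vi %*% (pheno$value - mu)
  env_eff <- v$var_env * drop(omega[, ei, drop = FALSE] %*% a)
  gebv <- v$var_gen * drop(g[, li, drop = FALSE] %*% a)
  J <- length(lines); I <- length(envs)
  gxe <- matrix(0, J, I, dimnames = list(lines, envs))
  for (jj in seq_len(J)) for (ii in seq_len(I))
    gxe[jj, ii] <- v$var_gxe * sum(g[jj, li] * omega[ii, ei] * a)
  list(mu = mu, env = env_eff, gebv = gebv, gxe = gxe)
}

# mask a fraction of grid cells while keeping every line trained
mask_trial <- function(pheno, g, env_ids, train_frac = 2 / 3, seed = 9) {
  parts <- cv_partitions(rownames(g), env_ids, n_partitions = 1,
                         train_frac = train_frac,
                         allocation_method = "Random", seed = seed)
  yw <- pheno_to_wide(pheno, rownames(g), env_ids)
  ytr <- yw
  ytr[!parts[[1]]$train] <- NA
  list(train = wide_to_pheno(ytr), mask = parts[[1]], y_full = yw)
}
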