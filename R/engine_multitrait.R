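# First-stage multi-environment GBLUP with unstructured between-environment
# genetic and residual covariances, fitted by Gibbs sampling with
# inverse-Wishart priors and missing-cell data augmentation.

#' MCMC configuration for the Gibbs samplers
#'
#' @param n_iter total Gibbs iterations (default 20000).
#' @param burn_in discarded warm-up iterations (default 10000).
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @param seed integer seed; identical configurations and data give
#'   bitwise-identical posterior means.
#' @param prior_df prior degrees of freedom for all variance(-matrix) priors
#'   (default 5).
#' @param prior_scale_fraction fraction of the phenotypic variance assigned
#'   a priori to the non-residual model terms jointly (default 0.5); the
#'   remainder goes to the residual.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000L, burn_in = 10000L, thin = 1L, seed = 1L,
                        prior_df = 5, prior_scale_fraction = 0.5) {
  n_iter <- stopifnot_scalar_count(n_iter, "n_iter", 2L)
  burn_in <- stopifnot_scalar_count(burn_in, "burn_in", 0L)
  thin <- stopifnot_scalar_count(thin, "thin", 1L)
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  if (prior_df <= 0) stop("`prior_df` must be positive", call. = FALSE)
  if (!(prior_scale_fraction > 0 && prior_scale_fraction < 1))
    stop("`prior_scale_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), prior_df = prior_df,
                 prior_scale_fraction = prior_scale_fraction),
            class = "mcmc_config")
}

#' First-stage unstructured environment-covariance fit
#'
#' Gibbs sampler for the multi-response model `Y = 1 mu' + U + E` on a lines
#' x environments matrix: rows of `U` share the genomic relationship
#' structure `G` across lines and an unstructured covariance `Omega` across
#' environments; rows of `E` are independent with unstructured residual
#' covariance `R`. Both covariance matrices carry inverse-Wishart priors with
#' `prior_df` degrees of freedom and identity scale, and masked (testing)
#' cells are handled by data augmentation. The posterior means of `Omega` and
#' `R` are the genetic and residual between-environment covariances consumed
#' by [build_omega()].
#'
#' @param y_wide J x I numeric matrix of adjusted phenotypes; `NA` marks
#'   masked (testing) cells. Row names are line ids, column names
#'   environment ids.
#' @param g J x J genomic relationship matrix, rows matching `y_wide`.
#' @param config an [mcmc_config()].
#' @return An object of class `multitrait_fit` with `omega_gen` (posterior
#'   mean genetic covariance between environments), `omega_res` (posterior
#'   mean residual covariance), `mu`, `u_hat` (posterior mean line values per
#'   environment), `n_samples_used` and `env_ids`.
#' @export
fit_multitrait_unstructured <- function(y_wide, g, config = mcmc_config()) {
  if (!is.matrix(y_wide)) stop("`y_wide` must be a lines x environments matrix", call. = FALSE)
  J <- nrow(y_wide); I <- ncol(y_wide)
  if (I < 1L) stop("need at least one environment", call. = FALSE)
  n_obs_env <- colSums(!is.na(y_wide))
  if (any(n_obs_env == 0L))
    stop("environment(s) with no observed cells: ",
         paste(colnames(y_wide)[n_obs_env == 0L], collapse = ", "), call. = FALSE)
  if (!is.null(rownames(y_wide)) && !is.null(rownames(g))) {
    if (!all(rownames(y_wide) %in% rownames(g)))
      stop("lines in `y_wide` missing from G", call. = FALSE)
    g <- g[rownames(y_wide), rownames(y_wide)]
  }
  if (nrow(g) != J) stop("G dimension does not match the number of lines", call. = FALSE)
  g <- repair_psd(g, mode = "jitter", name = "G")

  eg <- eigen(g, symmetric = TRUE)
  d <- pmax(eg$values, 1e-8)
  Q <- eg$vectors

  df0 <- config$prior_df
  if (df0 <= I - 1)
    stop("`prior_df` must exceed the number of environments minus one", call. = FALSE)
  S0 <- diag(I)

  miss <- is.na(y_wide)
  any_miss <- any(miss)
  # group rows by missing pattern for vectorised conditional imputation
  if (any_miss) {
    pat <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
    groups <- split(seq_len(J), pat)
    groups <- groups[vapply(groups, function(idx) any(miss[idx[1L], ]), logical(1L))]
  }

  n_keep <- length(seq(config$burn_in + 1L, config$n_iter, by = config$thin))
  sum_omega <- matrix(0, I, I)
  sum_res <- matrix(0, I, I)
  sum_mu <- numeric(I)
  sum_u <- matrix(0, J, I)

  with_seed(config$seed, {
    mu <- colMeans(y_wide, na.rm = TRUE)
    yimp <- y_wide
    for (i in seq_len(I)) yimp[miss[, i], i] <- mu[i]
    U <- matrix(0, J, I)
    Omega <- diag(I)
    Rres <- diag(I)

    for (it in seq_len(config$n_iter)) {
      # 1. impute masked cells from their row-conditional normal
      if (any_miss) {
        for (idx in groups) {
          mi <- which(miss[idx[1L], ]); oi <- which(!miss[idx[1L], ])
          mean_mat <- sweep(U[idx, , drop = FALSE], 2L, mu, "+")
          if (length(oi) == 0L) {
            cm <- mean_mat[, mi, drop = FALSE]
            cv <- Rres[mi, mi, drop = FALSE]
          } else {
            Roo_inv <- solve(Rres[oi, oi, drop = FALSE])
            Rmo <- Rres[mi, oi, drop = FALSE]
            resid_o <- yimp[idx, oi, drop = FALSE] - mean_mat[, oi, drop = FALSE]
            cm <- mean_mat[, mi, drop = FALSE] + resid_o %*% t(Rmo %*% Roo_inv)
            cv <- Rres[mi, mi, drop = FALSE] - Rmo %*% Roo_inv %*% t(Rmo)
          }
          cv <- (cv + t(cv)) / 2
          L <- chol(cv + diag(1e-12, length(mi)))
          z <- matrix(stats::rnorm(length(idx) * length(mi)), length(idx))
          yimp[idx, mi] <- cm + z %*% L
        }
      }

      # 2. environment means (flat prior)
      Emat <- yimp - U
      mu <- colMeans(Emat) +
        drop(stats::rnorm(I) %*% chol((Rres + t(Rres)) / (2 * J)))

      # 3. line values U via double diagonalisation of (Omega, Rres)
      er <- eigen((Rres + t(Rres)) / 2, symmetric = TRUE)
      r_half_inv <- er$vectors %*% (t(er$vectors) / sqrt(pmax(er$values, 1e-10)))
      r_half <- er$vectors %*% (t(er$vectors) * sqrt(pmax(er$values, 1e-10)))
      M <- r_half_inv %*% Omega %*% r_half_inv
      em <- eigen((M + t(M)) / 2, symmetric = TRUE)
      gam <- pmax(em$values, 0)
      B <- r_half_inv %*% em$vectors          # row transform: cov(u' B) = diag
      B_inv <- t(em$vectors) %*% r_half
      Ybar <- (crossprod(Q, sweep(yimp, 2L, mu))) %*% B
      shrink <- outer(d, gam) / (outer(d, gam) + 1)
      Ubar <- shrink * Ybar +
        sqrt(shrink) * matrix(stats::rnorm(J * I), J, I)
      Ut <- Ubar %*% B_inv                    # back to environment scale (G-eigenbasis)
      U <- Q %*% Ut

      # 4. covariance updates (inverse-Wishart)
      Omega <- riwish(df0 + J, S0 + crossprod(Ut, Ut / d))
      Emat <- sweep(yimp - U, 2L, mu)
      Rres <- riwish(df0 + J, S0 + crossprod(Emat))

      if (it > config$burn_in && (it - config$burn_in - 1L) %% config$thin == 0L) {
        sum_omega <- sum_omega + Omega
        sum_res <- sum_res + Rres
        sum_mu <- sum_mu + mu
        sum_u <- sum_u + U
      }
    }
  })

  env_ids <- colnames(y_wide) %||% paste0("Env", seq_len(I))
  omega_gen <- sum_omega / n_keep
  omega_res <- sum_res / n_keep
  dimnames(omega_gen) <- dimnames(omega_res) <- list(env_ids, env_ids)
  structure(list(
    omega_gen = omega_gen,
    omega_res = omega_res,
    mu = stats::setNames(sum_mu / n_keep, env_ids),
    u_hat = sum_u / n_keep,
    n_samples_used = n_keep,
    env_ids = env_ids,
    config = config
  ), class = "multitrait_fit")
}

#' @export
print.multitrait_fit <- function(x, ...) {
  cg <- stats::cov2cor(x$omega_gen)
  cat(sprintf("Multi-environment unstructured fit: %d environments, %d posterior samples\n",
              length(x$env_ids), x$n_samples_used))
  cat("  genetic correlations between environments:\n")
  print(round(cg, 3))
  invisible(x)
}

#' Build an environment covariance matrix for a prediction method
#'
#' Returns the between-environment covariance `Omega_E` used by the second
#' stage, according to the method tag:
#' \describe{
#'   \item{GBLUP, GBLUP_TRN}{identity matrix (no environment structure).}
#'   \item{GBLUP_CE}{the first-stage genetic covariance `omega_gen`.}
#'   \item{GBLUP_CE_Abs}{elementwise absolute value of `omega_gen`.}
#'   \item{GBLUP_CE_mean}{`0.5 * omega_gen + 0.5 * omega_res`.}
#'   \item{GBLUP_CE_Res}{the residual covariance `omega_res`.}
#' }
#' Derived matrices (absolute value, average) need not be positive
#' semi-definite; negative eigenvalues are clipped at zero and a 1e-8 jitter
#' added, with the repair recorded in attribute `psd_repair`.
#'
#' @param method_tag one of `"GBLUP"`, `"GBLUP_CE"`, `"GBLUP_CE_Abs"`,
#'   `"GBLUP_CE_mean"`, `"GBLUP_CE_Res"`, `"GBLUP_TRN"`.
#' @param mt a `multitrait_fit` (required for the CE variants).
#' @param I number of environments (required for the identity methods when
#'   `mt` is absent).
#' @param env_ids optional environment ids for the dimnames.
#' @return I x I covariance matrix with attributes `method_tag` and (when a
#'   repair occurred) `psd_repair`.
#' @export
build_omega <- function(method_tag, mt = NULL, I = NULL, env_ids = NULL) {
  tags <- c("GBLUP", "GBLUP_CE", "GBLUP_CE_Abs", "GBLUP_CE_mean", "GBLUP_CE_Res", "GBLUP_TRN")
  if (!(is.character(method_tag) && length(method_tag) == 1L && method_tag %in% tags))
    stop("unknown method tag: ", paste(method_tag, collapse = ", "),
         " (expected one of ", paste(tags, collapse = ", "), ")", call. = FALSE)
  if (method_tag %in% c("GBLUP", "GBLUP_TRN")) {
    if (is.null(I)) {
      if (is.null(mt)) stop("provide `I` (or `mt`) for the identity methods", call. = FALSE)
      I <- length(mt$env_ids)
    }
    omega <- diag(I)
    env_ids <- env_ids %||% if (!is.null(mt)) mt$env_ids else paste0("Env", seq_len(I))
  } else {
    if (is.null(mt)) stop(method_tag, " requires a first-stage `multitrait_fit`", call. = FALSE)
    omega <- switch(method_tag,
      GBLUP_CE = mt$omega_gen,
      GBLUP_CE_Abs = abs(mt$omega_gen),
      GBLUP_CE_mean = 0.5 * mt$omega_gen + 0.5 * mt$omega_res,
      GBLUP_CE_Res = mt$omega_res)
    env_ids <- env_ids %||% mt$env_ids
  }
  omega <- repair_psd(omega, mode = "clip", name = paste("Omega_E for", method_tag))
  dimnames(omega) <- list(env_ids, env_ids)
  attr(omega, "method_tag") <- method_tag
  omega
}
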