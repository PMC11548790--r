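# Bayesian GBLUP for sparse multi-environment trials.
#
# Model for the BLUE of line j in environment i:
#   y_ij = mu + L_i + g_j + gL_ij + e_ij
# with L ~ N(0, sigma2_env * Omega_E), g ~ N(0, sigma2_gen * G),
# gL ~ N(0, sigma2_gxe * (Zg G Zg') o (Ze Omega_E Ze'))   (Hadamard product),
# e ~ iid N(0, sigma2_res).
#
# Over the full lines x environments grid in environment-major order the
# interaction kernel is the Kronecker product Omega_E (x) G, so all effects
# are sampled in the eigenbases of G and Omega_E with O(J^2 I + J I^2) work
# per iteration; held-out cells enter as missing-data nodes (data
# augmentation), which also yields their predictive posterior means.

#' Fit the sparse-testing GBLUP model by Gibbs sampling
#'
#' Fits the single-response model `y_ij = mu + L_i + g_j + gL_ij + e_ij` on
#' the training records, with environment effects structured by `omega`, line
#' effects by the genomic relationship matrix `g`, and the
#' genotype-by-environment term by the Hadamard (here Kronecker) product of
#' the two kernels. All four variance components carry scaled-inverse-
#' chi-square priors whose modes split the phenotypic variance according to
#' `prior_scale_fraction`. Cells of the full line x environment grid that are
#' absent from `pheno` are treated as missing-data nodes, so their posterior
#' predictive means are available to [predict_cells()].
#'
#' @param pheno data.frame of training records with columns `line`, `env`,
#'   `value`; every line of `g` must appear at least once.
#' @param g J x J genomic relationship matrix with line ids as dimnames.
#' @param omega I x I environment covariance from [build_omega()] (identity
#'   for the plain GBLUP and GBLUP_TRN methods).
#' @param config an [mcmc_config()].
#' @param fixed_variances optional named list fixing any of `var_env`,
#'   `var_gen`, `var_gxe`, `var_res` at given values (their Gibbs updates are
#'   disabled); `var_gxe = 0` removes the interaction term.
#' @return An object of class `gblup_fit` with posterior means: `mu_hat`,
#'   `env_effects` (length I), `gebv` (length J), `gxe_effects` (J x I),
#'   variance components `var_env`, `var_gen`, `var_gxe`, `var_res`, the
#'   posterior-mean grid predictions `yhat_grid`, and bookkeeping (`line_ids`,
#'   `env_ids`, `config`, `method_tag`).
#' @export
fit_gblup <- function(pheno, g, omega, config = mcmc_config(), fixed_variances = NULL) {
  check_pheno_table(pheno)
  if (is.null(rownames(g))) stop("G must carry line ids as dimnames", call. = FALSE)
  line_ids <- rownames(g)
  env_ids <- colnames(omega) %||% sort(unique(as.character(pheno$env)))
  I <- ncol(omega)
  if (length(env_ids) != I) stop("environment ids do not match `omega` dimension", call. = FALSE)
  bad_env <- setdiff(unique(as.character(pheno$env)), env_ids)
  if (length(bad_env))
    stop("environments not present in `omega`: ", paste(bad_env, collapse = ", "), call. = FALSE)
  bad_line <- setdiff(unique(as.character(pheno$line)), line_ids)
  if (length(bad_line))
    stop("lines not present in G: ", paste(bad_line, collapse = ", "), call. = FALSE)
  untrained <- setdiff(line_ids, unique(as.character(pheno$line)))
  if (length(untrained))
    stop("line(s) absent from the training records: ",
         paste(untrained, collapse = ", "),
         " (every line must be observed in at least one environment)", call. = FALSE)

  y <- pheno_to_wide(pheno, line_ids = line_ids, env_ids = env_ids)
  J <- length(line_ids)
  n <- J * I
  miss <- is.na(y)
  obs_vals <- y[!miss]

  g <- repair_psd(g[line_ids, line_ids], mode = "jitter", name = "G")
  omega <- check_symmetric(unclass(omega), name = "Omega_E")

  eg <- eigen(g, symmetric = TRUE)
  keep_g <- eg$values > 1e-8 * max(eg$values)
  Qg <- eg$vectors[, keep_g, drop = FALSE]
  dg <- eg$values[keep_g]
  eo <- eigen(omega, symmetric = TRUE)
  if (min(eo$values) < -1e-8)
    stop("`omega` is not positive semi-definite after repair", call. = FALSE)
  keep_o <- eo$values > 1e-8 * max(eo$values)
  Po <- eo$vectors[, keep_o, drop = FALSE]
  lam <- eo$values[keep_o]
  mg <- length(dg); mo <- length(lam)

  df0 <- config$prior_df
  psf <- config$prior_scale_fraction
  vy <- max(stats::var(obs_vals), 1e-6)
  scale_term <- (psf * vy / 3) * (df0 + 2) / df0
  scale_res <- ((1 - psf) * vy) * (df0 + 2) / df0

  fv <- fixed_variances %||% list()
  use_gxe <- !(("var_gxe" %in% names(fv)) && fv$var_gxe == 0)
  dl <- if (use_gxe) outer(dg, lam) else NULL  # interaction eigenvalues

  n_keep <- length(seq(config$burn_in + 1L, config$n_iter, by = config$thin))
  sum_mu <- 0; sum_env <- numeric(I); sum_g <- numeric(J)
  sum_gl <- matrix(0, J, I); sum_fit <- matrix(0, J, I)
  sum_v <- c(env = 0, gen = 0, gxe = 0, res = 0)

  with_seed(config$seed, {
    mu <- mean(obs_vals)
    lvec <- numeric(I)          # environment effects
    gvec <- numeric(J)          # line effects (GEBVs)
    gl <- matrix(0, J, I)       # interaction effects on the grid
    v_env <- fv$var_env %||% (psf * vy / 3)
    v_gen <- fv$var_gen %||% (psf * vy / 3)
    v_gxe <- if (use_gxe) fv$var_gxe %||% (psf * vy / 3) else 0
    v_res <- fv$var_res %||% ((1 - psf) * vy)
    yimp <- y
    yimp[miss] <- mu

    for (it in seq_len(config$n_iter)) {
      fitted <- mu + outer(gvec, lvec, "+") + gl

      # impute held-out cells
      if (any(miss))
        yimp[miss] <- fitted[miss] + stats::rnorm(sum(miss), 0, sqrt(v_res))

      # grand mean (flat prior)
      resid0 <- yimp - (fitted - mu)
      mu <- stats::rnorm(1L, mean(resid0), sqrt(v_res / n))

      # environment effects in the Omega_E eigenbasis
      rm_env <- yimp - mu - gvec - gl       # gvec recycles down columns
      ce <- drop(crossprod(Po, colSums(rm_env)))
      ve <- 1 / (J / v_res + 1 / (v_env * lam))
      be <- ve * ce / v_res + sqrt(ve) * stats::rnorm(mo)
      lvec <- drop(Po %*% be)

      # line effects in the G eigenbasis
      rm_gen <- sweep(yimp - mu - gl, 2L, lvec)
      cg <- drop(crossprod(Qg, rowSums(rm_gen)))
      vg <- 1 / (I / v_res + 1 / (v_gen * dg))
      bg <- vg * cg / v_res + sqrt(vg) * stats::rnorm(mg)
      gvec <- drop(Qg %*% bg)

      # interaction effects in the Kronecker eigenbasis
      if (use_gxe) {
        rm_gxe <- sweep(yimp - mu - gvec, 2L, lvec)
        C <- crossprod(Qg, rm_gxe %*% Po)
        vl <- 1 / (1 / v_res + 1 / (v_gxe * dl))
        Bco <- vl * C / v_res + sqrt(vl) * matrix(stats::rnorm(mg * mo), mg, mo)
        gl <- Qg %*% tcrossprod(Bco, Po)
      }

      # variance components (scaled-inverse-chi-square)
      if (is.null(fv$var_env))
        v_env <- rinvchisq(df0 + mo, (df0 * scale_term + sum(be^2 / lam)) / (df0 + mo))
      if (is.null(fv$var_gen))
        v_gen <- rinvchisq(df0 + mg, (df0 * scale_term + sum(bg^2 / dg)) / (df0 + mg))
      if (use_gxe && is.null(fv$var_gxe))
        v_gxe <- rinvchisq(df0 + mg * mo,
                           (df0 * scale_term + sum(Bco^2 / dl)) / (df0 + mg * mo))
      if (is.null(fv$var_res)) {
        fitted <- mu + outer(gvec, lvec, "+") + gl
        sse <- sum((yimp - fitted)^2)
        v_res <- rinvchisq(df0 + n, (df0 * scale_res + sse) / (df0 + n))
      }

      if (it > config$burn_in && (it - config$burn_in - 1L) %% config$thin == 0L) {
        sum_mu <- sum_mu + mu
        sum_env <- sum_env + lvec
        sum_g <- sum_g + gvec
        sum_gl <- sum_gl + gl
        sum_fit <- sum_fit + (mu + outer(gvec, lvec, "+") + gl)
        sum_v <- sum_v + c(v_env, v_gen, v_gxe, v_res)
      }
    }
  })

  yhat <- sum_fit / n_keep
  dimnames(yhat) <- list(line_ids, env_ids)
  gxe <- sum_gl / n_keep
  dimnames(gxe) <- list(line_ids, env_ids)
  vbar <- sum_v / n_keep
  structure(list(
    mu_hat = sum_mu / n_keep,
    env_effects = stats::setNames(sum_env / n_keep, env_ids),
    gebv = stats::setNames(sum_g / n_keep, line_ids),
    gxe_effects = gxe,
    var_env = unname(vbar["env"]),
    var_gen = unname(vbar["gen"]),
    var_gxe = unname(vbar["gxe"]),
    var_res = unname(vbar["res"]),
    yhat_grid = yhat,
    n_samples_used = n_keep,
    line_ids = line_ids,
    env_ids = env_ids,
    method_tag = attr(omega, "method_tag") %||% NA_character_,
    config = config
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit (%s): %d lines x %d environments, %d posterior samples\n",
              x$method_tag, length(x$line_ids), length(x$env_ids), x$n_samples_used))
  cat(sprintf("  mu = %.3f; variances: env %.3f, gen %.3f, gxe %.3f, res %.3f\n",
              x$mu_hat, x$var_env, x$var_gen, x$var_gxe, x$var_res))
  invisible(x)
}

#' Predicted values for line-environment cells
#'
#' Returns the posterior mean of `mu + L_i + g_j + gL_ij` for each requested
#' cell. For cells that were held out of training, `gL_ij` is the posterior
#' mean obtained by treating the cell as a missing-data node of the joint
#' kernel during sampling; predictions are deterministic given the fit.
#'
#' @param fit a `gblup_fit`.
#' @param cells data.frame with columns `line` and `env`.
#' @return numeric vector of predictions, one per row of `cells`.
#' @export
predict_cells <- function(fit, cells) {
  if (!all(c("line", "env") %in% names(cells)))
    stop("`cells` must have columns line and env", call. = FALSE)
  i <- match(as.character(cells$line), fit$line_ids)
  j <- match(as.character(cells$env), fit$env_ids)
  if (anyNA(i))
    stop("unknown line(s): ",
         paste(unique(cells$line[is.na(i)]), collapse = ", "), call. = FALSE)
  if (anyNA(j))
    stop("unknown environment(s): ",
         paste(unique(cells$env[is.na(j)]), collapse = ", "), call. = FALSE)
  fit$yhat_grid[cbind(i, j)]
}

#' Across-TPE genomic scores of a fit
#'
#' The per-line score `mu + g_j` (grand mean plus GEBV) computed from the
#' observed data only — the predictor the GBLUP_TRN method uses for every
#' held-out cell of line j. Rankings equal GEBV rankings.
#'
#' @param fit a `gblup_fit` whose training data observed every line at least
#'   once.
#' @return named numeric vector of per-line scores.
#' @export
gebv_across_tpe <- function(fit) {
  fit$mu_hat + fit$gebv
}

#' Export a fit as JSON plus CSV effect tables
#'
#' Writes `<path>.json` (grand mean, variance components, method tag) and
#' `<path>_effects.csv` (per-line GEBVs and per-cell interaction effects).
#'
#' @param fit a `gblup_fit`.
#' @param path output path stem.
#' @export
write_gblup_fit <- function(fit, path) {
  jsonlite::write_json(list(
    method_tag = fit$method_tag,
    mu_hat = fit$mu_hat,
    var_env = fit$var_env, var_gen = fit$var_gen,
    var_gxe = fit$var_gxe, var_res = fit$var_res,
    n_samples_used = fit$n_samples_used
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  eff <- data.frame(line = fit$line_ids, gebv = unname(fit$gebv))
  eff <- cbind(eff, as.data.frame(fit$gxe_effects))
  utils::write.csv(eff, paste0(path, "_effects.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}
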