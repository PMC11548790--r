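# Synthetic marker and multi-environment phenotype data with known truths:
# the generator mirrors the additive + environment + Hadamard-interaction
# structure of the fitted model, providing recovery targets for the engine.

#' Simulate a SNP dosage matrix
#'
#' Markers are independent: each marker draws an allele frequency uniformly
#' from `maf_range` and line dosages as Binomial(2, p_j)
#' (Hardy-Weinberg proportions); a fraction of cells is masked as missing
#' uniformly at random.
#'
#' @param J number of lines (>= 2).
#' @param p number of markers (>= 2).
#' @param maf_range allele-frequency range, within (0, 0.5\]; default
#'   (0.1, 0.5).
#' @param missing_frac fraction of cells set to NA (default 0).
#' @param seed integer seed.
#' @return lines x markers dosage matrix with ids `L1..LJ` / `M1..Mp`.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.1, 0.5), missing_frac = 0,
                             seed = 1L) {
  J <- stopifnot_scalar_count(J, "J", 2L)
  p <- stopifnot_scalar_count(p, "p", 2L)
  if (!(length(maf_range) == 2L && maf_range[1L] > 0 && maf_range[2L] <= 0.5 &&
        maf_range[1L] <= maf_range[2L]))
    stop("`maf_range` must be (low, high) within (0, 0.5]", call. = FALSE)
  if (!(missing_frac >= 0 && missing_frac < 1))
    stop("`missing_frac` must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    freqs <- stats::runif(p, maf_range[1L], maf_range[2L])
    m <- matrix(stats::rbinom(J * p, 2L, rep(freqs, each = J)), J, p)
    if (missing_frac > 0) {
      n_miss <- round(missing_frac * length(m))
      m[safe_sample(seq_along(m), n_miss)] <- NA
    }
    storage.mode(m) <- "double"
    dimnames(m) <- list(paste0("L", seq_len(J)), paste0("M", seq_len(p)))
    attr(m, "true_freqs") <- freqs
    m
  })
}

#' Simulate a multi-environment trial with known truths
#'
#' Draws one complete lines x environments table of cell values
#' `y_ij = mu + L_i + g_j + gL_ij + e_ij` with
#' `L ~ N(0, sigma2_env * omega_true)`, `g ~ N(0, sigma2_gen * G)`,
#' `gL` drawn on the full grid from the Kronecker/Hadamard kernel
#' `sigma2_gxe * (omega_true (x) G)` via the eigendecompositions of both
#' factors, and iid residuals. The implied narrow-sense cell heritability
#' `h2 = sigma2_gen / (sigma2_gen + sigma2_gxe + sigma2_res)` is stored with
#' the truths.
#'
#' @param g J x J genomic relationship matrix with line-id dimnames.
#' @param I number of environments.
#' @param mu grand mean, in trait units (default 6, a typical grain yield in
#'   t/ha).
#' @param sigma2_env environment variance (default 1).
#' @param sigma2_gen additive genetic variance (default 1).
#' @param sigma2_gxe genotype-by-environment variance (default 0.5).
#' @param sigma2_res residual variance (default 0.5).
#' @param omega_true I x I environment covariance; default compound symmetry
#'   with correlation 0.5.
#' @param seed integer seed.
#' @return list with `pheno` (long data.frame `line`, `env`, `value` over the
#'   complete grid) and `truth`, a `sim_truth` list holding `true_mu`,
#'   `true_env_effects`, `true_gebv`, `true_gxe`, the four variance
#'   components, `omega_true`, `h2` and `seed`.
#' @export
simulate_met <- function(g, I, mu = 6, sigma2_env = 1, sigma2_gen = 1,
                         sigma2_gxe = 0.5, sigma2_res = 0.5,
                         omega_true = NULL, seed = 1L) {
  I <- stopifnot_scalar_count(I, "I", 1L)
  if (is.null(rownames(g))) stop("G must carry line ids as dimnames", call. = FALSE)
  if (any(c(sigma2_env, sigma2_gen, sigma2_gxe, sigma2_res) < 0))
    stop("variance components must be non-negative", call. = FALSE)
  omega_true <- omega_true %||% (0.5 * diag(I) + 0.5)
  omega_true <- check_symmetric(omega_true, name = "omega_true")
  if (nrow(omega_true) != I) stop("`omega_true` must be I x I", call. = FALSE)
  g <- check_symmetric(g, name = "G")
  J <- nrow(g)
  line_ids <- rownames(g)
  env_ids <- paste0("Env", seq_len(I))

  eg <- eigen(g, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop("G is not positive semi-definite", call. = FALSE)
  eo <- eigen(omega_true, symmetric = TRUE)
  if (min(eo$values) < -1e-8) stop("`omega_true` is not positive semi-definite", call. = FALSE)
  dg <- pmax(eg$values, 0); do_ <- pmax(eo$values, 0)

  out <- with_seed(seed, {
    lvec <- drop(eo$vectors %*% (sqrt(sigma2_env * do_) * stats::rnorm(I)))
    gvec <- drop(eg$vectors %*% (sqrt(sigma2_gen * dg) * stats::rnorm(J)))
    z <- matrix(stats::rnorm(J * I), J, I)
    gxe <- sqrt(sigma2_gxe) *
      (eg$vectors %*% (sqrt(dg) * z) %*% (sqrt(do_) * t(eo$vectors)))
    eps <- matrix(stats::rnorm(J * I, 0, sqrt(sigma2_res)), J, I)
    list(lvec = lvec, gvec = gvec, gxe = gxe, eps = eps)
  })

  y <- mu + outer(out$gvec, out$lvec, "+") + out$gxe + out$eps
  dimnames(y) <- list(line_ids, env_ids)
  pheno <- wide_to_pheno(y)

  truth <- structure(list(
    true_mu = mu,
    true_env_effects = stats::setNames(out$lvec, env_ids),
    true_gebv = stats::setNames(out$gvec, line_ids),
    true_gxe = structure(out$gxe, dimnames = list(line_ids, env_ids)),
    sigma2_env = sigma2_env, sigma2_gen = sigma2_gen,
    sigma2_gxe = sigma2_gxe, sigma2_res = sigma2_res,
    omega_true = structure(omega_true, dimnames = list(env_ids, env_ids)),
    h2 = sigma2_gen / (sigma2_gen + sigma2_gxe + sigma2_res),
    seed = as.integer(seed)
  ), class = "sim_truth")
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete sparse-testing scenario
#'
#' Convenience wrapper reproducing the package's default study shape:
#' simulate markers, run QC and imputation, build the VanRaden relationship
#' matrix and draw a multi-environment trial from it. Defaults follow the
#' scale of a single-season wheat TPE dataset: 166 lines, 4 environments,
#' 2000 markers, cell heritability 0.5.
#'
#' @param J,I,p lines, environments, markers.
#' @param seed master seed (markers use `seed`, phenotypes `seed + 1`).
#' @param ... further arguments passed to [simulate_met()].
#' @return list with `markers`, `g`, `pheno`, `truth`.
#' @export
simulate_scenario <- function(J = 166L, I = 4L, p = 2000L, seed = 1L, ...) {
  m <- simulate_markers(J, p, missing_frac = 0.02, seed = seed)
  qc <- qc_filter(m)
  m_complete <- impute_missing(qc$markers, seed = seed)
  g <- grm_vanraden(m_complete)
  met <- simulate_met(g, I, seed = seed + 1L, ...)
  list(markers = m_complete, g = g, pheno = met$pheno, truth = met$truth)
}
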