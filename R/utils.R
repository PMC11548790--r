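# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise
safe_sample <- function(x, size) {
  if (length(x) == 1L) return(rep(x, length.out = size))
  sample(x, size)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_symmetric <- function(m, tol = 1e-10, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop(sprintf("`%s` is not symmetric within tolerance", name), call. = FALSE)
  (m + t(m)) / 2
}

#' Repair a nearly positive semi-definite matrix
#'
#' Two repair modes are used in the package. `"jitter"` (for genomic
#' relationship matrices) tolerates eigenvalues down to `-1e-8` only, adding a
#' small diagonal jitter when the minimum eigenvalue is negative but within
#' that band, and fails otherwise so construction bugs are not masked.
#' `"clip"` (for derived environment covariances, e.g. elementwise absolute
#' values, which need not be PSD) clips negative eigenvalues at zero, adds the
#' jitter, and records the clipped mass.
#'
#' @param m symmetric matrix.
#' @param mode `"jitter"` or `"clip"`.
#' @param jitter diagonal value added when a repair is applied.
#' @param name label used in error messages.
#' @return The repaired matrix; attribute `psd_repair` holds a list with the
#'   minimum eigenvalue seen and (for `"clip"`) the total clipped eigenvalue
#'   mass, or `NULL` when no repair was needed.
#' @keywords internal
repair_psd <- function(m, mode = c("jitter", "clip"), jitter = 1e-8, name = "matrix") {
  mode <- match.arg(mode)
  m <- check_symmetric(m, name = name)
  ev <- eigen(m, symmetric = TRUE)
  min_ev <- min(ev$values)
  if (min_ev >= 0) {
    attr(m, "psd_repair") <- NULL
    return(m)
  }
  if (mode == "jitter") {
    if (min_ev < -1e-8)
      stop(sprintf("`%s` has eigenvalue %.3e below the -1e-8 tolerance; not a valid PSD matrix",
                   name, min_ev), call. = FALSE)
    out <- m + diag(jitter, nrow(m))
    attr(out, "psd_repair") <- list(mode = "jitter", min_eigenvalue = min_ev)
  } else {
    clipped <- sum(abs(ev$values[ev$values < 0]))
    vals <- pmax(ev$values, 0)
    out <- ev$vectors %*% (vals * t(ev$vectors))
    out <- (out + t(out)) / 2
    out <- out + diag(jitter, nrow(m))
    dimnames(out) <- dimnames(m)
    attr(out, "psd_repair") <- list(mode = "clip", min_eigenvalue = min_ev,
                                    clipped_mass = clipped)
  }
  out
}

# scaled-inverse-chi-square draw: df * scale / chisq(df)
rinvchisq <- function(df, scale) {
  df * scale / stats::rchisq(1L, df)
}

# inverse-Wishart draw IW(df, S): X^{-1} ~ Wishart(df, S^{-1})
riwish <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  solve(W)
}
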