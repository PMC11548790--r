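# Marker QC, imputation and the VanRaden genomic relationship matrix.
#
# A marker matrix is a plain numeric matrix of allele dosages (lines in rows,
# markers in columns) with values in {0, 1, 2} and NA for missing genotypes.
# Row names are line identifiers, column names marker identifiers.

check_marker_matrix <- function(m, allow_missing = TRUE, name = "marker matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("`%s` must be a numeric matrix (lines x markers)", name), call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("`%s` must carry line ids as rownames and marker ids as colnames", name),
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicated line ids in marker matrix", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicated marker ids in marker matrix", call. = FALSE)
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("marker dosages must be coded 0/1/2 (NA for missing)", call. = FALSE)
  if (!allow_missing && anyNA(m))
    stop(sprintf("`%s` contains missing genotypes; impute first", name), call. = FALSE)
  invisible(m)
}

#' Per-marker allele frequencies from non-missing genotypes
#'
#' Estimates the frequency of the counted (dosage) allele at each marker as the
#' mean dosage over non-missing lines divided by 2.
#'
#' @param m numeric lines x markers dosage matrix (0/1/2, NA missing) with row
#'   and column names.
#' @return Named numeric vector of frequencies in \[0, 1\], one per marker.
#' @examples
#' m <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(paste0("L", 1:4), "m1"))
#' allele_frequencies(m) # 0.5
#' @export
allele_frequencies <- function(m) {
  check_marker_matrix(m)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L))
    stop("markers with no non-missing genotypes: ",
         paste(colnames(m)[n_obs == 0L], collapse = ", "), call. = FALSE)
  colSums(m, na.rm = TRUE) / (2 * n_obs)
}

#' Marker quality control filter
#'
#' Removes markers in two fixed stages: first markers whose missing-data
#' fraction strictly exceeds `missing_max`, then markers whose minor allele
#' frequency (computed on non-missing genotypes of the survivors) is strictly
#' below `maf_min`. Line and marker order are preserved.
#'
#' @param m dosage matrix as in [allele_frequencies()].
#' @param maf_min minor allele frequency threshold in (0, 0.5]; default 0.05.
#' @param missing_max missing-fraction threshold in (0, 1); default 0.50.
#' @return A list with `markers` (the filtered matrix) and `report`, a
#'   `qc_report` with counts `n_markers_in`, `n_removed_missing`,
#'   `n_removed_maf`, `n_markers_out` and the thresholds used.
#' @export
qc_filter <- function(m, maf_min = 0.05, missing_max = 0.50) {
  check_marker_matrix(m)
  if (!(maf_min > 0 && maf_min <= 0.5)) stop("`maf_min` must be in (0, 0.5]", call. = FALSE)
  if (!(missing_max > 0 && missing_max < 1)) stop("`missing_max` must be in (0, 1)", call. = FALSE)
  n_in <- ncol(m)
  miss_frac <- colMeans(is.na(m))
  keep_miss <- miss_frac <= missing_max
  n_removed_missing <- sum(!keep_miss)
  m1 <- m[, keep_miss, drop = FALSE]
  if (ncol(m1) == 0L) stop("all markers removed by the missing-data filter", call. = FALSE)
  p <- allele_frequencies(m1)
  maf <- pmin(p, 1 - p)
  keep_maf <- maf >= maf_min
  n_removed_maf <- sum(!keep_maf)
  m2 <- m1[, keep_maf, drop = FALSE]
  if (ncol(m2) == 0L) stop("all markers removed by the MAF filter", call. = FALSE)
  report <- structure(list(
    n_markers_in = n_in,
    n_removed_missing = n_removed_missing,
    n_removed_maf = n_removed_maf,
    n_markers_out = ncol(m2),
    maf_threshold = maf_min,
    missing_threshold = missing_max
  ), class = "qc_report")
  list(markers = m2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC: %d in -> %d out (%d removed: %d missing > %.0f%%, %d MAF < %g)\n",
              x$n_markers_in, x$n_markers_out,
              x$n_removed_missing + x$n_removed_maf,
              x$n_removed_missing, 100 * x$missing_threshold,
              x$n_removed_maf, x$maf_threshold))
  invisible(x)
}

#' Impute missing genotypes from the marginal marker distribution
#'
#' Fills each missing cell at marker j with an independent draw from the
#' marginal genotype distribution parameterised by the allele frequency
#' estimated from the non-missing genotypes of that marker. The default
#' `"binomial2"` model draws Binomial(2, p_j) dosages, preserving the 0/1/2
#' coding; `"bernoulli"` draws Bernoulli(p_j) presence/absence codes for data
#' coded 0/1.
#'
#' @param m dosage matrix after [qc_filter()].
#' @param seed integer seed; identical seeds give identical imputations.
#' @param model `"binomial2"` (default) or `"bernoulli"`.
#' @return The matrix with all missing cells filled; non-missing cells are
#'   unchanged.
#' @export
impute_missing <- function(m, seed, model = c("binomial2", "bernoulli")) {
  check_marker_matrix(m)
  model <- match.arg(model)
  p <- allele_frequencies(m)
  miss <- which(is.na(m))
  if (length(miss) == 0L) return(m)
  pj <- p[((miss - 1L) %/% nrow(m)) + 1L]
  size <- if (model == "binomial2") 2L else 1L
  m[miss] <- with_seed(seed, stats::rbinom(length(miss), size, pj))
  m
}

#' VanRaden genomic relationship matrix
#'
#' Computes G = W W' / (2 * sum_j p_j (1 - p_j)) where W is the column-centred
#' dosage matrix (w_ij = x_ij - 2 p_j) and p_j the allele frequency of marker
#' j. The input must be complete (impute first). If the minimum eigenvalue of
#' G is negative but within -1e-8, a 1e-8 diagonal jitter is added; more
#' negative values raise an error.
#'
#' @param m complete dosage matrix (no NA), at least 2 polymorphic markers.
#' @return J x J genomic relationship matrix with line ids as dimnames.
#' @export
grm_vanraden <- function(m) {
  check_marker_matrix(m, allow_missing = FALSE)
  p <- allele_frequencies(m)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; the VanRaden denominator is zero", call. = FALSE)
  if (sum(p > 0 & p < 1) < 2L)
    stop("need at least 2 polymorphic markers to build G", call. = FALSE)
  w <- sweep(m, 2L, 2 * p)
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2
  dimnames(g) <- list(rownames(m), rownames(m))
  repair_psd(g, mode = "jitter", name = "genomic relationship matrix")
}
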