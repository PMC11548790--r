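# Readers and writers for the package's plain-text interchange formats.

#' Read a marker dosage matrix from CSV/TSV
#'
#' Expects a header row of marker ids and a first column of line ids; cells
#' are 0/1/2 dosages with empty or `NA` for missing.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma) unless `sep` is given.
#' @param sep optional field separator override.
#' @return numeric lines x markers matrix with dimnames.
#' @export
read_markers <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  check_marker_matrix(m)
  m
}

#' Write a marker dosage matrix to CSV
#' @param m marker matrix.
#' @param path output file path.
#' @export
write_markers <- function(m, path) {
  check_marker_matrix(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read diploid genotypes from a VCF file as alternate-allele dosages
#'
#' Converts the GT field of a diploid VCF to 0/1/2 dosage counts of the
#' alternate allele (missing genotypes become NA). Requires the `vcfR`
#' package.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return lines x markers dosage matrix (samples in rows).
#' @export
read_markers_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the `vcfR` package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1L, 2L), function(x) {
    if (is.na(x) || grepl("\\.", x)) return(NA_real_)
    alleles <- strsplit(x, "[/|]")[[1L]]
    if (length(alleles) != 2L) return(NA_real_)
    sum(alleles != "0")
  })
  m <- t(dose)  # samples in rows
  colnames(m) <- rownames(gt)
  check_marker_matrix(m)
  m
}

#' Write / read a genomic relationship matrix as CSV
#'
#' Line ids appear both as the header and as the first column.
#' @param g symmetric relationship matrix with line-id dimnames.
#' @param path file path.
#' @export
write_grm <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  g <- as.matrix(df)
  storage.mode(g) <- "double"
  if (!identical(rownames(g), colnames(g)))
    stop("G matrix file must have identical row and column line ids", call. = FALSE)
  check_symmetric(g, name = "G")
}

#' Read a long-format phenotype table
#'
#' Expects columns `line`, `env`, `value` (extra columns are ignored); one
#' record per line-environment cell.
#'
#' @param path CSV file path.
#' @return data.frame with columns `line`, `env`, `value`.
#' @export
read_pheno <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "env", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns line, env, value", call. = FALSE)
  df <- df[, need]
  df$value <- as.numeric(df$value)
  check_pheno_table(df)
  df
}

check_pheno_table <- function(pheno) {
  if (!is.data.frame(pheno) || !all(c("line", "env", "value") %in% names(pheno)))
    stop("phenotypes must be a data.frame with columns line, env, value", call. = FALSE)
  key <- paste(pheno$line, pheno$env, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate line-environment records in phenotype table", call. = FALSE)
  invisible(pheno)
}

#' Convert a long phenotype table to a lines x environments matrix
#'
#' Unobserved cells become NA; this wide layout is the input of the
#' first-stage multi-environment (unstructured covariance) fit.
#'
#' @param pheno data.frame with columns `line`, `env`, `value`.
#' @param line_ids,env_ids optional orderings; default sorted unique values.
#' @return J x I numeric matrix with NA for unobserved cells.
#' @export
pheno_to_wide <- function(pheno, line_ids = NULL, env_ids = NULL) {
  check_pheno_table(pheno)
  line_ids <- line_ids %||% sort(unique(as.character(pheno$line)))
  env_ids <- env_ids %||% sort(unique(as.character(pheno$env)))
  y <- matrix(NA_real_, length(line_ids), length(env_ids),
              dimnames = list(line_ids, env_ids))
  i <- match(as.character(pheno$line), line_ids)
  j <- match(as.character(pheno$env), env_ids)
  if (anyNA(i) || anyNA(j))
    stop("phenotype table contains lines/environments outside the requested ids", call. = FALSE)
  y[cbind(i, j)] <- pheno$value
  y
}

#' Convert a wide phenotype matrix to the long table format
#' @param y lines x environments matrix (NA = unobserved).
#' @return data.frame with columns `line`, `env`, `value` (observed cells only).
#' @export
wide_to_pheno <- function(y) {
  obs <- which(!is.na(y), arr.ind = TRUE)
  data.frame(line = rownames(y)[obs[, 1L]],
             env = colnames(y)[obs[, 2L]],
             value = y[obs],
             stringsAsFactors = FALSE)
}
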