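# Orchestration of a full sparse-testing evaluation: data (loaded or
# simulated) -> marker QC -> G -> cross-validation designs -> six
# prediction methods x two allocation schemes -> metrics report.

ALL_METHODS <- c("GBLUP", "GBLUP_CE", "GBLUP_CE_Abs", "GBLUP_CE_mean",
                 "GBLUP_CE_Res", "GBLUP_TRN")

#' Build and validate a run configuration
#'
#' Either `marker_file`/`pheno_file` (CSV paths, see [read_markers()] and
#' [read_pheno()]) or a `simulation` block (arguments for
#' [simulate_scenario()]) must be supplied. A configuration can also be read
#' from a YAML file with [read_run_config()].
#'
#' @param marker_file,pheno_file optional input CSV paths.
#' @param simulation optional named list passed to [simulate_scenario()].
#' @param methods method tags to evaluate (default all six).
#' @param allocations allocation schemes (default `c("IBD", "Random")`).
#' @param n_partitions cross-validation partitions (default 10).
#' @param train_frac training fraction (default 0.5).
#' @param mcmc an [mcmc_config()]; its seed is overridden per fit from
#'   `seed`.
#' @param nrmse_normalizer,top_fracs metric options.
#' @param impute_model `"binomial2"` or `"bernoulli"` (see
#'   [impute_missing()]).
#' @param maf_min,missing_max marker QC thresholds.
#' @param out_dir optional output directory; when given, CSV/JSON reports and
#'   a manifest are written there.
#' @param seed master seed for designs, imputation and samplers.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(marker_file = NULL, pheno_file = NULL, simulation = NULL,
                       methods = ALL_METHODS,
                       allocations = c("IBD", "Random"),
                       n_partitions = 10L, train_frac = 0.5,
                       mcmc = mcmc_config(),
                       nrmse_normalizer = "mean", top_fracs = c(0.10, 0.20),
                       impute_model = "binomial2",
                       maf_min = 0.05, missing_max = 0.50,
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulation) && (is.null(marker_file) || is.null(pheno_file)))
    stop("provide `marker_file` and `pheno_file`, or a `simulation` block", call. = FALSE)
  bad <- setdiff(methods, ALL_METHODS)
  if (length(bad))
    stop("unknown method tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad_alloc <- setdiff(allocations, c("IBD", "Random"))
  if (length(bad_alloc))
    stop("unknown allocation(s): ", paste(bad_alloc, collapse = ", "), call. = FALSE)
  if (!inherits(mcmc, "mcmc_config")) mcmc <- do.call(mcmc_config, as.list(mcmc))
  n_partitions <- stopifnot_scalar_count(n_partitions, "n_partitions", 1L)
  structure(list(
    marker_file = marker_file, pheno_file = pheno_file, simulation = simulation,
    methods = methods, allocations = allocations,
    n_partitions = n_partitions, train_frac = train_frac,
    mcmc = mcmc, nrmse_normalizer = nrmse_normalizer, top_fracs = top_fracs,
    impute_model = impute_model, maf_min = maf_min, missing_max = missing_max,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mcmc)) raw$mcmc <- do.call(mcmc_config, raw$mcmc)
  do.call(run_config, raw)
}

# load or simulate the inputs declared in a config
resolve_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    sc <- do.call(simulate_scenario, sim_args)
    return(list(g = sc$g, pheno = sc$pheno, truth = sc$truth))
  }
  m <- read_markers(config$marker_file)
  qc <- qc_filter(m, maf_min = config$maf_min, missing_max = config$missing_max)
  m_complete <- impute_missing(qc$markers, seed = config$seed,
                               model = config$impute_model)
  g <- grm_vanraden(m_complete)
  pheno <- read_pheno(config$pheno_file)
  keep <- pheno$line %in% rownames(g)
  if (!all(keep)) {
    warning(sum(!keep), " phenotype records dropped: lines without genotypes")
    pheno <- pheno[keep, , drop = FALSE]
  }
  g <- g[rownames(g) %in% unique(pheno$line), rownames(g) %in% unique(pheno$line)]
  list(g = g, pheno = pheno, qc_report = qc$report)
}

#' Run the full sparse-testing experiment
#'
#' For every allocation scheme and cross-validation partition: mask the test
#' cells, run the first-stage unstructured covariance fit (when a CE method
#' is requested), build the per-method environment covariance, fit the GBLUP
#' model on the training cells, predict the test cells (for GBLUP_TRN, score
#' every line by its across-TPE genomic estimate), and evaluate COR, NRMSE
#' and PM_10/PM_20. Partition metrics are aggregated into means, standard
#' deviations and relative-efficiency tables. With an `out_dir` configured,
#' CSV/JSON reports and a reproducibility manifest are written.
#'
#' @param config a [run_config()] (or the path of a YAML file for one).
#' @param verbose print per-stage progress to stderr (default FALSE).
#' @return a [aggregate_metrics()] report (invisibly when written to disk).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a run_config", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  inputs <- resolve_inputs(config)
  g <- inputs$g
  pheno <- inputs$pheno
  line_ids <- rownames(g)
  env_ids <- sort(unique(as.character(pheno$env)))
  y_full <- pheno_to_wide(pheno, line_ids, env_ids)
  needs_stage1 <- any(config$methods %in%
                        c("GBLUP_CE", "GBLUP_CE_Abs", "GBLUP_CE_mean", "GBLUP_CE_Res"))

  all_rows <- list()
  fit_seed <- 0L
  for (alloc in config$allocations) {
    alloc_seed <- config$seed + 1000L * match(alloc, c("IBD", "Random"))
    parts <- cv_partitions(line_ids, env_ids,
                           n_partitions = config$n_partitions,
                           train_frac = config$train_frac,
                           allocation_method = alloc, seed = alloc_seed)
    for (part in parts) {
      say("allocation %s partition %d", alloc, part$partition_index)
      y_train <- y_full
      y_train[part$test] <- NA
      train_long <- wide_to_pheno(y_train)
      test_mask <- part$test & !is.na(y_full)
      obs_cells <- which(test_mask, arr.ind = TRUE)
      observed <- data.frame(line = line_ids[obs_cells[, 1L]],
                             env = env_ids[obs_cells[, 2L]],
                             value = y_full[test_mask],
                             stringsAsFactors = FALSE)

      mt <- NULL
      if (needs_stage1) {
        cfg1 <- config$mcmc
        cfg1$seed <- config$seed + 10000L + fit_seed
        mt <- fit_multitrait_unstructured(y_train, g, cfg1)
      }

      preds <- list()
      for (tag in config$methods) {
        omega <- build_omega(tag, mt = mt, I = length(env_ids), env_ids = env_ids)
        cfg <- config$mcmc
        fit_seed <- fit_seed + 1L
        cfg$seed <- config$seed + 20000L + fit_seed
        fit <- fit_gblup(train_long, g, omega, cfg)
        if (tag == "GBLUP_TRN") {
          scores <- gebv_across_tpe(fit)
          preds[[tag]] <- data.frame(line = observed$line, env = observed$env,
                                     pred = unname(scores[observed$line]),
                                     stringsAsFactors = FALSE)
        } else {
          preds[[tag]] <- data.frame(line = observed$line, env = observed$env,
                                     pred = predict_cells(fit, observed),
                                     stringsAsFactors = FALSE)
        }
      }
      all_rows[[length(all_rows) + 1L]] <-
        evaluate_partition(observed, preds,
                           top_fracs = config$top_fracs,
                           allocation_tag = alloc,
                           partition_index = part$partition_index,
                           nrmse_normalizer = config$nrmse_normalizer)
    }
  }

  report <- aggregate_metrics(do.call(rbind, all_rows))
  if (!is.null(config$out_dir)) {
    write_metrics_report(report, config$out_dir)
    manifest <- list(
      package_version = as.character(utils::packageVersion("sparsemet")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = config$seed,
      methods = config$methods,
      allocations = config$allocations,
      n_partitions = config$n_partitions,
      train_frac = config$train_frac,
      mcmc = unclass(config$mcmc),
      simulation = config$simulation,
      marker_file = config$marker_file,
      pheno_file = config$pheno_file
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
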