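# Genotype-selection quality metrics and their aggregation across
# cross-validation partitions and datasets.

#' Pearson correlation between observed and predicted values
#'
#' @param observed,predicted numeric vectors of equal length (at least 3).
#' @return product-moment correlation in \[-1, 1\].
#' @export
pearson_cor <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  if (length(observed) < 3L)
    stop("need at least 3 pairs to compute a correlation", call. = FALSE)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0)
    stop("zero variance in observed or predicted values; correlation undefined", call. = FALSE)
  stats::cor(observed, predicted)
}

#' Normalised root mean square error
#'
#' RMSE of the predictions divided by a normaliser of the observed values:
#' their mean (default, the usual convention for strictly positive yield
#' traits), standard deviation, or range.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param normalizer `"mean"`, `"sd"` or `"range"`.
#' @return non-negative scalar.
#' @export
nrmse <- function(observed, predicted, normalizer = c("mean", "sd", "range")) {
  normalizer <- match.arg(normalizer)
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(normalizer,
                  mean = mean(observed),
                  sd = stats::sd(observed),
                  range = diff(range(observed)))
  if (!is.finite(denom) || denom == 0)
    stop("zero normaliser for NRMSE; consider normalizer = \"sd\"", call. = FALSE)
  rmse / denom
}

#' Percentage of matching in the top fraction of lines
#'
#' Compares the `ceiling(top_frac * J)` lines with the largest predicted
#' scores against those with the largest observed scores (higher is better,
#' ties broken by position in the input order) and returns the percentage
#' overlap.
#'
#' @param observed_scores,predicted_scores numeric vectors over the same set
#'   of lines (names, when present, must agree).
#' @param top_frac fraction in (0, 1), e.g. 0.10 or 0.20.
#' @return percentage in \[0, 100\].
#' @export
percent_matching <- function(observed_scores, predicted_scores, top_frac) {
  if (length(observed_scores) != length(predicted_scores))
    stop("score vectors must have equal length", call. = FALSE)
  if (!is.null(names(observed_scores)) && !is.null(names(predicted_scores))) {
    if (!identical(names(observed_scores), names(predicted_scores)))
      stop("score vectors are over different line sets", call. = FALSE)
  }
  if (!(top_frac > 0 && top_frac < 1))
    stop("`top_frac` must be in (0, 1)", call. = FALSE)
  J <- length(observed_scores)
  m <- ceiling(top_frac * J)
  idx <- seq_len(J)
  top_obs <- idx[order(-observed_scores, idx)][seq_len(m)]
  top_pred <- idx[order(-predicted_scores, idx)][seq_len(m)]
  100 * length(intersect(top_obs, top_pred)) / m
}

#' Relative efficiency of the GBLUP_TRN method against another method
#'
#' For correlation and percentage-matching metrics (higher is better),
#' `RE = 100 * trn_mean / other_mean`; for NRMSE (lower is better) the ratio
#' is inverted, `RE = 100 * other_mean / trn_mean`. In both cases `RE > 100`
#' means GBLUP_TRN performed better. The additive form `gain = RE - 100` is
#' returned alongside.
#'
#' @param trn_mean average metric of the GBLUP_TRN method.
#' @param other_mean average metric of the comparison method.
#' @param metric_kind `"cor"`, `"pm"` or `"nrmse"`.
#' @return list with elements `re` and `gain` (percent).
#' @export
relative_efficiency <- function(trn_mean, other_mean, metric_kind = c("cor", "pm", "nrmse")) {
  metric_kind <- match.arg(metric_kind)
  num <- if (metric_kind == "nrmse") other_mean else trn_mean
  den <- if (metric_kind == "nrmse") trn_mean else other_mean
  if (!is.finite(den) || den <= 0)
    stop("relative efficiency needs a positive denominator mean", call. = FALSE)
  re <- 100 * num / den
  list(re = re, gain = re - 100)
}

#' Evaluate one cross-validation partition for several methods
#'
#' Computes COR and NRMSE over the test cells and PM_10/PM_20 at line level,
#' where a line's observed score is the mean of its test-cell BLUEs and its
#' predicted score the mean of its predicted test-cell values (for GBLUP_TRN
#' the prediction is constant across a line's cells, so this is its
#' across-TPE score).
#'
#' @param observed data.frame of test cells with columns `line`, `env`,
#'   `value`.
#' @param predictions named list (one element per method) of data.frames with
#'   columns `line`, `env`, `pred` covering all test cells.
#' @param top_fracs fractions for the percentage-matching metrics (default
#'   0.10 and 0.20).
#' @param allocation_tag,partition_index bookkeeping copied into the output.
#' @param nrmse_normalizer passed to [nrmse()].
#' @return data.frame with one row per method: `method_tag`,
#'   `allocation_tag`, `partition_index`, `cor`, `nrmse`, `pm_10`, `pm_20`,
#'   `n_test_cells`.
#' @export
evaluate_partition <- function(observed, predictions,
                               top_fracs = c(0.10, 0.20),
                               allocation_tag = NA_character_,
                               partition_index = NA_integer_,
                               nrmse_normalizer = "mean") {
  if (!all(c("line", "env", "value") %in% names(observed)))
    stop("`observed` must have columns line, env, value", call. = FALSE)
  if (is.null(names(predictions)) || any(names(predictions) == ""))
    stop("`predictions` must be a named list (one element per method)", call. = FALSE)
  key <- function(d) paste(d$line, d$env, sep = "\r")
  obs_key <- key(observed)
  rows <- lapply(names(predictions), function(tag) {
    pr <- predictions[[tag]]
    if (!all(c("line", "env", "pred") %in% names(pr)))
      stop("predictions for ", tag, " must have columns line, env, pred", call. = FALSE)
    m <- match(obs_key, key(pr))
    if (anyNA(m))
      stop("method ", tag, " is missing predictions for cells: ",
           paste(gsub("\r", ":", obs_key[is.na(m)]), collapse = ", "), call. = FALSE)
    pred <- pr$pred[m]
    obs_line <- tapply(observed$value, observed$line, mean)
    pred_line <- tapply(pred, observed$line, mean)
    pred_line <- pred_line[names(obs_line)]
    pm <- vapply(top_fracs,
                 function(f) percent_matching(obs_line, pred_line, f), numeric(1L))
    out <- data.frame(method_tag = tag,
                      allocation_tag = allocation_tag,
                      partition_index = partition_index,
                      cor = pearson_cor(observed$value, pred),
                      nrmse = nrmse(observed$value, pred, nrmse_normalizer),
                      n_test_cells = nrow(observed),
                      stringsAsFactors = FALSE)
    for (ii in seq_along(top_fracs))
      out[[sprintf("pm_%d", round(100 * top_fracs[ii]))]] <- pm[ii]
    out
  })
  do.call(rbind, rows)
}

#' Aggregate per-partition metrics into a report
#'
#' Produces per-method (and per-allocation) means and standard deviations of
#' every metric, relative-efficiency tables of GBLUP_TRN against each other
#' method computed from those means, and — when a `dataset` column is present
#' — an across-dataset summary averaging the dataset-level means without
#' weighting.
#'
#' @param partition_metrics data.frame as returned by stacking
#'   [evaluate_partition()] rows (optionally with a `dataset` column).
#' @param trn_tag method tag of the reference method (default
#'   `"GBLUP_TRN"`).
#' @return An object of class `metrics_report`: list with `partitions` (the
#'   input), `summary` (method x allocation x metric means/sd; `sd` is 0 with
#'   `sd_degenerate = TRUE` when only one partition is available), `re`
#'   (relative efficiencies and gains) and optionally `across_datasets`.
#' @export
aggregate_metrics <- function(partition_metrics, trn_tag = "GBLUP_TRN") {
  pm_df <- as.data.frame(partition_metrics)
  metric_cols <- intersect(c("cor", "nrmse", grep("^pm_", names(pm_df), value = TRUE)),
                           names(pm_df))
  if (!length(metric_cols)) stop("no metric columns found", call. = FALSE)
  if (!"allocation_tag" %in% names(pm_df)) pm_df$allocation_tag <- NA_character_

  summarise_block <- function(df) {
    groups <- split(df, list(df$method_tag, df$allocation_tag), drop = TRUE)
    do.call(rbind, lapply(groups, function(gdf) {
      do.call(rbind, lapply(metric_cols, function(mc) {
        vals <- gdf[[mc]]
        data.frame(method_tag = gdf$method_tag[1L],
                   allocation_tag = gdf$allocation_tag[1L],
                   metric = mc,
                   mean = mean(vals),
                   sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                   sd_degenerate = length(vals) == 1L,
                   n_partitions = length(vals),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  summary_df <- summarise_block(pm_df)
  rownames(summary_df) <- NULL

  re_df <- NULL
  if (trn_tag %in% pm_df$method_tag) {
    blocks <- split(summary_df, list(summary_df$allocation_tag, summary_df$metric),
                    drop = TRUE)
    re_rows <- lapply(blocks, function(b) {
      trn_mean <- b$mean[b$method_tag == trn_tag]
      if (!length(trn_mean)) return(NULL)
      others <- b[b$method_tag != trn_tag, , drop = FALSE]
      if (!nrow(others)) return(NULL)
      kind <- if (b$metric[1L] == "nrmse") "nrmse"
              else if (b$metric[1L] == "cor") "cor" else "pm"
      do.call(rbind, lapply(seq_len(nrow(others)), function(ri) {
        eff <- relative_efficiency(trn_mean, others$mean[ri], kind)
        data.frame(allocation_tag = others$allocation_tag[ri],
                   metric = others$metric[ri],
                   method_tag = others$method_tag[ri],
                   re = eff$re, gain = eff$gain,
                   stringsAsFactors = FALSE)
      }))
    })
    re_df <- do.call(rbind, re_rows)
    if (!is.null(re_df)) rownames(re_df) <- NULL
  }

  across <- NULL
  if ("dataset" %in% names(pm_df) && length(unique(pm_df$dataset)) > 1L) {
    per_ds <- lapply(split(pm_df, pm_df$dataset), summarise_block)
    stacked <- do.call(rbind, per_ds)
    keys <- split(stacked, list(stacked$method_tag, stacked$allocation_tag, stacked$metric),
                  drop = TRUE)
    across <- do.call(rbind, lapply(keys, function(b) {
      data.frame(method_tag = b$method_tag[1L], allocation_tag = b$allocation_tag[1L],
                 metric = b$metric[1L], mean = mean(b$mean),
                 n_datasets = nrow(b), stringsAsFactors = FALSE)
    }))
    rownames(across) <- NULL
  }

  structure(list(partitions = pm_df, summary = summary_df,
                 re = re_df, across_datasets = across, trn_tag = trn_tag),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Sparse-testing metrics report\n")
  cat(sprintf("  %d partition rows, %d method/allocation/metric summaries\n",
              nrow(x$partitions), nrow(x$summary)))
  cors <- x$summary[x$summary$metric == "cor", c("method_tag", "allocation_tag", "mean", "sd")]
  if (nrow(cors)) {
    cat("  mean COR by method and allocation:\n")
    print(cors, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits `metrics_partitions.csv`, `metrics_summary.csv`, `re_table.csv`
#' (when available) and a JSON twin `report.json` in `dir`.
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if absent).
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$partitions, file.path(dir, "metrics_partitions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$summary, file.path(dir, "metrics_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$re))
    utils::write.csv(report$re, file.path(dir, "re_table.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(partitions = report$partitions,
                            summary = report$summary,
                            re = report$re,
                            across_datasets = report$across_datasets),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
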