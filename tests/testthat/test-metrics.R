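test_that("pearson_cor matches hand-computed and boundary cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_equal(pearson_cor(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_cor(x, rep(2, 4)), "variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("nrmse normalises the root mean square error by the observed mean", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(rep(2, 4), rep(3, 4)), 0.5)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 6)), sqrt(3) / 2)
  # scale invariance under mean normalisation
  obs <- c(2, 4, 7, 5); pred <- c(3, 4, 6, 6)
  expect_equal(nrmse(3 * obs, 3 * pred), nrmse(obs, pred))
  expect_error(nrmse(c(-1, 0, 1), c(0, 0, 0)), "sd")
  expect_equal(nrmse(c(-1, 0, 1), c(-1, 0.5, 1), normalizer = "sd"),
               sqrt(0.25 / 3) / 1)
})

test_that("percent_matching counts top-set overlap with deterministic ties", {
  obs <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  names(obs) <- paste0("L", 1:10)
  expect_equal(percent_matching(obs, obs, 0.2), 100)
  pred_disjoint <- rev(obs); names(pred_disjoint) <- names(obs)
  expect_equal(percent_matching(obs, pred_disjoint, 0.2), 0)
  # exactly one of the two predicted top lines is truly top-2
  pred_half <- obs
  pred_half[c("L2", "L5")] <- c(1.5, 9.5)   # L2 drops out, L1 stays
  expect_equal(percent_matching(obs, pred_half, 0.2), 50)
  # invariance to strictly increasing transforms of either vector
  expect_equal(percent_matching(obs, exp(pred_half / 3), 0.2), 50)
  expect_equal(percent_matching(obs^3, pred_half, 0.2), 50)
})

test_that("relative efficiency follows the metric-specific ratio convention", {
  expect_equal(relative_efficiency(0.8, 0.8, "cor")$re, 100)
  expect_equal(relative_efficiency(0.8, 0.8, "cor")$gain, 0)
  expect_equal(relative_efficiency(0.90, 0.75, "cor")$re, 120)
  expect_equal(relative_efficiency(0.90, 0.75, "cor")$gain, 20)
  # NRMSE: smaller is better, so the ratio inverts
  expect_equal(relative_efficiency(0.50, 0.60, "nrmse")$re, 120)
  expect_equal(relative_efficiency(0.50, 0.60, "nrmse")$gain, 20)
  expect_error(relative_efficiency(0.5, 0, "cor"), "positive")
  # antisymmetry: RE(a,b) * RE(b,a) = 100^2
  for (pair in list(c(0.9, 0.6), c(0.42, 0.37), c(55, 70))) {
    expect_equal(relative_efficiency(pair[1], pair[2], "pm")$re *
                   relative_efficiency(pair[2], pair[1], "pm")$re, 1e4)
  }
})

test_that("evaluate_partition reproduces hand-computed metrics on a toy set", {
  observed <- data.frame(line = c("A", "B", "C", "D", "E", "F"),
                         env = c("E1", "E1", "E1", "E2", "E2", "E2"),
                         value = c(10, 8, 6, 9, 7, 5))
  preds <- list(toy = data.frame(line = observed$line, env = observed$env,
                                 pred = c(9, 8.5, 5, 10, 6, 6)))
  res <- evaluate_partition(observed, preds, allocation_tag = "IBD",
                            partition_index = 1L)
  expect_equal(nrow(res), 1)
  expect_equal(res$cor, 0.8641101, tolerance = 1e-6)
  expect_equal(res$nrmse, 0.1247219, tolerance = 1e-6)
  expect_equal(res$pm_10, 0)    # ceil(0.1*6) = 1: obs top is A, pred top is D
  expect_equal(res$pm_20, 100)  # top-2 sets coincide ({A, D})
  expect_equal(res$n_test_cells, 6)

  # perfect predictions
  perfect <- list(p = data.frame(line = observed$line, env = observed$env,
                                 pred = observed$value))
  resp <- evaluate_partition(observed, perfect)
  expect_equal(resp$cor, 1)
  expect_equal(resp$nrmse, 0)
  expect_equal(resp$pm_10, 100)
  expect_equal(resp$pm_20, 100)

  # constant shift keeps ranking metrics perfect, moves only NRMSE
  shifted <- list(s = data.frame(line = observed$line, env = observed$env,
                                 pred = observed$value + 1.5))
  ress <- evaluate_partition(observed, shifted)
  expect_equal(ress$cor, 1)
  expect_equal(ress$pm_20, 100)
  expect_equal(ress$nrmse, 1.5 / mean(observed$value))

  # missing predictions are reported by cell
  broken <- list(b = preds$toy[-2, ])
  expect_error(evaluate_partition(observed, broken), "B:E1")
})

test_that("aggregation averages partitions and derives RE tables from means", {
  rows <- rbind(
    data.frame(method_tag = "GBLUP_TRN", allocation_tag = "IBD", partition_index = 1:2,
               cor = c(0.8, 0.9), nrmse = c(0.5, 0.6), pm_10 = c(40, 60), pm_20 = c(50, 70)),
    data.frame(method_tag = "GBLUP", allocation_tag = "IBD", partition_index = 1:2,
               cor = c(0.7, 0.8), nrmse = c(0.55, 0.65), pm_10 = c(30, 50), pm_20 = c(40, 60)))
  rep <- aggregate_metrics(rows)
  s <- rep$summary
  trn_cor <- s[s$method_tag == "GBLUP_TRN" & s$metric == "cor", ]
  expect_equal(trn_cor$mean, 0.85)
  expect_equal(trn_cor$sd, 0.0707107, tolerance = 1e-6)
  expect_false(trn_cor$sd_degenerate)
  # RE from the means, not per partition: cor 0.85/0.75, nrmse 0.6/0.55
  re <- rep$re
  expect_equal(re$re[re$metric == "cor"], 100 * 0.85 / 0.75)
  expect_equal(re$re[re$metric == "nrmse"], 100 * 0.60 / 0.55)
  expect_equal(re$gain, re$re - 100)

  # single partition: sd reported as 0 and flagged
  rep1 <- aggregate_metrics(rows[rows$partition_index == 1, ])
  expect_true(all(rep1$summary$sd == 0))
  expect_true(all(rep1$summary$sd_degenerate))

  # permuting partition order leaves the report unchanged
  rep_perm <- aggregate_metrics(rows[c(3, 1, 4, 2), ])
  expect_equal(rep_perm$summary, rep$summary)
  expect_equal(rep_perm$re, rep$re)
})

test_that("across-dataset summaries average the dataset-level means unweighted", {
  rows <- expand.grid(method_tag = "GBLUP", allocation_tag = "IBD",
                      partition_index = 1:2, dataset = c("d1", "d2"),
                      stringsAsFactors = FALSE)
  rows$cor <- c(0.6, 0.8, 0.3, 0.5)  # d1 mean 0.7, d2 mean 0.4
  rows$nrmse <- 1; rows$pm_10 <- 50; rows$pm_20 <- 50
  rep <- aggregate_metrics(rows)
  ac <- rep$across_datasets
  expect_equal(ac$mean[ac$metric == "cor"], mean(c(0.7, 0.4)))
  expect_equal(ac$n_datasets[ac$metric == "cor"], 2)
})
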