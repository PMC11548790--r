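test_that("the 12-line, 4-environment, block-size-9 training design is equireplicate", {
  d <- find_incomplete_block(12, 4, 9, seed = 1)
  expect_equal(sum(d$incidence), 36)           # N = J * r = I * k
  expect_equal(unname(colSums(d$incidence)), rep(9, 4))
  expect_equal(unname(d$replications), rep(3, 12))
  # concurrence bookkeeping
  expect_equal(d$concurrence, tcrossprod(d$incidence))
  expect_equal(unname(diag(d$concurrence)), unname(d$replications))
})

test_that("the swap descent finds the balanced (7, 7, 3) design with lambda = 1", {
  d <- find_incomplete_block(7, 7, 3, seed = 2)
  lam <- d$concurrence[upper.tri(d$concurrence)]
  expect_true(all(lam == 1))
  expect_true(attr(d, "balanced"))
})

test_that("degenerate and invalid incomplete-block requests are rejected", {
  # (4, 2, 2): counting forces the two blocks to partition the lines
  d <- find_incomplete_block(4, 2, 2, seed = 3)
  expect_equal(unname(d$replications), rep(1, 4))
  expect_equal(sum(d$incidence[, 1] * d$incidence[, 2]), 0)

  expect_error(find_incomplete_block(12, 4, 8, seed = 1), "divisible")
  expect_error(find_incomplete_block(5, 3, 5, seed = 1), "sparse")
})

test_that("the descent objective is monotone non-increasing and reproducible", {
  for (s in 1:5) {
    d <- find_incomplete_block(10, 5, 4, seed = s)
    tr <- attr(d, "objective_trace")
    expect_true(all(diff(tr) <= 1e-9))
  }
  d1 <- find_incomplete_block(10, 5, 4, seed = 42)
  d2 <- find_incomplete_block(10, 5, 4, seed = 42)
  expect_identical(d1$incidence, d2$incidence)
})

test_that("random allocation respects the replication cap and block sizes", {
  # worked sizes: J = 12, I = 4, r = 3 gives k = ceiling(36/4) = 9
  d <- random_allocation(12, 4, 3, seed = 1)
  expect_equal(d$k, 9L)
  expect_equal(unname(colSums(d$incidence)), rep(9, 4))

  # r = 1 with two environments forces disjoint pairs
  d2 <- random_allocation(4, 2, 1, seed = 5)
  expect_equal(unname(d2$replications), rep(1, 4))
  expect_equal(sum(d2$incidence[, 1] * d2$incidence[, 2]), 0)

  # k = J is not sparse
  expect_error(random_allocation(10, 5, 5, seed = 1), "sparse")

  # fuzz: cap r (or r + 1 under the logged fallback) never exceeded
  set.seed(99)
  for (case in 1:12) {
    J <- sample(8:30, 1); I <- sample(2:6, 1)
    r_max <- max(1, min(I, floor((J - 1) * I / J)))
    r <- sample(seq_len(r_max), 1)
    if (ceiling(J * r / I) >= J) next
    d <- random_allocation(J, I, r, seed = case)
    excess <- d$replications - r
    expect_lte(max(excess), 1)
    expect_equal(attr(d, "fallback"), sum(excess > 0))
    expect_equal(unname(colSums(d$incidence)), rep(d$k, I))
  }

  d3 <- random_allocation(12, 4, 3, seed = 7)
  d4 <- random_allocation(12, 4, 3, seed = 7)
  expect_identical(d3$incidence, d4$incidence)
})

test_that("cross-validation partitions are complementary and keep every line trained", {
  lines <- paste0("L", 1:100)
  envs <- paste0("E", 1:4)
  parts <- cv_partitions(lines, envs, n_partitions = 10, seed = 1)
  masks <- lapply(parts, function(p) p$train)
  # with I = 4 and a 50% split every line trains in exactly 2 environments
  for (p in parts) {
    expect_true(all(rowSums(p$train) == 2))
    expect_true(all(p$train == !p$test))
    expect_equal(unname(colSums(p$train)), rep(50, 4))
  }
  # partitions are distinct
  for (i in 1:9) for (j in (i + 1):10)
    expect_false(identical(masks[[i]], masks[[j]]))
  # reproducible from the master seed
  parts2 <- cv_partitions(lines, envs, n_partitions = 10, seed = 1)
  expect_identical(masks, lapply(parts2, function(p) p$train))
})

test_that("partitions handle odd environment counts and the Random method", {
  for (method in c("IBD", "Random")) {
    for (I in c(2, 3, 5)) {
      lines <- paste0("L", 1:37)
      envs <- paste0("E", seq_len(I))
      parts <- cv_partitions(lines, envs, n_partitions = 3,
                             allocation_method = method, seed = 4)
      k <- 19  # half of 37 lines, rounded up
      for (p in parts) {
        expect_true(all(rowSums(p$train) >= 1))          # every line trained
        expect_equal(unname(colSums(p$train)), rep(k, I)) # equal block sizes
        counts <- rowSums(p$train)
        expect_lte(max(counts) - min(counts), 1)          # balanced quotas
      }
    }
  }
  expect_error(cv_partitions(paste0("L", 1:10), paste0("E", 1:2),
                             train_frac = 0.05, seed = 1),
               "training")
})

test_that("designs and partitions export to plain-text files", {
  d <- find_incomplete_block(12, 4, 9, seed = 1)
  stem <- tempfile()
  write_design(d, stem)
  inc <- as.matrix(utils::read.csv(paste0(stem, ".csv"), row.names = 1))
  expect_equal(unname(inc), unname(d$incidence))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(meta$k, 9)
  expect_equal(unlist(meta$replications), rep(3, 12), ignore_attr = TRUE)

  parts <- cv_partitions(paste0("L", 1:12), paste0("E", 1:4),
                         n_partitions = 2, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_cv_partitions(parts, f)
  long <- utils::read.csv(f)
  expect_equal(nrow(long), 2 * 12 * 4)
  expect_setequal(unique(long$role), c("train", "test"))
})
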