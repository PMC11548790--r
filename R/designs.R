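# Sparse allocation of lines (treatments) to environments (blocks):
# incomplete-block designs by concurrence-variance swap descent, the
# constrained-random allocation, and cross-validation partitions.

#' Construct an allocation design object
#'
#' Wraps a binary lines x environments incidence matrix with its replication
#' vector (row sums), concurrence matrix (incidence %*% t(incidence)) and
#' block size. All columns must have equal sums (equally sized environments).
#'
#' @param incidence J x I matrix of 0/1 (1 = line tested in environment).
#' @param method_tag `"IBD"` or `"Random"`.
#' @return An object of class `allocation_design` with elements `incidence`,
#'   `J`, `I`, `k`, `replications`, `concurrence`, `method_tag`.
#' @export
allocation_design <- function(incidence, method_tag = c("IBD", "Random")) {
  method_tag <- match.arg(method_tag)
  if (!is.matrix(incidence)) stop("`incidence` must be a matrix", call. = FALSE)
  storage.mode(incidence) <- "double"
  if (!all(incidence %in% c(0, 1))) stop("incidence entries must be 0/1", call. = FALSE)
  ks <- colSums(incidence)
  if (length(unique(ks)) != 1L)
    stop("all environments must hold the same number of lines", call. = FALSE)
  conc <- tcrossprod(incidence)
  structure(list(
    incidence = incidence,
    J = nrow(incidence),
    I = ncol(incidence),
    k = as.integer(ks[1L]),
    replications = rowSums(incidence),
    concurrence = conc,
    method_tag = method_tag
  ), class = "allocation_design")
}

#' @export
print.allocation_design <- function(x, ...) {
  lam <- x$concurrence[upper.tri(x$concurrence)]
  cat(sprintf("%s allocation: %d lines x %d environments, block size %d, N = %d\n",
              x$method_tag, x$J, x$I, x$k, sum(x$incidence)))
  cat(sprintf("  replications: %s\n",
              paste(range(x$replications), collapse = "-")))
  cat(sprintf("  concurrence: range %s, variance objective %.3f\n",
              paste(range(lam), collapse = "-"), concurrence_variance(x)))
  invisible(x)
}

#' Pairwise-concurrence variance objective of a design
#'
#' Sum over unordered line pairs of squared deviations of the concurrence
#' count from its mean. Zero iff all pairs co-occur equally often (a balanced
#' incomplete block design).
#'
#' @param design an `allocation_design` (or a 0/1 incidence matrix).
#' @return non-negative scalar.
#' @export
concurrence_variance <- function(design) {
  conc <- if (inherits(design, "allocation_design")) design$concurrence
          else tcrossprod(design)
  lam <- conc[upper.tri(conc)]
  sum((lam - mean(lam))^2)
}

# lower bound of the objective given integer concurrences with fixed total
concurrence_lower_bound <- function(J, I, k) {
  n_pairs <- J * (J - 1) / 2
  total <- I * k * (k - 1) / 2          # sum of pair concurrences
  lbar <- total / n_pairs
  lo <- floor(lbar); hi <- ceiling(lbar)
  n_hi <- total - lo * n_pairs          # pairs that must take value hi
  n_lo <- n_pairs - n_hi
  n_lo * (lo - lbar)^2 + n_hi * (hi - lbar)^2
}

# greedy initial fill honouring per-line replication quotas exactly:
# each environment takes the k lines with the largest remaining quota
# (seeded random tie-break); errors if infeasible.
fill_by_quota <- function(J, I, k, quota, randomize = FALSE) {
  inc <- matrix(0, J, I)
  remaining <- as.integer(quota)
  if (sum(remaining) != I * k) stop("quota must sum to I*k", call. = FALSE)
  if (any(remaining < 0L) || any(remaining > I)) stop("infeasible quota", call. = FALSE)
  for (b in seq_len(I)) {
    envs_left <- I - b + 1L
    must <- which(remaining >= envs_left)
    if (length(must) > k)
      stop("infeasible allocation: more forced lines than block slots", call. = FALSE)
    pool <- setdiff(which(remaining > 0L), must)
    need <- k - length(must)
    if (need > length(pool))
      stop("infeasible allocation: not enough candidate lines for a block", call. = FALSE)
    extra <- if (need == 0L) integer(0)
             else if (randomize) safe_sample(pool, need)
             else pool[order(-remaining[pool], stats::runif(length(pool)))][seq_len(need)]
    pick <- c(must, extra)
    inc[pick, b] <- 1
    remaining[pick] <- remaining[pick] - 1L
  }
  inc
}

# change in the sum of squared concurrences when line a (in block b1 only)
# and line b (in block b2 only) exchange blocks; vectorised over all (a, b)
swap_deltas <- function(inc, lambda, k, b1, b2) {
  m1 <- which(inc[, b1] == 1)
  m2 <- which(inc[, b2] == 1)
  A <- setdiff(m1, m2)
  B <- setdiff(m2, m1)
  if (length(A) == 0L || length(B) == 0L) return(NULL)
  s1 <- rowSums(lambda[, m1, drop = FALSE])
  s2 <- rowSums(lambda[, m2, drop = FALSE])
  dg <- diag(lambda)
  d_ab <- 2 * (outer(-s1[A] + dg[A] + s2[A], s1[B] + dg[B] - s2[B], "+")
               - 2 * lambda[A, B, drop = FALSE]) + 4 * (k - 1)
  list(A = A, B = B, d = d_ab)
}

apply_swap <- function(inc, lambda, a, b, b1, b2) {
  S1 <- setdiff(which(inc[, b1] == 1), a)
  S2 <- setdiff(which(inc[, b2] == 1), b)
  lambda[a, S1] <- lambda[a, S1] - 1; lambda[S1, a] <- lambda[S1, a] - 1
  lambda[b, S1] <- lambda[b, S1] + 1; lambda[S1, b] <- lambda[S1, b] + 1
  lambda[b, S2] <- lambda[b, S2] - 1; lambda[S2, b] <- lambda[S2, b] - 1
  lambda[a, S2] <- lambda[a, S2] + 1; lambda[S2, a] <- lambda[S2, a] + 1
  inc[a, b1] <- 0; inc[b, b1] <- 1
  inc[b, b2] <- 0; inc[a, b2] <- 1
  list(inc = inc, lambda = lambda)
}

# one descent move: scan every block pair, then apply one quota-preserving
# swap chosen uniformly among those with the most negative objective change.
# When no strictly improving swap exists and sideways moves are allowed, an
# objective-neutral swap is applied instead (a plateau walk): this lets the
# search escape the flat local optima typical of balanced-design objectives
# without ever increasing the objective.
descent_move <- function(inc, lambda, k, allow_sideways = FALSE) {
  I <- ncol(inc)
  best_d <- Inf
  best <- NULL
  flats <- NULL
  for (b1 in seq_len(I - 1L)) for (b2 in seq((b1 + 1L), I)) {
    sw <- swap_deltas(inc, lambda, k, b1, b2)
    if (is.null(sw)) next
    dmin <- min(sw$d)
    if (dmin < best_d - 1e-9) {
      idx <- which(sw$d <= dmin + 1e-9, arr.ind = TRUE)
      best <- cbind(a = sw$A[idx[, 1L]], b = sw$B[idx[, 2L]], b1 = b1, b2 = b2)
      best_d <- dmin
    } else if (dmin <= best_d + 1e-9 && !is.null(best)) {
      idx <- which(sw$d <= best_d + 1e-9, arr.ind = TRUE)
      best <- rbind(best, cbind(a = sw$A[idx[, 1L]], b = sw$B[idx[, 2L]],
                                b1 = b1, b2 = b2))
    }
    if (allow_sideways && best_d > -1e-9) {
      zero <- which(abs(sw$d) <= 1e-9, arr.ind = TRUE)
      if (nrow(zero))
        flats <- rbind(flats, cbind(a = sw$A[zero[, 1L]], b = sw$B[zero[, 2L]],
                                    b1 = b1, b2 = b2))
    }
  }
  improved <- is.finite(best_d) && best_d < -1e-9
  cand <- if (improved) best else if (allow_sideways) flats else NULL
  if (is.null(cand) || nrow(cand) == 0L)
    return(list(inc = inc, lambda = lambda, improved = FALSE, moved = FALSE))
  pick <- cand[sample(nrow(cand), 1L), ]
  upd <- apply_swap(inc, lambda, pick[["a"]], pick[["b"]], pick[["b1"]], pick[["b2"]])
  list(inc = upd$inc, lambda = upd$lambda, improved = improved, moved = TRUE)
}

# swap-descent search for a (partially) balanced incomplete block design
# with given per-line quotas; multi-start keeps the best design found.
# Within a start the objective is monotone non-increasing: improving moves
# are interleaved with at most `plateau_patience` consecutive
# objective-neutral plateau steps. `max_sweeps` bounds the number of
# full-neighbourhood scans per start (each move scans all block pairs once).
ibd_search <- function(J, I, k, quota, max_sweeps, n_starts,
                       randomize_fill = FALSE, plateau_patience = 60L) {
  # objective lower bound only exact for equireplicate designs; 0 is always a bound
  lb <- if (length(unique(quota)) == 1L) concurrence_lower_bound(J, I, k) else 0
  max_moves <- max_sweeps * I * (I - 1L)  # several moves per nominal sweep
  best <- NULL
  best_obj <- Inf
  for (s in seq_len(n_starts)) {
    inc <- fill_by_quota(J, I, k, quota, randomize = randomize_fill)
    lambda <- tcrossprod(inc)
    obj <- concurrence_variance(inc)
    trace <- obj
    moves <- 0L
    patience <- 0L
    while (obj > lb + 1e-9 && moves < max_moves) {
      step <- descent_move(inc, lambda, k, allow_sideways = TRUE)
      if (!step$moved) break
      inc <- step$inc; lambda <- step$lambda
      moves <- moves + 1L
      obj <- concurrence_variance(inc)
      trace <- c(trace, obj)
      if (step$improved) {
        patience <- 0L
      } else {
        patience <- patience + 1L
        if (patience > plateau_patience) break
      }
    }
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(inc = inc, objective = obj, trace = trace, sweeps = moves)
    }
    if (best_obj <= lb + 1e-9) break
  }
  best
}

#' Incomplete-block allocation of lines to environments
#'
#' Searches for a (balanced, when one exists) incomplete block design with `J`
#' lines, `I` equally sized blocks of `k` lines, and exactly `r = I*k/J`
#' replicates per line, by seeded swap descent on the pairwise-concurrence
#' variance: starting from a random equireplicate fill, pairs of blocks
#' exchange lines whenever the exchange reduces the objective
#' sum over line pairs of (concurrence - mean)^2. When a balanced design with
#' integer concurrence `lambda = r(k-1)/(J-1)` exists and is found, all pairs
#' co-occur exactly `lambda` times; otherwise the returned design is partially
#' balanced with the minimal objective value found.
#'
#' @param J number of lines (treatments); `J >= 2`.
#' @param I number of environments (blocks); `I >= 2`.
#' @param k lines per environment; must satisfy `k < J` and `I*k` divisible
#'   by `J`.
#' @param seed integer seed making the search reproducible.
#' @param max_sweeps maximum descent sweeps per start (default 200).
#' @param n_starts random restarts kept until a balanced design is found
#'   (default 20).
#' @return An `allocation_design` (method tag `"IBD"`); attributes
#'   `objective` (achieved concurrence variance), `objective_trace` (monotone
#'   non-increasing per-sweep values of the best start) and `balanced`
#'   (logical).
#' @examples
#' d <- find_incomplete_block(12, 4, 9, seed = 1)
#' range(d$replications)  # 3 3
#' @export
find_incomplete_block <- function(J, I, k, seed = 1L, max_sweeps = 200L, n_starts = 20L) {
  J <- stopifnot_scalar_count(J, "J", 2L)
  I <- stopifnot_scalar_count(I, "I", 2L)
  k <- stopifnot_scalar_count(k, "k", 1L)
  if (k >= J)
    stop("`k` must be smaller than `J`: complete blocks are not a sparse design", call. = FALSE)
  if ((I * k) %% J != 0L)
    stop(sprintf("I*k = %d is not divisible by J = %d; adjust k so every line can be replicated equally",
                 I * k, J), call. = FALSE)
  r <- (I * k) %/% J
  res <- with_seed(seed, ibd_search(J, I, k, quota = rep(r, J),
                                    max_sweeps = max_sweeps, n_starts = n_starts))
  inc <- res$inc
  dimnames(inc) <- list(paste0("L", seq_len(J)), paste0("Env", seq_len(I)))
  out <- allocation_design(inc, "IBD")
  attr(out, "objective") <- res$objective
  attr(out, "objective_trace") <- res$trace
  lam_target <- r * (k - 1) / (J - 1)
  attr(out, "balanced") <- (res$objective <= 1e-9) && (lam_target == round(lam_target))
  out
}

#' Constrained-random allocation of lines to environments
#'
#' Sequentially fills `I` equally sized environments with
#' `k = ceiling(J*r/I)` lines each, sampling uniformly without replacement
#' from the lines currently present in fewer than `r` environments. When
#' fewer than `k` such candidates remain, the shortfall is filled from the
#' lines with the smallest current replication (ties broken by line index),
#' allowing at most `r + 1` appearances; this fallback is recorded.
#'
#' @param J number of lines.
#' @param I number of environments.
#' @param r target replicates per line, `1 <= r <= I`.
#' @param seed integer seed.
#' @return An `allocation_design` (method tag `"Random"`); attribute
#'   `fallback` gives the number of lines exceeding `r` replicates (each by
#'   exactly one).
#' @export
random_allocation <- function(J, I, r, seed = 1L) {
  J <- stopifnot_scalar_count(J, "J", 1L)
  I <- stopifnot_scalar_count(I, "I", 1L)
  r <- stopifnot_scalar_count(r, "r", 1L)
  if (r > I) stop("`r` cannot exceed the number of environments", call. = FALSE)
  k <- as.integer(ceiling(J * r / I))
  if (k >= J)
    stop(sprintf("block size k = ceiling(J*r/I) = %d is not smaller than J = %d; not a sparse design",
                 k, J), call. = FALSE)
  counts <- integer(J)
  inc <- matrix(0, J, I)
  with_seed(seed, {
    for (b in seq_len(I)) {
      cand <- which(counts < r)
      if (length(cand) >= k) {
        pick <- safe_sample(cand, k)
      } else {
        pick <- cand
        pool <- setdiff(seq_len(J), pick)
        pool <- pool[counts[pool] <= r]  # r+1 at most after increment
        pool <- pool[order(counts[pool], pool)]
        need <- k - length(pick)
        if (need > length(pool))
          stop("no feasible fill for this environment even with the fallback", call. = FALSE)
        pick <- c(pick, pool[seq_len(need)])
      }
      inc[pick, b] <- 1
      counts[pick] <- counts[pick] + 1L
    }
  })
  dimnames(inc) <- list(paste0("L", seq_len(J)), paste0("Env", seq_len(I)))
  out <- allocation_design(inc, "Random")
  attr(out, "fallback") <- sum(counts > r)
  out
}

#' Cross-validation partitions for sparse-testing evaluation
#'
#' Builds `n_partitions` train/test splits of the full lines x environments
#' grid in which the training cells of each partition form a sparse
#' allocation (incomplete-block or random) with `k = round(train_frac * J)`
#' lines per environment, and every line is observed in at least one training
#' environment. With `I = 4` environments and `train_frac = 0.5` every line
#' trains in exactly 2 environments and is tested in the other 2. When
#' `train_frac * I` is not an integer, per-line training counts take the two
#' nearest integers, balanced so all environments keep `k` training lines.
#'
#' @param line_ids character vector of line identifiers.
#' @param env_ids character vector of environment identifiers.
#' @param n_partitions number of random partitions (default 10).
#' @param train_frac fraction of cells used for training (default 0.5).
#' @param allocation_method `"IBD"` or `"Random"`.
#' @param seed master seed; partition i uses `seed + i`.
#' @param max_sweeps,n_starts IBD search controls (see
#'   [find_incomplete_block()]).
#' @return A list of `cv_partition` objects, each with logical J x I matrices
#'   `train` and `test` (complementary), `partition_index`, `seed` and
#'   `allocation_method`.
#' @export
cv_partitions <- function(line_ids, env_ids, n_partitions = 10L, train_frac = 0.5,
                          allocation_method = c("IBD", "Random"), seed = 1L,
                          max_sweeps = 50L, n_starts = 5L) {
  allocation_method <- match.arg(allocation_method)
  line_ids <- as.character(line_ids)
  env_ids <- as.character(env_ids)
  if (anyDuplicated(line_ids) || anyDuplicated(env_ids))
    stop("line and environment ids must be unique", call. = FALSE)
  J <- length(line_ids); I <- length(env_ids)
  if (J < 2L || I < 2L) stop("need at least 2 lines and 2 environments", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1)) stop("`train_frac` must be in (0, 1)", call. = FALSE)
  k <- as.integer(floor(train_frac * J + 0.5))  # round half up: a 50% split of
  # an odd line count keeps ceil(J/2) training slots, so two environments
  # still cover every line
  total <- I * k
  base <- total %/% J
  n_hi <- total %% J
  if (base < 1L)
    stop("`train_frac` too small: some line would have no training environment", call. = FALSE)
  lapply(seq_len(n_partitions), function(i) {
    part_seed <- seed + i
    inc <- with_seed(part_seed, {
      quota <- rep(base, J)
      if (n_hi > 0L) quota[safe_sample(seq_len(J), n_hi)] <- base + 1L
      if (allocation_method == "IBD") {
        ibd_search(J, I, k, quota, max_sweeps = max_sweeps, n_starts = n_starts)$inc
      } else {
        fill_by_quota(J, I, k, quota, randomize = TRUE)
      }
    })
    train <- inc == 1
    dimnames(train) <- list(line_ids, env_ids)
    structure(list(train = train, test = !train,
                   partition_index = i, seed = part_seed,
                   allocation_method = allocation_method),
              class = "cv_partition")
  })
}

#' @export
print.cv_partition <- function(x, ...) {
  cat(sprintf("CV partition %d (%s): %d training / %d testing cells; per-line training envs %s\n",
              x$partition_index, x$allocation_method, sum(x$train), sum(x$test),
              paste(range(rowSums(x$train)), collapse = "-")))
  invisible(x)
}

#' Export an allocation design as CSV plus JSON diagnostics
#'
#' Writes the 0/1 incidence matrix to `<path>.csv` and a diagnostics block
#' (block size, replication vector, concurrence summary, objective) to
#' `<path>.json`.
#'
#' @param design an `allocation_design`.
#' @param path output path stem (no extension).
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design$incidence), paste0(path, ".csv"),
                   row.names = TRUE, quote = FALSE)
  lam <- design$concurrence[upper.tri(design$concurrence)]
  diag_block <- list(
    method = design$method_tag,
    J = design$J, I = design$I, k = design$k,
    replications = as.vector(design$replications),
    concurrence_min = min(lam), concurrence_max = max(lam),
    concurrence_variance = concurrence_variance(design),
    objective = attr(design, "objective"),
    fallback = attr(design, "fallback")
  )
  jsonlite::write_json(diag_block, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export cross-validation partitions as a long CSV
#'
#' One row per line-environment-partition with a `role` column
#' (`train`/`test`).
#'
#' @param partitions list of `cv_partition` objects from [cv_partitions()].
#' @param path output CSV path.
#' @export
write_cv_partitions <- function(partitions, path) {
  rows <- do.call(rbind, lapply(partitions, function(p) {
    grid <- expand.grid(line = rownames(p$train), env = colnames(p$train),
                        stringsAsFactors = FALSE)
    grid$partition <- p$partition_index
    grid$role <- ifelse(p$train[cbind(match(grid$line, rownames(p$train)),
                                      match(grid$env, colnames(p$train)))],
                        "train", "test")
    grid
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
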