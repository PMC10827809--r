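# Shared fixtures, built in code at test time.

# small ground truth + cohorts, memoised per (grid, seed) within a run
tiny_config <- function(grid = c(16, 16, 16), seed = 11, ...) {
  sim_config(grid = grid, n_healthy = 12, n_early = 10, n_progressive = 10,
             seed = seed, ...)
}

.gt_cache <- new.env(parent = emptyenv())
tiny_gt <- function(grid = c(16, 16, 16), seed = 11, ...) {
  key <- paste(c(grid, seed, ...), collapse = "_")
  if (is.null(.gt_cache[[key]]))
    .gt_cache[[key]] <- generate_ground_truth(tiny_config(grid, seed, ...))
  .gt_cache[[key]]
}

# a constant-valued cohort: every subject's T1 identically `value`
constant_cohort <- function(n, grid = c(6, 6, 6), value = 900,
                            voxel_size = c(1, 1, 1)) {
  ages <- seq(25, 55, length.out = n)
  sexes <- rep(c(0, 1), length.out = n)
  lapply(seq_len(n), function(i)
    subject_record(sprintf("S%02d", i), ages[i], sexes[i],
                   brain_volume(array(value, dim = grid), voxel_size)))
}

full_mask <- function(grid = c(6, 6, 6), voxel_size = c(1, 1, 1)) {
  brain_mask(array(TRUE, dim = grid), voxel_size)
}

# independent brute-force oracles ------------------------------------------

# per-voxel least squares via scaled normal equations
oracle_ls <- function(X, y) {
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2L, s, `/`)
  drop(solve(crossprod(Xs), crossprod(Xs, y))) / s
}

# Spearman by explicit average ranks + textbook Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# BH step-up by the definition: sort, p_adj(i) = min_{j>=i} m*p(j)/j, cap 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# recursive flood fill over an explicit neighbour predicate
oracle_components <- function(mask, connectivity = 26) {
  grid <- dim(mask)
  lab <- array(0L, dim = grid)
  nxt <- 0L
  conn_ok <- function(d) {
    nz <- sum(d != 0)
    nz > 0 && nz <= switch(as.character(connectivity), "6" = 1, "18" = 2,
                           "26" = 3)
  }
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[apply(offs, 1, conn_ok), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      cc <- arrayInd(cur, grid)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + as.integer(offs[r, ])
        if (any(nb < 1L) || any(nb > grid)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- c(queue, (nb[3] - 1L) * grid[1] * grid[2] +
                       (nb[2] - 1L) * grid[1] + nb[1])
        }
      }
    }
  }
  nxt
}
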