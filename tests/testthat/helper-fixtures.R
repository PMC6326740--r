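# Shared fixtures and independent oracles used across the suite.

# Random symmetric "FC-like" matrix with unit diagonal: sample correlation
# of random data, so it is a genuine correlation matrix.
random_fc <- function(n_regions, n_frames = 50L, seed = 1L) {
  set.seed(seed)
  W <- stats::cor(matrix(rnorm(n_frames * n_regions), n_frames, n_regions))
  dimnames(W) <- NULL
  diag(W) <- 1
  W
}

# Brute-force region-level BGC by explicit pair enumeration.
oracle_region_bgc <- function(W, partition) {
  n <- partition$n_total
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(partition$network[i])
    acc <- 0
    cnt <- 0L
    for (j in seq_len(n)) {
      if (as.character(partition$network[j]) != own) {
        acc <- acc + W[i, j]
        cnt <- cnt + 1L
      }
    }
    out[i] <- acc / cnt
  }
  out
}

oracle_within_fc <- function(W, partition, network) {
  idx <- which(partition$network == network)
  acc <- 0
  cnt <- 0L
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b) {
        acc <- acc + W[idx[a], idx[b]]
        cnt <- cnt + 1L
      }
    }
  }
  acc / cnt
}

oracle_bgc_excluding <- function(W, partition, network, excluded) {
  idx <- which(partition$network == network)
  drop_nets <- c(network, excluded)
  vals <- vapply(idx, function(i) {
    acc <- 0
    cnt <- 0L
    for (j in seq_len(partition$n_total)) {
      if (!(as.character(partition$network[j]) %in% drop_nets)) {
        acc <- acc + W[i, j]
        cnt <- cnt + 1L
      }
    }
    acc / cnt
  }, numeric(1))
  mean(vals)
}

oracle_between_fc <- function(W, partition, netA, netB) {
  ia <- which(partition$network == netA)
  ib <- which(partition$network == netB)
  acc <- 0
  cnt <- 0L
  for (i in ia) for (j in ib) {
    acc <- acc + W[i, j]
    cnt <- cnt + 1L
  }
  acc / cnt
}

# Independent Benjamini-Hochberg step-up: adj_(i) = min_{j>=i} p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Small four-network test partition matching the scaled simulation geometry.
scaled_partition <- function() {
  make_partition(rep(15L, 4L),
                 c("Fronto-parietal", "Default mode", "Language",
                   "Visual 1"))
}
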