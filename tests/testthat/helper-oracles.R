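# Independent brute-force oracles. Each one enumerates pairs (or sums of
# squares) directly and shares no code with the implementation it checks.

# Haplotype diversity as 1 - (identical pairs)/(all pairs), enumerated over
# every unordered pair of samples; algebraically equal to Nei's unbiased
# n(1 - sum p^2)/(n - 1).
oracle_H <- function(haps) {
  n <- length(haps)
  same <- 0L
  pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pairs <- pairs + 1L
      if (haps[i] == haps[j]) same <- same + 1L
    }
  }
  1 - same / pairs
}

oracle_pairwise_d <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

oracle_mpd <- function(mat) {
  d <- oracle_pairwise_d(mat)
  n <- nrow(mat)
  tot <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + d[i, j]
      npair <- npair + 1L
    }
  }
  tot / npair
}

oracle_pi <- function(mat) oracle_mpd(mat) / ncol(mat)

# Sharing proportions by direct enumeration over sample pairs.
oracle_sharing <- function(haps, pops) {
  upops <- unique(pops)
  k <- length(upops)
  m <- matrix(NA_real_, k, k, dimnames = list(upops, upops))
  for (a in seq_len(k)) {
    ia <- which(pops == upops[a])
    if (length(ia) >= 2L) {
      same <- 0L; pairs <- 0L
      for (x in seq_along(ia)) {
        for (y in seq_along(ia)) {
          if (x < y) {
            pairs <- pairs + 1L
            if (haps[ia[x]] == haps[ia[y]]) same <- same + 1L
          }
        }
      }
      m[a, a] <- same / pairs
    }
    for (b in seq_len(k)) {
      if (a == b) next
      ib <- which(pops == upops[b])
      same <- 0L
      for (x in ia) for (y in ib) if (haps[x] == haps[y]) same <- same + 1L
      m[a, b] <- same / (length(ia) * length(ib))
    }
  }
  m
}

# Two-group AMOVA PhiST from explicit sums of squares (Excoffier 1992),
# written from the variance-component definitions.
oracle_phist <- function(d, groups) {
  N <- nrow(d)
  ss <- function(idx) {
    tot <- 0
    for (i in idx) for (j in idx) tot <- tot + d[i, j]^2
    tot / 2  # each unordered pair counted twice
  }
  ss_total <- ss(seq_len(N)) / N
  gs <- unique(groups)
  ss_within <- 0
  sum_n2 <- 0
  for (g in gs) {
    idx <- which(groups == g)
    ss_within <- ss_within + ss(idx) / length(idx)
    sum_n2 <- sum_n2 + length(idx)^2
  }
  sigma_w <- ss_within / (N - length(gs))
  n_c <- (N - sum_n2 / N) / (length(gs) - 1)
  msd_among <- (ss_total - ss_within) / (length(gs) - 1)
  sigma_a <- (msd_among - sigma_w) / n_c
  sigma_a / (sigma_a + sigma_w)
}
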