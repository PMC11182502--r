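#' Pairwise Hamming distances between sequence rows
#'
#' Number of differing positions between every pair of rows of a character
#' matrix (complete data; upstream masking/filtering guarantees no missing
#' characters, so no pairwise-deletion convention is needed).
#'
#' @param mat Character matrix, samples in rows.
#' @return A symmetric integer matrix of pairwise differences.
#' @export
pairwise_differences <- function(mat) {
  stopifnot(is.matrix(mat))
  n <- nrow(mat)
  d <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- sum(mat[i, ] != mat[j, ])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

as_seq_matrix <- function(x) {
  if (inherits(x, "alignment_set")) return(x$seqs)
  if (inherits(x, "genotype_table")) {
    if (any(x$calls == x$missing_token)) {
      stop("genotype table contains missing calls; run drop_missing_sites() first",
           call. = FALSE)
    }
    return(x$calls)
  }
  if (is.matrix(x) && is.character(x)) return(x)
  stop("expected an alignment_set, genotype_table or character matrix", call. = FALSE)
}

#' Haplotype (gene) diversity and its variance
#'
#' Nei's (1987) unbiased estimator
#' \eqn{H = n(1 - \sum p_i^2)/(n-1)} with sampling variance
#' \eqn{V(H) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 - (\sum p_i^2)^2\right) + \sum p_i^2 - (\sum p_i^2)^2\right]},
#' where \eqn{p_i} are haplotype relative frequencies. `H` is the
#' probability that two sequences drawn without replacement differ; it is 0
#' iff a single haplotype is present and exactly 1 when all samples are
#' distinct.
#'
#' @param counts Nonnegative integer vector of haplotype counts (one
#'   population); must total at least 2.
#' @return A list with elements `H` and `var_H`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity is undefined for n < 2", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n * (1 - s2) / (n - 1)
  var_H <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, var_H = var_H)
}

#' Nucleotide diversity and its variance
#'
#' Per-site nucleotide diversity
#' \eqn{\pi = \sum_{i<j} d_{ij} / (\binom{n}{2} L)} over the retained
#' columns, where \eqn{d_{ij}} is the pairwise Hamming distance and `L` the
#' effective (retained) length; variance by Nei (1987, eq. 10.9):
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param x A `masked_alignment`, `genotype_table` (no missing calls) or
#'   character matrix, restricted to one population (optionally via
#'   `samples`).
#' @param samples Optional vector of sample ids to subset.
#' @return A list with elements `pi`, `var_pi` and `L` (the effective
#'   length used for normalization).
#' @export
nucleotide_diversity <- function(x, samples = NULL) {
  mat <- as_seq_matrix(x)
  if (!is.null(samples)) mat <- mat[samples, , drop = FALSE]
  n <- nrow(mat)
  L <- ncol(mat)
  if (n < 2) stop("nucleotide diversity is undefined for n < 2", call. = FALSE)
  if (L == 0) stop("no retained columns (L = 0)", call. = FALSE)
  if (any(mat == "N")) stop("N present among retained columns; mask first", call. = FALSE)
  d <- pairwise_differences(mat)
  pi <- sum(d[upper.tri(d)]) / (choose(n, 2) * L)
  var_pi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, var_pi = var_pi, L = L)
}

#' Mean number of pairwise differences (MPD)
#'
#' \eqn{MPD = \sum_{i<j} d_{ij} / \binom{n}{2}}, in raw site counts (not
#' per-site): the average number of nucleotide differences between two
#' sequences of the population. `MPD = pi * L` on the same data.
#'
#' @inheritParams nucleotide_diversity
#' @return The MPD (numeric scalar, >= 0).
#' @export
mean_pairwise_differences <- function(x, samples = NULL) {
  mat <- as_seq_matrix(x)
  if (!is.null(samples)) mat <- mat[samples, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2) stop("MPD is undefined for n < 2", call. = FALSE)
  d <- pairwise_differences(mat)
  sum(d[upper.tri(d)]) / choose(n, 2)
}

#' Percentage difference from the mean
#'
#' For a statistic observed across populations, expresses each population's
#' value as a percent deviation from the across-population mean:
#' \eqn{100 (x_p - \bar{x})/\bar{x}}. Used to visualize which populations
#' are above or below average diversity.
#'
#' @param values Named numeric vector (one value per population); the mean
#'   must be nonzero.
#' @return Named numeric vector of percent deviations (may be negative).
#' @export
percent_from_mean <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero; percent difference from mean is undefined", call. = FALSE)
  100 * (values - m) / m
}

#' Per-population diversity summary
#'
#' Computes, for each population in the metadata: sample size `n`, number
#' of distinct haplotypes `k`, haplotype diversity `H` and its variance,
#' per-site nucleotide diversity `pi` and its variance, the mean number of
#' pairwise differences `MPD`, and the percent deviation of `H` and `pi`
#' from their across-population means. Populations with fewer than
#' `min_n` samples are reported with `NA` statistics.
#'
#' @param x A `masked_alignment` or missing-free `genotype_table`.
#' @param meta Sample metadata covering all samples in `x`.
#' @param min_n Minimum sample size for estimation (default 2).
#' @return A data frame with one row per population and columns
#'   `population, n, k, H, var_H, pi, var_pi, MPD, pct_from_mean_H,
#'   pct_from_mean_pi`, plus an `effective_length` attribute.
#' @export
diversity_summary <- function(x, meta, min_n = 2L) {
  mat <- as_seq_matrix(x)
  meta <- as_sample_metadata(as.data.frame(meta))
  ht <- if (inherits(x, "genotype_table")) genotype_haplotypes(x, meta)
        else collapse_haplotypes(x, meta)
  pops <- rownames(ht$counts)
  pop_of <- stats::setNames(meta$population, meta$sample_id)[rownames(mat)]
  res <- lapply(pops, function(p) {
    ids <- rownames(mat)[pop_of == p]
    n <- length(ids)
    k <- sum(ht$counts[p, ] > 0L)
    if (n < min_n) {
      return(data.frame(population = p, n = n, k = k, H = NA_real_,
                        var_H = NA_real_, pi = NA_real_, var_pi = NA_real_,
                        MPD = NA_real_, stringsAsFactors = FALSE))
    }
    hd <- haplotype_diversity(ht$counts[p, ])
    nd <- nucleotide_diversity(mat[ids, , drop = FALSE])
    data.frame(population = p, n = n, k = k, H = hd$H, var_H = hd$var_H,
               pi = nd$pi, var_pi = nd$var_pi,
               MPD = mean_pairwise_differences(mat[ids, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$H)
  out$pct_from_mean_H <- NA_real_
  out$pct_from_mean_pi <- NA_real_
  if (any(ok) && mean(out$H[ok]) != 0) {
    out$pct_from_mean_H[ok] <- percent_from_mean(out$H[ok])
  }
  if (any(ok) && mean(out$pi[ok]) != 0) {
    out$pct_from_mean_pi[ok] <- percent_from_mean(out$pi[ok])
  }
  attr(out, "effective_length") <- ncol(mat)
  out
}
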