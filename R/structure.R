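#' Two-group AMOVA PhiST from a distance matrix
#'
#' Analysis of molecular variance (Excoffier et al. 1992) for two groups of
#' haploid sequences, using squared pairwise distances. With `N` sequences
#' in groups of sizes \eqn{n_1, n_2}:
#' \deqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N, \quad
#'       SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g,}
#' \eqn{\sigma^2_w = SS_{within}/(N-2)},
#' \eqn{\sigma^2_a = (SS_{among} - \sigma^2_w)/n_c} with
#' \eqn{n_c = N - (n_1^2+n_2^2)/N} and one among-group degree of freedom,
#' and \eqn{\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)}.
#'
#' @param d Symmetric matrix of pairwise distances (not squared).
#' @param groups Vector of two group labels, one per row of `d`.
#' @return PhiST (numeric scalar; may be slightly negative by sampling).
#' @keywords internal
amova_phist <- function(d, groups) {
  d2 <- d^2
  N <- nrow(d2)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) != 2L) stop("exactly two groups required", call. = FALSE)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in names(sizes)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  sigma_w <- ss_within / (N - 2)
  n_c <- N - sum(sizes^2) / N
  sigma_a <- (ss_among / 1 - sigma_w) / n_c
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise PhiST with permutation tests
#'
#' For every pair of populations with at least two samples each, performs a
#' two-group AMOVA on the matrix of pairwise Hamming distances and reports
#' \eqn{\Phi_{ST}}, the fraction of total molecular variance attributable
#' to the between-population component. Significance is assessed by
#' permuting individuals between the two populations (haplotypes kept
#' intact) and recomputing \eqn{\Phi_{ST}}; the p-value is
#' \eqn{(1 + \#\{\Phi^{perm} \ge \Phi^{obs}\}) / (1 + B)}.
#'
#' Negative \eqn{\Phi_{ST}} estimates (sampling noise around zero) are
#' reported as computed, not truncated; see [phist_for_nmds()] for the
#' NMDS-ready transform.
#'
#' @param x A `masked_alignment`, missing-free `genotype_table`, or
#'   character matrix of sequences.
#' @param meta Sample metadata covering all samples.
#' @param n_permutations Number of label permutations per pair (default
#'   1000).
#' @param seed Integer seed making the permutation p-values reproducible.
#' @return A `phist_result`: `populations`, symmetric `phi_st` matrix
#'   (diagonal 0), symmetric `p_values` matrix (diagonal `NA`),
#'   `n_permutations`, `seed`. Pairs involving a population with n < 2 are
#'   `NA` with a warning.
#' @export
pairwise_phist <- function(x, meta, n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  mat <- as_seq_matrix(x)
  meta <- as_sample_metadata(as.data.frame(meta))
  missing_meta <- setdiff(rownames(mat), meta$sample_id)
  if (length(missing_meta) > 0L) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  pop_of <- stats::setNames(meta$population, meta$sample_id)[rownames(mat)]
  pops <- unique(meta$population[meta$sample_id %in% rownames(mat)])
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  d <- pairwise_differences(mat)
  k <- length(pops)
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  pval <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  sizes <- table(pop_of)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("population(s) with n < 2 skipped in PhiST: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      if (pops[a] %in% small || pops[b] %in% small) {
        phi[a, b] <- phi[b, a] <- NA_real_
        next
      }
      idx <- which(pop_of %in% c(pops[a], pops[b]))
      dsub <- d[idx, idx, drop = FALSE]
      grp <- pop_of[idx]
      obs <- amova_phist(dsub, grp)
      hits <- 0L
      for (r in seq_len(n_permutations)) {
        if (amova_phist(dsub, sample(grp)) >= obs) hits <- hits + 1L
      }
      p <- (1 + hits) / (1 + n_permutations)
      phi[a, b] <- phi[b, a] <- obs
      pval[a, b] <- pval[b, a] <- p
    }
  }
  structure(
    list(populations = pops, phi_st = phi, p_values = pval,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed)),
    class = "phist_result"
  )
}

#' @export
print.phist_result <- function(x, ...) {
  cat(sprintf("<phist_result> %d populations, %d permutations (seed %d)\n",
              length(x$populations), x$n_permutations, x$seed))
  invisible(x)
}

#' Prepare a PhiST matrix for NMDS
#'
#' Non-metric MDS requires nonnegative dissimilarities with no off-diagonal
#' exact zeros. Negative PhiST estimates are clamped to 0 and off-diagonal
#' exact zeros are then offset by `eps`; the diagonal stays 0.
#'
#' @param pr A `phist_result` or a symmetric numeric matrix.
#' @param eps Offset applied to off-diagonal exact zeros (default `1e-6`).
#' @return A symmetric dissimilarity matrix suitable for [nmds()].
#' @export
phist_for_nmds <- function(pr, eps = 1e-6) {
  m <- if (inherits(pr, "phist_result")) pr$phi_st else pr
  m <- pmax(m, 0)
  zero <- m == 0 & row(m) != col(m)
  m[zero] <- eps
  diag(m) <- 0
  m
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's NMDS via [MASS::isoMDS()]: a classical (metric) scaling
#' configuration is refined by isotonic regression of configuration
#' distances on the rank order of the input dissimilarities, minimizing
#' stress-1. Stress is reported in percent. Optionally the fit is repeated
#' from seeded random initial configurations and the lowest-stress solution
#' kept.
#'
#' @param d Symmetric dissimilarity matrix, zero diagonal, nonnegative with
#'   no off-diagonal zeros (see [phist_for_nmds()]).
#' @param k Number of dimensions (default 2).
#' @param n_restarts Additional random-start fits (default 0:
#'   deterministic classical-scaling start only).
#' @param seed Seed for the random restarts.
#' @param maxit Maximum isoMDS iterations (default 100).
#' @return An `ordination_result` with `points` (rows = objects), `k`, and
#'   `stress` (percent).
#' @export
nmds <- function(d, k = 2L, n_restarts = 0L, seed = 1L, maxit = 100L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
    stop("'d' must be a symmetric dissimilarity matrix", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("'d' must have a zero diagonal", call. = FALSE)
  if (any(d < 0)) stop("negative dissimilarities; use phist_for_nmds() first", call. = FALSE)
  if (any(d[upper.tri(d)] == 0)) {
    stop("off-diagonal zero dissimilarities; use phist_for_nmds() first", call. = FALSE)
  }
  n <- nrow(d)
  if (k < 1L || k > n - 1L) stop("need 1 <= k <= n - 1", call. = FALSE)
  dd <- stats::as.dist(d)
  # classical-scaling start; pad deterministically when the double-centred
  # matrix has fewer than k positive eigenvalues (isoMDS rejects rank-
  # deficient or duplicated initial configurations)
  y0 <- suppressWarnings(stats::cmdscale(dd, k = k))
  if (ncol(y0) < k) {
    pad <- matrix(0, n, k - ncol(y0))
    y0 <- cbind(y0, pad)
  }
  scale0 <- max(mean(d), 1e-8)
  jitter0 <- scale0 * 1e-4 *
    matrix(sin(seq_len(n * k) * 9973), n, k)  # fixed, seed-free perturbation
  y0 <- y0 + jitter0
  fit <- MASS::isoMDS(dd, y = y0, k = k, maxit = maxit, trace = FALSE)
  if (n_restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      y0 <- matrix(stats::rnorm(n * k), n, k)
      cand <- MASS::isoMDS(dd, y = y0, k = k, maxit = maxit, trace = FALSE)
      if (cand$stress < fit$stress) fit <- cand
    }
  }
  pts <- fit$points
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Dim", seq_len(k))
  structure(list(points = pts, k = as.integer(k), stress = fit$stress),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  if (!is.null(x$stress)) {
    cat(sprintf("<ordination_result> NMDS, %d objects in %d dimensions, stress %.3f%%\n",
                nrow(x$points), x$k, x$stress))
  } else {
    cat(sprintf("<ordination_result> CA, %d rows x %d columns, total inertia %.4f\n",
                nrow(x$points), nrow(x$column_points), x$total_inertia))
  }
  invisible(x)
}

#' Correspondence analysis of a frequency table
#'
#' Classical (simple) correspondence analysis of a populations-by-
#' haplogroups count table. With correspondence matrix `P = table/n`, row
#' masses `r`, column masses `c`, the matrix of standardized residuals
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}} is decomposed by SVD
#' \eqn{S = U \Sigma V^T}; principal coordinates are
#' \eqn{F = D_r^{-1/2} U \Sigma} (rows) and \eqn{G = D_c^{-1/2} V \Sigma}
#' (columns). The inertia of axis `k` is \eqn{\sigma_k^2}, and total
#' inertia \eqn{\sum_k \sigma_k^2 = \chi^2 / n}.
#'
#' A table of row-wise relative frequencies (rows summing to 1) is accepted
#' and re-expressed with uniform pseudo-counts of 1000 per row (flagged in
#' the `frequencies_rescaled` attribute), since CA row masses require
#' relative row weights.
#'
#' @param tab Nonnegative matrix of counts, populations in rows,
#'   categories (haplogroups) in columns; no all-zero row or column.
#' @return An `ordination_result` with row principal coordinates `points`,
#'   `column_points`, row/column standard coordinates (`row_standard`,
#'   `column_standard`), `inertia_per_axis` and `total_inertia`.
#' @export
correspondence_analysis <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative entries in frequency table", call. = FALSE)
  rescaled <- FALSE
  if (all(abs(rowSums(tab) - 1) < 1e-8)) {
    tab <- tab * 1000
    rescaled <- TRUE
  }
  zr <- rownames(tab)[rowSums(tab) == 0]
  zc <- colnames(tab)[colSums(tab) == 0]
  if (length(zr) > 0L) stop("all-zero row(s): ", paste(zr, collapse = ", "), call. = FALSE)
  if (length(zc) > 0L) stop("all-zero column(s): ", paste(zc, collapse = ", "), call. = FALSE)
  n <- sum(tab)
  P <- tab / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  keep <- sv$d > max(sv$d[1], 1) * 1e-12
  if (!any(keep)) keep[1] <- TRUE  # rank-0 residual (independence): one ~zero axis
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  ax <- paste0("CA", seq_along(d))
  row_std <- diag(1 / sqrt(r)) %*% U
  col_std <- diag(1 / sqrt(cc)) %*% V
  Frow <- row_std %*% diag(d, nrow = length(d))
  Gcol <- col_std %*% diag(d, nrow = length(d))
  dimnames(Frow) <- list(rownames(tab), ax)
  dimnames(Gcol) <- list(colnames(tab), ax)
  dimnames(row_std) <- list(rownames(tab), ax)
  dimnames(col_std) <- list(colnames(tab), ax)
  out <- structure(
    list(points = Frow, column_points = Gcol,
         row_standard = row_std, column_standard = col_std,
         inertia_per_axis = stats::setNames(d^2, ax),
         total_inertia = sum(d^2), k = length(d)),
    class = "ordination_result"
  )
  attr(out, "frequencies_rescaled") <- rescaled
  out
}

#' Significance marks for a PhiST matrix
#'
#' Marks population pairs whose PhiST is not significantly different from
#' zero (permutation p > threshold) with a cross symbol, following the
#' display convention of pairwise-distance heatmaps. No multiple-testing
#' correction is applied (a caveat when many pairs are tested).
#'
#' @param pr A `phist_result`.
#' @param alpha Significance threshold (default 0.05).
#' @return Character matrix: `"x"` where p > `alpha`, `""` elsewhere,
#'   `NA` on the diagonal.
#' @export
phist_significance_marks <- function(pr, alpha = 0.05) {
  stopifnot(inherits(pr, "phist_result"))
  marks <- ifelse(pr$p_values > alpha, "x", "")
  diag(marks) <- NA_character_
  marks
}
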