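#' Identical-haplotype sharing within and between populations
#'
#' The proportion of pairs of identical sequences within and between
#' populations. Between two populations A and B the statistic counts all
#' \eqn{n_A n_B} cross pairs:
#' \eqn{S(A,B) = \sum_h c_A(h) c_B(h) / (n_A n_B)};
#' within a population it counts unordered pairs:
#' \eqn{S(A,A) = \sum_h \binom{c_A(h)}{2} / \binom{n_A}{2}}.
#' These denominators make the matrix symmetric, and make the diagonal
#' equal 1 exactly when all of a population's sequences are identical.
#' Self-pairs are never counted. Populations of size 1 get a flagged `NA`
#' diagonal (a single sequence carries no within-population sharing
#' evidence) but contribute normally to between-population entries.
#'
#' High within-population sharing indicates small population size or a
#' recent bottleneck; high between-population sharing indicates recent
#' contact or shared ancestry.
#'
#' @param ht A `haplotype_table` (see [collapse_haplotypes()]).
#' @return A `sharing_matrix`: symmetric populations-by-populations matrix
#'   of sharing proportions in `[0, 1]`.
#' @export
sharing_matrix <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  counts <- ht$counts
  if (nrow(counts) == 0L || sum(counts) == 0L) {
    stop("empty haplotype table", call. = FALSE)
  }
  pops <- rownames(counts)
  n <- rowSums(counts)
  k <- length(pops)
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k)) {
    if (n[a] >= 2L) {
      m[a, a] <- sum(choose(counts[a, ], 2)) / choose(n[a], 2)
    }
    if (a < k) {
      for (b in (a + 1L):k) {
        v <- sum(counts[a, ] * counts[b, ]) / (n[a] * n[b])
        m[a, b] <- v
        m[b, a] <- v
      }
    }
  }
  structure(m, class = c("sharing_matrix", "matrix"))
}

#' Order a sharing matrix for heatmap-style display
#'
#' Reorders rows and columns by a metadata-driven grouping (language family,
#' then population), matching the convention of grouped sharing heatmaps.
#' Values are unchanged.
#'
#' @param sm A `sharing_matrix`.
#' @param meta Sample metadata; its `population` and `language_family`
#'   columns define the grouping and must cover every population in `sm`.
#' @return The reordered matrix (plain labelled matrix, ready for
#'   [write_matrix()]).
#' @export
sharing_heatmap_table <- function(sm, meta) {
  stopifnot(inherits(sm, "sharing_matrix"))
  meta <- as_sample_metadata(as.data.frame(meta))
  pops <- rownames(sm)
  key <- unique(meta[, c("population", "language_family")])
  missing <- setdiff(pops, key$population)
  if (length(missing) > 0L) {
    stop("population(s) absent from ordering metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- key[key$population %in% pops, ]
  ord <- key$population[order(key$language_family, key$population)]
  out <- unclass(sm)[ord, ord]
  out
}

#' Long-format sharing table
#'
#' @param sm A `sharing_matrix`.
#' @return A data frame with columns `popA`, `popB`, `sharing`, one row per
#'   unordered population pair (including the diagonal).
#' @export
sharing_long <- function(sm) {
  stopifnot(inherits(sm, "sharing_matrix"))
  pops <- rownames(sm)
  idx <- which(upper.tri(sm, diag = TRUE), arr.ind = TRUE)
  data.frame(popA = pops[idx[, 1L]], popB = pops[idx[, 2L]],
             sharing = sm[idx], stringsAsFactors = FALSE)
}
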