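#' Construct a mask specification
#'
#' A mask is a set of labelled, non-overlapping, 1-based inclusive reference
#' coordinate ranges to exclude from analysis.
#'
#' @param start,end Integer vectors of inclusive range bounds (`start <= end`).
#' @param label Character vector of range labels.
#' @return A `mask_spec`: a data frame of normalized (sorted) ranges.
#' @export
mask_spec <- function(start, end, label = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.null(label)) {
    label <- if (length(start) > 0L) paste0("range", seq_along(start)) else character(0)
  }
  if (length(start) != length(end) || length(start) != length(label)) {
    stop("start, end and label must have equal length", call. = FALSE)
  }
  if (any(start < 1L)) stop("mask coordinates are 1-based; start must be >= 1", call. = FALSE)
  if (any(end < start)) {
    stop("mask range(s) with end < start: ",
         paste(label[end < start], collapse = ", "), call. = FALSE)
  }
  o <- order(start)
  ranges <- data.frame(start = start[o], end = end[o], label = label[o],
                       stringsAsFactors = FALSE)
  if (nrow(ranges) > 1L && any(ranges$start[-1L] <= ranges$end[-nrow(ranges)])) {
    stop("mask ranges overlap after normalization", call. = FALSE)
  }
  structure(ranges, class = c("mask_spec", "data.frame"))
}

#' The default complete-mitogenome mask
#'
#' Eight regions of the mitogenome that are unreliable in multiple sequence
#' alignments and conventionally excluded before haplotype-based analysis:
#' the HVS-II poly-C stretch (np 303-317), the CA repeat (np 514-523),
#' C-stretch 1 (np 568-573), a 12S rRNA homopolymer (np 956-965), the
#' historical position np 3107, C-stretch 2 (np 5895-5899), the 9-bp
#' deletion/insertion region (np 8272-8289) and the HVS-I poly-C stretch
#' (np 16180-16195). Coordinates are 1-based inclusive reference positions
#' (RSRS/rCRS numbering); the ranges cover 81 positions in total.
#'
#' @return A `mask_spec` with the eight ranges.
#' @export
default_mtdna_mask <- function() {
  mask_spec(
    start = c(303L, 514L, 568L, 956L, 3107L, 5895L, 8272L, 16180L),
    end   = c(317L, 523L, 573L, 965L, 3107L, 5899L, 8289L, 16195L),
    label = c("HVS-II_poly-C", "CA_repeat", "C-stretch_1", "12S_rRNA",
              "historical_3107", "C-stretch_2", "9bp_indel", "HVS-I_poly-C")
  )
}

#' Total number of reference positions covered by a mask
#'
#' @param mask A `mask_spec`.
#' @return Integer count of masked positions.
#' @export
mask_width <- function(mask) {
  stopifnot(inherits(mask, "mask_spec"))
  sum(mask$end - mask$start + 1L)
}

#' Apply site-exclusion rules to an alignment
#'
#' Removes (1) columns whose reference position falls in any mask range,
#' (2) columns containing one or more `N` over the analysis sample set
#' (when `drop_n_columns`), and (3) columns containing a gap character
#' (when `drop_gap_columns`; gap columns relative to the reference carry no
#' reference coordinate and cannot be addressed by coordinate ranges).
#' Column removal is dataset-wide (complete deletion), so every downstream
#' statistic sees one common site set.
#'
#' A removed column is recorded once, with the first matching reason in the
#' order mask range, N, gap. Mask ranges beyond the reference length are
#' ignored with a warning. Idempotent: re-masking a masked alignment with
#' the same spec removes nothing further.
#'
#' @param aln An `alignment_set` (or `masked_alignment`).
#' @param mask A `mask_spec`; may be empty (`mask_spec(integer(), integer())`).
#' @param drop_n_columns Drop columns containing `N`? Default `TRUE`.
#' @param drop_gap_columns Drop columns containing `-`? Default `TRUE`.
#' @return A `masked_alignment`: the retained alignment plus
#'   `removed_columns` (column index and reason) and `effective_length`.
#' @export
apply_mask <- function(aln, mask, drop_n_columns = TRUE, drop_gap_columns = TRUE) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!inherits(mask, "mask_spec")) stop("'mask' must be a mask_spec", call. = FALSE)
  if (nrow(mask) > 0L && is.null(aln$column_to_refpos)) {
    stop("alignment has no reference coordinate map; cannot apply a nonempty mask",
         call. = FALSE)
  }
  ncols <- ncol(aln$seqs)
  refpos <- aln$column_to_refpos %||% seq_len(ncols)
  max_ref <- suppressWarnings(max(refpos, na.rm = TRUE))
  if (nrow(mask) > 0L && any(mask$start > max_ref)) {
    beyond <- mask$label[mask$start > max_ref]
    warning("mask range(s) beyond reference length ", max_ref, " ignored: ",
            paste(beyond, collapse = ", "), call. = FALSE)
  }
  in_range <- rep(FALSE, ncols)
  for (i in seq_len(nrow(mask))) {
    in_range <- in_range | (!is.na(refpos) & refpos >= mask$start[i] & refpos <= mask$end[i])
  }
  has_n <- if (drop_n_columns) colSums(aln$seqs == "N") > 0L else rep(FALSE, ncols)
  has_gap <- if (drop_gap_columns) colSums(aln$seqs == "-") > 0L else rep(FALSE, ncols)
  reason <- rep(NA_character_, ncols)
  reason[has_gap] <- "contains_gap"
  reason[has_n] <- "contains_N"
  reason[in_range] <- "in_mask_range"
  drop <- !is.na(reason)
  removed <- data.frame(column = which(drop), reason = reason[drop],
                        stringsAsFactors = FALSE)
  keep <- which(!drop)
  out <- new_alignment_set(aln$seqs[, keep, drop = FALSE],
                           reference_id = aln$reference_id,
                           column_to_refpos = refpos[keep])
  out$removed_columns <- removed
  out$effective_length <- length(keep)
  class(out) <- c("masked_alignment", "alignment_set")
  out
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf(
    "<masked_alignment> %d sequences x %d retained columns (%d removed: %s)\n",
    nrow(x$seqs), x$effective_length, nrow(x$removed_columns),
    if (nrow(x$removed_columns) > 0L) {
      paste(names(table(x$removed_columns$reason)),
            table(x$removed_columns$reason), sep = "=", collapse = ", ")
    } else "none"
  ))
  invisible(x)
}

new_haplotype_table <- function(haplotype_ids, haplotype_seqs, counts, sample_to_haplotype) {
  n_total <- sum(counts)
  if (n_total != length(sample_to_haplotype)) {
    stop("haplotype table is inconsistent: counts total ", n_total,
         " but ", length(sample_to_haplotype), " samples mapped", call. = FALSE)
  }
  structure(
    list(
      haplotype_ids = haplotype_ids,
      haplotype_seqs = haplotype_seqs,
      counts = counts,
      sample_to_haplotype = sample_to_haplotype
    ),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes, %d samples, %d populations\n",
              length(x$haplotype_ids), sum(x$counts), nrow(x$counts)))
  invisible(x)
}

collapse_strings <- function(strings, meta) {
  stopifnot(!is.null(names(strings)))
  missing_meta <- setdiff(names(strings), meta$sample_id)
  if (length(missing_meta) > 0L) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  pop <- stats::setNames(meta$population, meta$sample_id)[names(strings)]
  hap_seq <- unique(strings)  # order of first appearance
  hap_ids <- paste0("H", seq_along(hap_seq))
  idx <- match(strings, hap_seq)
  pops <- unique(meta$population[meta$sample_id %in% names(strings)])
  counts <- matrix(0L, nrow = length(pops), ncol = length(hap_seq),
                   dimnames = list(pops, hap_ids))
  tab <- table(factor(pop, levels = pops), factor(idx, levels = seq_along(hap_seq)))
  counts[] <- as.integer(tab)
  new_haplotype_table(hap_ids, stats::setNames(hap_seq, hap_ids), counts,
                      stats::setNames(hap_ids[idx], names(strings)))
}

#' Collapse aligned sequences into haplotypes
#'
#' Haplotypes are equivalence classes of exact string identity over the
#' retained alignment columns; collapsing therefore always operates on a
#' masked alignment. Haplotype ids are assigned in order of first
#' appearance; counts are tabulated per population.
#'
#' @param aln A `masked_alignment` (or `alignment_set`).
#' @param meta Sample metadata (see [read_metadata()]); every sample in the
#'   alignment must be present.
#' @return A `haplotype_table`: haplotype ids/sequences, a population-by-
#'   haplotype count matrix, and the sample-to-haplotype map.
#' @export
collapse_haplotypes <- function(aln, meta) {
  stopifnot(inherits(aln, "alignment_set"))
  meta <- as_sample_metadata(as.data.frame(meta))
  strings <- apply(aln$seqs, 1L, paste, collapse = "")
  collapse_strings(strings, meta)
}

#' Drop genotype sites with any missing call
#'
#' A site is removed when it carries one or more missing calls across all
#' samples (complete deletion), so that remaining sites support full-length
#' haplotype strings for every sample. Site order is preserved; removed
#' positions are reported in the `removed_sites` attribute.
#'
#' @param g A `genotype_table`.
#' @return A `genotype_table` without missing calls.
#' @export
drop_missing_sites <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  has_missing <- colSums(g$calls == g$missing_token) > 0L
  if (all(has_missing) && ncol(g$calls) > 0L) {
    warning("all sites contain missing calls; result has no sites", call. = FALSE)
  }
  out <- new_genotype_table(g$sample_ids, g$site_positions[!has_missing],
                            g$calls[, !has_missing, drop = FALSE], g$missing_token)
  attr(out, "removed_sites") <- g$site_positions[has_missing]
  out
}

#' Collapse SNP genotypes into haplotypes
#'
#' The haplotype of a sample is its concatenated allele string across all
#' sites; collapsing semantics are identical to [collapse_haplotypes()].
#' The table must contain no missing calls — run [drop_missing_sites()]
#' first.
#'
#' @param g A `genotype_table` with no missing calls and >= 1 site.
#' @param meta Sample metadata covering all samples.
#' @return A `haplotype_table`.
#' @export
genotype_haplotypes <- function(g, meta) {
  stopifnot(inherits(g, "genotype_table"))
  if (ncol(g$calls) == 0L) {
    stop("genotype table has no sites; cannot form haplotypes", call. = FALSE)
  }
  if (any(g$calls == g$missing_token)) {
    stop("genotype table contains missing calls; run drop_missing_sites() first",
         call. = FALSE)
  }
  meta <- as_sample_metadata(as.data.frame(meta))
  strings <- apply(g$calls, 1L, paste, collapse = "")
  names(strings) <- g$sample_ids
  collapse_strings(strings, meta)
}
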