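# Small in-code fixture builders shared across test files.

# Build an alignment_set from equal-length strings, e.g. aln_from_strings(
#   c(S1 = "ACGT", S2 = "ACGA")).
aln_from_strings <- function(strings) {
  mat <- do.call(rbind, lapply(strings, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(strings)
  uniparental:::new_alignment_set(mat)
}

masked_from_strings <- function(strings) {
  apply_mask(aln_from_strings(strings), mask_spec(integer(), integer()))
}

meta_df <- function(ids, pops, family = "") {
  as_sample_metadata(data.frame(
    sample_id = ids, population = pops, language_family = family,
    stringsAsFactors = FALSE
  ))
}

# Random alignment over a small alphabet; low cardinality makes shared
# haplotypes and distance ties likely, which is what the collapsing and
# sharing code must handle.
random_aln <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), n, L,
                dimnames = list(sprintf("S%02d", seq_len(n)), NULL))
  uniparental:::new_alignment_set(mat)
}

# Build a haplotype_table straight from a population x haplotype count matrix.
ht_from_counts <- function(counts) {
  hap_ids <- colnames(counts)
  if (is.null(hap_ids)) hap_ids <- paste0("H", seq_len(ncol(counts)))
  colnames(counts) <- hap_ids
  samples <- character(0)
  haps <- character(0)
  for (p in rownames(counts)) {
    for (h in hap_ids) {
      n <- counts[p, h]
      if (n > 0) {
        samples <- c(samples, paste0(p, "_", h, "_", seq_len(n)))
        haps <- c(haps, rep(h, n))
      }
    }
  }
  uniparental:::new_haplotype_table(
    hap_ids, stats::setNames(hap_ids, hap_ids), counts,
    stats::setNames(haps, samples)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
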