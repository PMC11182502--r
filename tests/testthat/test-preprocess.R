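test_that("the default mitogenome mask has eight ordered ranges covering 81 positions", {
  m <- default_mtdna_mask()
  expect_equal(nrow(m), 8L)
  expect_true(all(m$start <= m$end))
  expect_equal(mask_width(m), 81L)
  # shipped TSV matches the built-in definition
  shipped <- read_mask(system.file("extdata", "mtdna_mask.tsv",
                                   package = "uniparental"))
  expect_equal(shipped$start, m$start)
  expect_equal(shipped$end, m$end)
})

test_that("mask_spec rejects invalid and overlapping ranges", {
  expect_error(mask_spec(5, 3), "end < start")
  expect_error(mask_spec(c(1, 5), c(6, 9)), "overlap")
  expect_silent(mask_spec(c(5, 1), c(9, 4)))  # unsorted but disjoint is fine
})

test_that("masking a full-length gapless panel removes exactly the 81 masked positions", {
  set.seed(42)
  aln <- random_aln(3, 16569)
  masked <- apply_mask(aln, default_mtdna_mask())
  expect_equal(nrow(masked$removed_columns), 81L)
  expect_true(all(masked$removed_columns$reason == "in_mask_range"))
  expect_equal(masked$effective_length, 16569L - 81L)
})

test_that("masking removes N and gap columns with recorded reasons and conserves columns", {
  aln <- aln_from_strings(c(s1 = "ACGTACGT", s2 = "ANGT-CGT", s3 = "ACGTACGA"))
  masked <- apply_mask(aln, mask_spec(c(1), c(1), "first"))
  expect_equal(sort(masked$removed_columns$column), c(1L, 2L, 5L))
  got <- masked$removed_columns
  expect_equal(got$reason[got$column == 1], "in_mask_range")
  expect_equal(got$reason[got$column == 2], "contains_N")
  expect_equal(got$reason[got$column == 5], "contains_gap")
  # conservation: removed + retained = original
  expect_equal(nrow(masked$removed_columns) + masked$effective_length, 8L)
  # empty mask, clean alignment: identity
  clean <- aln_from_strings(c(a = "ACGT", b = "ACGA"))
  out <- apply_mask(clean, mask_spec(integer(), integer()))
  expect_identical(out$seqs, clean$seqs)
  expect_equal(nrow(out$removed_columns), 0L)
  # flags disable N/gap dropping
  kept <- apply_mask(aln, mask_spec(integer(), integer()),
                     drop_n_columns = FALSE, drop_gap_columns = FALSE)
  expect_equal(kept$effective_length, 8L)
})

test_that("masking is idempotent", {
  set.seed(7)
  aln <- random_aln(4, 400, alphabet = c("A", "C", "G", "T", "N"))
  mask <- mask_spec(c(10, 50), c(20, 60), c("a", "b"))
  once <- apply_mask(aln, mask)
  twice <- apply_mask(once, mask)
  expect_identical(twice$seqs, once$seqs)
  expect_equal(nrow(twice$removed_columns), 0L)
})

test_that("mask ranges beyond the reference length are ignored with a warning", {
  aln <- aln_from_strings(c(a = "ACGTACGTAC", b = "ACGTACGTAG"))
  expect_warning(out <- apply_mask(aln, default_mtdna_mask()), "beyond reference length")
  expect_equal(out$effective_length, 10L)
})

test_that("haplotype collapsing forms identity classes with per-population counts", {
  # six identical sequences, one population
  masked <- masked_from_strings(stats::setNames(rep("ACGTAC", 6), paste0("m", 1:6)))
  ht <- collapse_haplotypes(masked, meta_df(paste0("m", 1:6), rep("Ma", 6)))
  expect_equal(length(ht$haplotype_ids), 1L)
  expect_equal(unname(ht$counts["Ma", 1]), 6L)

  # {s1,s1,s2} in A and {s1,s3} in B -> 3 haplotypes, counts by hand
  masked <- masked_from_strings(c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAT",
                                  b1 = "AAAA", b2 = "TTTT"))
  ht <- collapse_haplotypes(masked, meta_df(c("a1", "a2", "a3", "b1", "b2"),
                                            c("A", "A", "A", "B", "B")))
  expect_equal(length(ht$haplotype_ids), 3L)
  expect_equal(unname(ht$counts["A", ]), c(2L, 1L, 0L))
  expect_equal(unname(ht$counts["B", ]), c(1L, 0L, 1L))

  # all distinct -> one haplotype per sample
  masked <- masked_from_strings(c(x = "AAAA", y = "AAAT", z = "AATT"))
  ht <- collapse_haplotypes(masked, meta_df(c("x", "y", "z"), rep("P", 3)))
  expect_equal(length(ht$haplotype_ids), 3L)

  # missing metadata is an error naming the samples
  expect_error(
    collapse_haplotypes(masked, meta_df(c("x", "y"), c("P", "P"))),
    "without metadata: z"
  )
})

test_that("count-matrix total equals sample count on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    aln <- random_aln(n, 6, alphabet = c("A", "T"))
    meta <- meta_df(rownames(aln$seqs), sample(c("P1", "P2", "P3"), n, replace = TRUE))
    ht <- collapse_haplotypes(aln, meta)
    expect_equal(sum(ht$counts), n)
    expect_equal(unname(rowSums(ht$counts)),
                 unname(as.integer(table(meta$population)[rownames(ht$counts)])))
    expect_false(anyDuplicated(ht$haplotype_seqs) > 0)
  }
})

test_that("sites with any missing call are dropped wholesale", {
  calls <- matrix(c("A", "A", "G",
                    "N", "A", "A",
                    "G", "G", "G",
                    "A", "N", "A",
                    "T", "T", "T"), nrow = 3)
  g <- uniparental:::new_genotype_table(c("s1", "s2", "s3"),
                                        c(10L, 20L, 30L, 40L, 50L), calls)
  out <- drop_missing_sites(g)
  expect_identical(out$site_positions, c(10L, 30L, 50L))
  expect_identical(attr(out, "removed_sites"), c(20L, 40L))
  expect_false(any(out$calls == "N"))

  # no missing anywhere: identity
  clean <- uniparental:::new_genotype_table(c("s1", "s2"), c(1L, 2L),
                                            matrix(c("A", "G", "T", "T"), 2))
  expect_identical(drop_missing_sites(clean)$calls, clean$calls)

  # all sites missing: empty result with warning
  allmiss <- uniparental:::new_genotype_table(c("s1", "s2"), c(1L, 2L),
                                              matrix("N", 2, 2))
  expect_warning(empty <- drop_missing_sites(allmiss), "no sites")
  expect_equal(length(empty$site_positions), 0L)
})

test_that("genotype haplotypes concatenate alleles with the same collapsing semantics", {
  calls <- matrix(c("A", "A", "A", "C",
                    "G", "G", "T", "G"), nrow = 4)
  g <- uniparental:::new_genotype_table(paste0("s", 1:4), c(1L, 2L), calls)
  ht <- genotype_haplotypes(g, meta_df(paste0("s", 1:4), rep("P", 4)))
  expect_equal(length(ht$haplotype_ids), 3L)
  expect_equal(sort(unname(ht$counts["P", ]), decreasing = TRUE), c(2L, 1L, 1L))

  # degenerate and invalid inputs
  empty <- uniparental:::new_genotype_table(paste0("s", 1:2), integer(0),
                                            matrix(character(0), 2, 0))
  expect_error(genotype_haplotypes(empty, meta_df(paste0("s", 1:2), c("P", "P"))),
               "no sites")
  withmiss <- uniparental:::new_genotype_table(paste0("s", 1:2), 1L,
                                               matrix(c("A", "N"), 2, 1))
  expect_error(genotype_haplotypes(withmiss, meta_df(paste0("s", 1:2), c("P", "P"))),
               "drop_missing_sites")
})
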