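test_that("two-group AMOVA PhiST equals the explicit sums-of-squares oracle", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    n1 <- sample(2:(n - 2), 1)
    groups <- c(rep("A", n1), rep("B", n - n1))
    mat <- matrix(sample(c("A", "T", "G"), n * 15, replace = TRUE), n, 15)
    d <- pairwise_differences(mat)
    expect_equal(uniparental:::amova_phist(d, groups), oracle_phist(d, groups),
                 tolerance = 1e-10)
  }
})

test_that("PhiST hits its fixed-difference and no-structure anchors", {
  # A fixed for one haplotype, B fixed for another: all variance among groups
  mat <- rbind(matrix("A", 5, 10), matrix("T", 5, 10))
  rownames(mat) <- paste0("s", 1:10)
  meta <- meta_df(rownames(mat), rep(c("A", "B"), each = 5))
  pr <- pairwise_phist(mat, meta, n_permutations = 199, seed = 1)
  expect_equal(pr$phi_st["A", "B"], 1)
  # only the 2/252 label shuffles recreating the split reach phi = 1
  expect_lt(pr$p_values["A", "B"], 0.05)

  # two samples with identical haplotype composition: no among-group variance
  mat2 <- rbind(matrix("A", 3, 10), matrix("T", 3, 10),
                matrix("A", 3, 10), matrix("T", 3, 10))
  rownames(mat2) <- paste0("s", 1:12)
  meta2 <- meta_df(rownames(mat2), rep(c("P", "P", "Q", "Q"), each = 3))
  pr2 <- pairwise_phist(mat2, meta2, n_permutations = 199, seed = 2)
  expect_lt(pr2$phi_st["P", "Q"], 0.05)  # ~0, may be slightly negative
  expect_gt(pr2$p_values["P", "Q"], 0.05)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(3)
  aln <- random_aln(12, 40, alphabet = c("A", "C"))
  meta <- meta_df(rownames(aln$seqs), rep(c("X", "Y", "Z"), each = 4))
  a <- pairwise_phist(aln, meta, n_permutations = 49, seed = 42)
  b <- pairwise_phist(aln, meta, n_permutations = 49, seed = 42)
  expect_identical(a$p_values, b$p_values)
  expect_true(isSymmetric(a$phi_st))
  expect_true(all(diag(a$phi_st) == 0))
  expect_true(all(is.na(diag(a$p_values))))
})

test_that("populations below the minimum size are skipped with a warning", {
  mat <- rbind(matrix("A", 2, 5), matrix("T", 2, 5), matrix("G", 1, 5))
  rownames(mat) <- paste0("s", 1:5)
  meta <- meta_df(rownames(mat), c("A", "A", "B", "B", "tiny"))
  expect_warning(pr <- pairwise_phist(mat, meta, n_permutations = 19, seed = 1),
                 "n < 2 skipped.*tiny")
  expect_true(is.na(pr$phi_st["A", "tiny"]))
  expect_false(is.na(pr$phi_st["A", "B"]))
  expect_error(pairwise_phist(mat, meta, n_permutations = 0), ">= 1")
})

test_that("phist_for_nmds clamps negatives and lifts off-diagonal zeros", {
  m <- matrix(c(0, -0.02, 0, -0.02, 0, 0.3, 0, 0.3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- phist_for_nmds(m)
  expect_equal(diag(d), stats::setNames(c(0, 0, 0), letters[1:3]))
  expect_equal(d["a", "b"], 1e-6)   # negative clamped to 0 then offset
  expect_equal(d["a", "c"], 1e-6)   # exact zero offset
  expect_equal(d["b", "c"], 0.3)
})

test_that("NMDS recovers a perfectly embeddable configuration with zero stress", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:4)
  ord <- nmds(d, k = 2)
  expect_lt(ord$stress, 1e-6)
  expect_equal(dim(ord$points), c(4L, 2L))
})

test_that("NMDS stress is non-increasing in the number of dimensions", {
  set.seed(17)
  m <- matrix(runif(36, 0.2, 1), 6, 6)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("p", 1:6)
  stresses <- vapply(1:4, function(k) nmds(d, k = k, n_restarts = 10)$stress,
                     numeric(1))
  expect_true(all(diff(stresses) <= 1e-8))
})

test_that("the deterministic NMDS start is competitive with random restarts", {
  set.seed(23)
  m <- matrix(runif(25, 0.2, 1), 5, 5)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("p", 1:5)
  base <- nmds(d, k = 2)
  multi <- nmds(d, k = 2, n_restarts = 25, seed = 99)
  expect_lte(multi$stress, base$stress + 1e-8)
  expect_lt(base$stress - multi$stress, 1e-3)
})

test_that("NMDS input validation rejects unusable dissimilarities", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(nmds(d), "symmetric")
  d2 <- matrix(c(0, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nmds(d2), "off-diagonal zero")
  d3 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nmds(d3), "negative")
})

test_that("CA structural identities hold", {
  # independence (rank-1) table: zero inertia
  indep <- outer(c(10, 20, 30), c(1, 2, 3))
  dimnames(indep) <- list(paste0("r", 1:3), paste0("c", 1:3))
  expect_lt(correspondence_analysis(indep)$total_inertia, 1e-12)

  # 2x2 diagonal table: chi^2 = n, inertia exactly 1
  diag2 <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(correspondence_analysis(diag2)$total_inertia, 1, tolerance = 1e-12)

  # Parseval: axis inertias sum to chi^2 / n
  set.seed(41)
  tab <- matrix(rpois(24, 6) + 1, 4, 6,
                dimnames = list(paste0("p", 1:4), paste0("h", 1:6)))
  ca <- correspondence_analysis(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab)$statistic)
  expect_equal(sum(ca$inertia_per_axis), unname(chi2) / sum(tab), tolerance = 1e-9)
  expect_equal(ca$total_inertia, sum(ca$inertia_per_axis), tolerance = 1e-12)

  # zero rows / columns are named in the error
  tab0 <- tab; tab0[2, ] <- 0
  expect_error(correspondence_analysis(tab0), "all-zero row.*p2")
  tab0 <- tab; tab0[, 3] <- 0
  expect_error(correspondence_analysis(tab0), "all-zero column.*h3")
})

test_that("CA agrees with vegan's eigendecomposition", {
  skip_if_not_installed("vegan")
  set.seed(43)
  tab <- matrix(rpois(30, 5) + 1, 5, 6,
                dimnames = list(paste0("p", 1:5), paste0("h", 1:6)))
  ca <- correspondence_analysis(tab)
  vg <- vegan::cca(tab)
  expect_equal(unname(ca$inertia_per_axis[seq_along(vg$CA$eig)]),
               unname(vg$CA$eig), tolerance = 1e-9)
})

test_that("CA depends only on the correspondence matrix and row profiles", {
  set.seed(47)
  tab <- matrix(rpois(20, 8) + 1, 4, 5,
                dimnames = list(paste0("p", 1:4), paste0("h", 1:5)))
  # uniform scaling of the whole table changes nothing
  a <- correspondence_analysis(tab)
  b <- correspondence_analysis(tab * 17)
  expect_equal(a$points, b$points, tolerance = 1e-9)
  expect_equal(a$inertia_per_axis, b$inertia_per_axis, tolerance = 1e-9)

  # distributional equivalence: two rows with proportional profiles merge
  # into one row at the same position, leaving the other rows untouched
  tab2 <- rbind(tab, p5 = 3 * tab["p4", ])
  merged <- rbind(tab[1:3, ], p45 = tab["p4", ] + tab2["p5", ])
  ca_split <- correspondence_analysis(tab2)
  ca_merge <- correspondence_analysis(merged)
  sgn <- sign(diag(crossprod(ca_split$points[1:3, , drop = FALSE],
                             ca_merge$points[1:3, , drop = FALSE])))
  aligned <- sweep(ca_merge$points, 2, sgn, "*")
  expect_equal(unname(ca_split$points[1:3, ]), unname(aligned[1:3, ]),
               tolerance = 1e-9)
  expect_equal(unname(ca_split$points["p4", ]), unname(aligned["p45", ]),
               tolerance = 1e-9)
  expect_equal(ca_split$total_inertia, ca_merge$total_inertia, tolerance = 1e-9)
})

test_that("frequency-only CA input is rescaled with a flag", {
  freq <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  ca <- correspondence_analysis(freq)
  expect_true(attr(ca, "frequencies_rescaled"))
})

test_that("significance marks flag non-significant pairs with a cross", {
  pr <- structure(list(
    populations = c("A", "B", "C"),
    phi_st = matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    p_values = matrix(c(NA, 0.2, 0.01, 0.2, NA, 0.04, 0.01, 0.04, NA), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    n_permutations = 99L, seed = 1L), class = "phist_result")
  marks <- phist_significance_marks(pr)
  expect_equal(marks["A", "B"], "x")
  expect_equal(marks["A", "C"], "")
  expect_true(is.na(marks["A", "A"]))
})
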