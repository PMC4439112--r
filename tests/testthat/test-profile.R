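test_that("gene ranking is deterministic with lexicographic ties", {
  expect_identical(rankGenes(c(g1 = 3, g2 = 1, g3 = 2))$gene_id,
                   c("g1", "g3", "g2"))
  expect_identical(rankGenes(c(b = 1, c = 1, a = 1))$gene_id,
                   c("a", "b", "c"))
  expect_identical(rankGenes(c(only = 5))$gene_id, "only")
  expect_identical(rankGenes(c(g1 = 3, g2 = 1), "ascending")$gene_id,
                   c("g2", "g1"))
  expect_error(rankGenes(c(g1 = NaN)), "finite")
})

test_that("binned frequencies are relative to the background fraction", {
  ids <- paste0("g", sprintf("%03d", 1:500))
  hasMatch <- setNames(c(rep(TRUE, 100), rep(FALSE, 400)), ids)
  ranked <- rankGenes(setNames(500:1, ids))
  bp <- binnedSeedFrequency(ranked, hasMatch, binSize = 250)
  # top bin: (100/250) / (100/500) = 2
  expect_equal(bp$relative_frequency[1], 2)
  expect_equal(bp$relative_frequency[2], 0)
  expect_identical(bp$bin_size, c(250L, 250L))
  expect_false(any(bp$partial))
  expect_error(binnedSeedFrequency(ranked, setNames(rep(FALSE, 500), ids)),
               "background")
})

test_that("the final partial bin is retained and flagged", {
  ids <- paste0("g", sprintf("%03d", 1:600))
  hasMatch <- setNames(rep(c(TRUE, FALSE), 300), ids)
  bp <- binnedSeedFrequency(ids, hasMatch, binSize = 250)
  expect_identical(bp$bin_size, c(250L, 250L, 100L))
  expect_identical(bp$partial, c(FALSE, FALSE, TRUE))
})

test_that("bin match fractions conserve the ranked-set fraction", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(300:900, 1)
    ids <- paste0("g", seq_len(n))
    hasMatch <- setNames(runif(n) < 0.3, ids)
    ranked <- rankGenes(setNames(rnorm(n), ids))
    bp <- binnedSeedFrequency(ranked, hasMatch, binSize = 250)
    expect_equal(sum(bp$bin_size), n)
    expect_equal(sum(bp$n_match) / n, mean(hasMatch))
    # weighted mean of bin fractions equals the overall fraction
    expect_equal(weighted.mean(bp$n_match / bp$bin_size, bp$bin_size),
                 mean(hasMatch))
  }
})

test_that("random rankings give top-bin relative frequency near 1", {
  set.seed(32)
  ids <- paste0("g", 1:1000)
  hasMatch <- setNames(c(rep(TRUE, 100), rep(FALSE, 900)), ids)
  top <- replicate(300, {
    ranked <- sample(ids)
    binnedSeedFrequency(ranked, hasMatch, 250)$relative_frequency[1]
  })
  expect_equal(mean(top), 1, tolerance = 0.1)
})

test_that("region flags and proportions follow the two counting modes", {
  matches <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    region = c("CDS", "UTR3", "CDS", "UTR3"),
    position = c(10L, 50L, 12L, 60L), kmer = "TTCCGTT",
    spans_boundary = FALSE)
  universe <- paste0("g", 1:4)
  flags <- regionFlags(matches, universe)
  expect_identical(flags$CDS, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(flags$UTR3, c(TRUE, FALSE, TRUE, FALSE))
  inc <- regionProportions(flags, "inclusive")
  expect_equal(inc$proportion[inc$category == "CDS"], 2 / 4)
  expect_equal(inc$proportion[inc$category == "UTR3"], 2 / 4)
  exc <- regionProportions(flags, "exclusive")
  # g1 has sites in two regions: counted in no single-region category
  expect_equal(exc$n_genes[exc$category == "CDS"], 1L)
  expect_equal(exc$n_genes[exc$category == "UTR3"], 1L)
  expect_equal(exc$n_genes[exc$category == "multiple"], 1L)
  expect_equal(exc$n_genes[exc$category == "none"], 1L)
  # exclusive accounting partitions the universe
  expect_equal(sum(exc$n_genes), length(universe))
  expect_error(regionFlags(matches, c("g1", "g2")), "absent")
})

test_that("empty match lists give all-zero proportions", {
  empty <- data.frame(gene_id = character(0), region = character(0),
                      position = integer(0), kmer = character(0),
                      spans_boundary = logical(0))
  flags <- regionFlags(empty, paste0("g", 1:3))
  inc <- regionProportions(flags, "inclusive")
  expect_equal(inc$proportion[inc$category %in% c("UTR5", "CDS", "UTR3")],
               rep(0, 3))
})

test_that("ecdf points are a right-continuous step function ending at 1", {
  p <- ecdfPoints(c(1, 2, 3))
  expect_equal(p$cumulative_fraction, c(1, 2, 3) / 3)
  dup <- ecdfPoints(c(5, 5, 7))
  expect_equal(dup$cumulative_fraction, c(2 / 3, 1))  # double step
  expect_equal(ecdfPoints(4)$cumulative_fraction, 1)
  r <- ecdfPoints(rnorm(100))
  expect_true(all(diff(r$cumulative_fraction) > 0))
  expect_equal(max(r$cumulative_fraction), 1)
  expect_error(ecdfPoints(numeric(0)), "finite")
})

test_that("region group comparison detects a planted location effect", {
  # identical groups: t = 0, two-sided p = 1
  flags <- data.frame(gene_id = paste0("g", 1:6),
                      UTR5 = FALSE,
                      CDS = rep(c(TRUE, FALSE), each = 3),
                      UTR3 = rep(c(FALSE, TRUE), each = 3))
  stat <- setNames(rep(c(1, 2, 3), 2), flags$gene_id)
  same <- regionDistributionCompare(stat, flags, "CDS", "UTR3")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # Monte-Carlo power oracle: 0.5 log2-unit effect, sigma 0.5,
  # n = 500/group is detected essentially always
  set.seed(33)
  reject <- replicate(60, {
    a <- rnorm(500, 0.5, 0.5)
    b <- rnorm(500, 0.0, 0.5)
    welchTTest(a, b, "a_greater")$p < 0.05
  })
  expect_gte(mean(reject), 0.99)

  # the same effect planted through the region-comparison interface
  n <- 1000
  ids <- paste0("g", sprintf("%04d", 1:n))
  flags2 <- data.frame(gene_id = ids, UTR5 = FALSE,
                       CDS = c(rep(TRUE, 500), rep(FALSE, 500)),
                       UTR3 = c(rep(FALSE, 500), rep(TRUE, 500)))
  stat2 <- setNames(c(rnorm(500, 0.5, 0.5), rnorm(500, 0, 0.5)), ids)
  res <- regionDistributionCompare(stat2, flags2, "CDS", "UTR3",
                                   alternative = "a_greater")
  expect_lt(res$p, 0.05)
  expect_gt(res$meanA, res$meanB)
  expect_identical(c(res$nA, res$nB), c(500L, 500L))

  # degenerate tiny groups are handled, not an error
  flags3 <- data.frame(gene_id = paste0("g", 1:4), UTR5 = FALSE,
                       CDS = c(TRUE, TRUE, FALSE, FALSE),
                       UTR3 = c(FALSE, FALSE, TRUE, TRUE))
  stat3 <- setNames(c(1, 1, 2, 2), flags3$gene_id)
  deg <- regionDistributionCompare(stat3, flags3, "CDS", "UTR3")
  expect_true(deg$degenerate)
  expect_error(regionDistributionCompare(stat3[1:3], flags3, "CDS",
                                         "UTR3"),
               "insufficient")
})

test_that("exclusive mode drops multi-region genes from comparisons", {
  flags <- data.frame(gene_id = paste0("g", 1:6), UTR5 = FALSE,
                      CDS = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      UTR3 = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  stat <- setNames(as.numeric(1:6), flags$gene_id)
  exc <- regionDistributionCompare(stat, flags, "CDS", "UTR3")
  expect_identical(c(exc$nA, exc$nB), c(2L, 3L))   # g1 excluded
  inc <- regionDistributionCompare(stat, flags, "CDS", "UTR3",
                                   mode = "inclusive")
  expect_identical(c(inc$nA, inc$nB), c(3L, 4L))
})

test_that("tiling relative frequency is 1 when target = background", {
  set.seed(34)
  utr3 <- Biostrings::DNAStringSet(
    setNames(vapply(1:30, function(i) randomDna(200), character(1)),
             paste0("g", 1:30)))
  tw <- tilingWindows(mir191())
  prof <- suppressWarnings(
    tilingRelativeFrequency(tw, paste0("g", 1:30),
                            paste0("g", 1:30), utr3))
  present <- !is.na(prof$relative_frequency)
  expect_true(any(present))
  expect_equal(prof$relative_frequency[present],
               rep(1, sum(present)))
  expect_error(tilingRelativeFrequency(tw, character(0),
                                       paste0("g", 1:30), utr3),
               "empty")
})
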