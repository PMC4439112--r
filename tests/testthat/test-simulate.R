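smallConfig <- function(...) {
  args <- list(nGenes = 120L, utr5Length = 60, cdsLength = 200,
               utr3Length = 150, nTargets = 15L, rngSeed = 11L)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

test_that("simulation is reproducible for a fixed seed", {
  s1 <- simulateStudy(smallConfig())
  s2 <- simulateStudy(smallConfig())
  expect_identical(as.character(transcriptSeqs(s1$models)),
                   as.character(transcriptSeqs(s2$models)))
  expect_identical(abundances(s1$experiment), abundances(s2$experiment))
  expect_identical(s1$sites, s2$sites)
  s3 <- simulateStudy(smallConfig(rngSeed = 12L))
  expect_false(identical(as.character(transcriptSeqs(s1$models)),
                         as.character(transcriptSeqs(s3$models))))
})

test_that("transcriptome has the configured size and clean planting", {
  cfg <- smallConfig()
  sim <- simulateTranscriptome(cfg)
  expect_identical(length(sim$models), 120L)
  expect_identical(nrow(sim$sites), 15L)
  sd7 <- seedDefinition(mir191())
  ann <- annotateGeneMatches(sim$models, sd7)
  # every planted site rediscovered at its declared place and region
  key <- function(df) paste(df$gene_id, df$region, df$position)
  expect_setequal(key(ann), key(sim$sites))
  expect_true(all(sim$sites$region == "UTR3"))
  # non-target genes contain no seed match anywhere
  nonTargets <- setdiff(geneIds(sim$models), sim$sites$gene_id)
  expect_false(any(ann$gene_id %in% nonTargets))
})

test_that("sites can be planted in the CDS or mixed regions", {
  simCds <- simulateTranscriptome(smallConfig(plantRegion = "CDS"))
  ann <- annotateGeneMatches(simCds$models, seedDefinition(mir191()))
  expect_true(all(ann$region == "CDS"))
  simMix <- simulateTranscriptome(
    smallConfig(plantRegion = "mixed", plantWeights = c(1, 1, 1),
                nTargets = 40L))
  expect_gt(length(unique(simMix$sites$region)), 1L)
})

test_that("background sites appear in non-target genes when requested", {
  cfg <- smallConfig(backgroundSiteRate = 0.2)
  sim <- simulateTranscriptome(cfg)
  bg <- sim$sites[!sim$sites$is_true_target, ]
  expect_equal(nrow(bg), round(0.2 * (120 - 15)))
  ann <- annotateGeneMatches(sim$models, seedDefinition(mir191()))
  expect_true(all(bg$gene_id %in% ann$gene_id))
})

test_that("noise-free abundances recover planted folds exactly", {
  sim <- simulateStudy(smallConfig(replicateNoiseSd = 0))
  tab <- scoreTargets(sim$experiment)
  truthIds <- sim$truth$gene_id[sim$truth$is_true_target]
  expect_setequal(tab$gene_id[tab$is_target], truthIds)
  E <- setNames(tab$enrichment, tab$gene_id)
  R <- setNames(tab$repression, tab$gene_id)
  expect_equal(unname(E[truthIds]), rep(3, length(truthIds)),
               tolerance = 1e-12)
  expect_equal(unname(R[truthIds]), rep(2, length(truthIds)),
               tolerance = 1e-12)
  expect_equal(unname(tab$score[tab$is_target]),
               rep(2.5, length(truthIds)), tolerance = 1e-12)
  nonTargets <- setdiff(tab$gene_id, truthIds)
  expect_equal(unname(E[nonTargets]), rep(1, length(nonTargets)))
  expect_equal(unname(R[nonTargets]), rep(1, length(nonTargets)))
})

test_that("noisy recovery rates match an independent closed-form oracle", {
  # pipeline at reduced scale
  cfg <- simulationConfig(nGenes = 3000L, nTargets = 200L, rngSeed = 17L)
  sim <- simulateStudy(cfg)
  tab <- scoreTargets(sim$experiment)
  called <- tab$gene_id[tab$is_target]
  truthIds <- sim$truth$gene_id[sim$truth$is_true_target]
  precision <- mean(called %in% truthIds)
  recall <- mean(truthIds %in% called)

  # oracle: direct simulation of the four class means, no pipeline code
  set.seed(18)
  m <- 2e5
  classMean <- function() rowMeans(matrix(exp(rnorm(m * 3, 0, 0.25)),
                                          m, 3))
  et <- classMean(); ec <- classMean()
  rt <- classMean(); rc <- classMean()
  nullS <- ((rt / et) / (rc / ec) + ec / et) / 2
  tgtS <- (3 * (rt / et) / (rc / ec) + 2 * ec / et) / 2
  expFP <- (cfg@nGenes - cfg@nTargets) * mean(nullS >= 1.5)
  expTP <- cfg@nTargets * mean(tgtS >= 1.5)
  expect_equal(precision, expTP / (expTP + expFP), tolerance = 0.08)
  expect_equal(recall, mean(tgtS >= 1.5), tolerance = 0.03)
})

test_that("truth table carries expected folds and site annotations", {
  sim <- simulateStudy(smallConfig())
  tr <- sim$truth
  expect_identical(nrow(tr), 120L)
  expect_equal(tr$expected_E[tr$is_true_target], rep(3, 15))
  expect_equal(tr$expected_R[tr$is_true_target], rep(2, 15))
  expect_equal(tr$expected_E[!tr$is_true_target], rep(1, 105))
  expect_true(all(!is.na(tr$region[tr$is_true_target])))
  expect_true(all(is.na(tr$region[!tr$is_true_target])))
  # baselines respect the truncation
  expect_true(all(abundances(sim$experiment) >= 0))
})
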