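# Synthetic transcriptomes and RIP/expression abundance tables with
# planted targets, for parameter-recovery validation of the pipeline.

#' The miR-191 guide strand
#'
#' Convenience constructor for the mature miR-191 guide
#' (5'-CAACGGAAUCCCAAAAGCAGCUG-3'), the miRNA the profiling design
#' was built around; its default 7mer-m8 seed match k-mer is
#' `TTCCGTT`.
#'
#' @return a [MatureMiRNA-class] object.
#' @examples
#' seedDefinition(mir191())
#' @export
mir191 <- function() MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")

#' @describeIn SimulationConfig-class Construct a configuration;
#'   defaults are the validation study conditions (see class slots).
#' @param nGenes,utr5Length,cdsLength,utr3Length,gcContent,nTargets,plantRegion,plantWeights,enrichmentFold,repressionFold,baselineMeanLog,baselineSdLog,minBaseline,replicateNoiseSd,nReplicates,backgroundSiteRate,rngSeed
#'   see the corresponding slots.
#' @export
simulationConfig <- function(nGenes = 10000L, utr5Length = 200,
                             cdsLength = 1200, utr3Length = 800,
                             gcContent = 0.5, nTargets = 500L,
                             plantRegion = "UTR3",
                             plantWeights = c(0.05, 0.35, 0.60),
                             enrichmentFold = 3, repressionFold = 2,
                             baselineMeanLog = log(50),
                             baselineSdLog = 1, minBaseline = 2,
                             replicateNoiseSd = 0.25,
                             nReplicates = 3L,
                             backgroundSiteRate = 0, rngSeed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      utr5Length = utr5Length, cdsLength = cdsLength,
      utr3Length = utr3Length, gcContent = gcContent,
      nTargets = as.integer(nTargets), plantRegion = plantRegion,
      plantWeights = plantWeights, enrichmentFold = enrichmentFold,
      repressionFold = repressionFold,
      baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
      minBaseline = minBaseline, replicateNoiseSd = replicateNoiseSd,
      nReplicates = as.integer(nReplicates),
      backgroundSiteRate = backgroundSiteRate,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nGenes, " genes, ",
      object@nTargets, " true targets (", object@plantRegion,
      " sites)\n  folds E = ", object@enrichmentFold, ", R = ",
      object@repressionFold, "; replicate noise sd = ",
      object@replicateNoiseSd, "; ", object@nReplicates,
      " replicates/class; seed = ", object@rngSeed, "\n", sep = "")
})

# iid random DNA of the given lengths at the configured GC content,
# returned as a character vector (one long draw, then split).
randomSequences <- function(lengths, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  letters <- sample(c("A", "C", "G", "T"), sum(lengths),
                    replace = TRUE, prob = p)
  big <- paste(letters, collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1L, ends)
}

#' Simulate a transcriptome with planted seed sites
#'
#' Generates random transcript sequences at the configured GC content,
#' partitioned into 5'UTR/CDS/3'UTR by Poisson-length regions. A
#' random subset of `nTargets` genes receives exactly one copy of the
#' seed match k-mer at a uniformly chosen position within the
#' configured plant region; all other sequence is guaranteed free of
#' the k-mer (rejection sampling), so seed-frequency gradients have a
#' clean expected signal. `backgroundSiteRate > 0` re-introduces
#' chance sites into that fraction of non-target genes.
#'
#' @param config a [SimulationConfig-class].
#' @param mirna the miRNA whose seed is planted; default [mir191()].
#' @param seed seed definition; default 7mer-m8 of `mirna`.
#' @return a list with elements `models` ([TranscriptModels-class])
#'   and `sites` (data.frame `gene_id`, `is_true_target`, `region`,
#'   `position`), reproducible for a fixed `rngSeed`.
#' @export
simulateTranscriptome <- function(config, mirna = mir191(),
                                  seed = seedDefinition(mirna)) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@rngSeed)
  n <- config@nGenes
  k <- seed@k
  kmer <- as.character(seed@matchKmer)

  u5 <- rpois(n, config@utr5Length)
  cds <- pmax(1L, rpois(n, config@cdsLength))
  u3 <- rpois(n, config@utr3Length)

  ids <- sprintf("gene%05d", seq_len(n))
  targetIdx <- sort(sample.int(n, config@nTargets))
  nonTargetIdx <- setdiff(seq_len(n), targetIdx)
  nBackground <- round(config@backgroundSiteRate * length(nonTargetIdx))
  backgroundIdx <- if (nBackground > 0)
    sort(sample(nonTargetIdx, nBackground)) else integer(0)

  pickRegion <- function(idx) {
    if (config@plantRegion != "mixed")
      return(rep(config@plantRegion, length(idx)))
    sample(c("UTR5", "CDS", "UTR3"), length(idx), replace = TRUE,
           prob = config@plantWeights)
  }
  plantIdx <- c(targetIdx, backgroundIdx)
  plantRegion <- c(pickRegion(targetIdx), pickRegion(backgroundIdx))

  # widen planted regions that are too short for the k-mer
  for (j in seq_along(plantIdx)) {
    i <- plantIdx[j]
    switch(plantRegion[j],
           UTR5 = { u5[i] <- max(u5[i], k) },
           CDS  = { cds[i] <- max(cds[i], k) },
           UTR3 = { u3[i] <- max(u3[i], k) })
  }
  total <- u5 + cds + u3

  # seed-free background sequence everywhere
  seqs <- randomSequences(total, config@gcContent)
  for (iter in seq_len(100L)) {
    bad <- which(grepl(kmer, seqs, fixed = TRUE))
    if (!length(bad)) break
    seqs[bad] <- randomSequences(total[bad], config@gcContent)
    if (iter == 100L)
      stop("could not generate seed-free sequence; shorten transcripts ",
           "or the k-mer", call. = FALSE)
  }

  regionBounds <- function(i, region)
    switch(region,
           UTR5 = c(1L, u5[i]),
           CDS  = c(u5[i] + 1L, u5[i] + cds[i]),
           UTR3 = c(u5[i] + cds[i] + 1L, total[i]))

  position <- integer(length(plantIdx))
  for (j in seq_along(plantIdx)) {
    i <- plantIdx[j]
    b <- regionBounds(i, plantRegion[j])
    planted <- FALSE
    for (try in seq_len(50L)) {
      pos <- b[1L] + sample.int(b[2L] - b[1L] - k + 2L, 1L) - 1L
      s2 <- seqs[i]
      substr(s2, pos, pos + k - 1L) <- kmer
      # insertion at a junction can create an extra overlapping copy;
      # accept only a single occurrence
      if (length(scanSequence(s2, kmer)) == 1L) {
        seqs[i] <- s2
        position[j] <- pos
        planted <- TRUE
        break
      }
    }
    if (!planted)
      stop("could not plant a unique seed site in gene ", ids[i],
           " (", plantRegion[j], " region too constrained)",
           call. = FALSE)
  }

  models <- TranscriptModels(
    stats::setNames(seqs, ids),
    cdsStart = u5 + 1L, cdsEnd = u5 + cds)
  sites <- data.frame(
    gene_id = ids[plantIdx],
    is_true_target = plantIdx %in% targetIdx,
    region = plantRegion,
    position = position,
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$gene_id), , drop = FALSE]
  rownames(sites) <- NULL
  list(models = models, sites = sites)
}

#' Simulate paired RIP/expression abundance tables
#'
#' Draws a log-normal baseline abundance per gene (left-truncated at
#' `minBaseline` to stay in the detected regime) and sets the four
#' library-class expectations: non-targets have all classes at
#' baseline; true targets have expression/treatment knocked down by
#' `repressionFold` and a RIP/treatment level such that the
#' normalized RISC-association ratio rises by `enrichmentFold` (the
#' RIP library samples the repressed transcript pool, so its raw
#' expectation is `baseline * enrichmentFold / repressionFold`).
#' Every replicate multiplies its class expectation by an independent
#' log-normal factor `exp(N(0, replicateNoiseSd^2))`.
#'
#' @param config a [SimulationConfig-class].
#' @param models transcript models from [simulateTranscriptome()].
#' @param sites planted-site table from [simulateTranscriptome()].
#' @return a list with `experiment` (a [RipExperiment-class]) and
#'   `truth` (data.frame `gene_id`, `is_true_target`, `region`,
#'   `position`, `expected_E`, `expected_R`).
#' @export
simulateAbundances <- function(config, models, sites) {
  stopifnot(is(config, "SimulationConfig"), is(models, "TranscriptModels"))
  set.seed(config@rngSeed + 1L)
  ids <- geneIds(models)
  n <- length(ids)
  baseline <- rlnorm(n, config@baselineMeanLog, config@baselineSdLog)
  for (iter in seq_len(1000L)) {
    low <- which(baseline < config@minBaseline)
    if (!length(low)) break
    baseline[low] <- rlnorm(length(low), config@baselineMeanLog,
                            config@baselineSdLog)
  }
  isTarget <- ids %in% sites$gene_id[sites$is_true_target]

  expectation <- list(
    expr_trt = baseline / ifelse(isTarget, config@repressionFold, 1),
    expr_ctl = baseline,
    rip_trt  = baseline * ifelse(isTarget, config@enrichmentFold /
                                            config@repressionFold, 1),
    rip_ctl  = baseline)
  classMeta <- data.frame(
    class = names(expectation),
    assay = c("expression", "expression", "rip", "rip"),
    condition = c("treatment", "control", "treatment", "control"),
    stringsAsFactors = FALSE)

  cols <- list()
  design <- list()
  for (ci in seq_len(nrow(classMeta))) {
    for (r in seq_len(config@nReplicates)) {
      noise <- exp(rnorm(n, 0, config@replicateNoiseSd))
      sid <- paste(classMeta$class[ci], r, sep = "_")
      cols[[sid]] <- expectation[[classMeta$class[ci]]] * noise
      design[[sid]] <- data.frame(sample_id = sid,
                                  assay = classMeta$assay[ci],
                                  condition = classMeta$condition[ci],
                                  replicate = r,
                                  stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- ids
  experiment <- RipExperiment(mat, do.call(rbind, design))

  siteAt <- match(ids, sites$gene_id)
  truth <- data.frame(
    gene_id = ids,
    is_true_target = isTarget,
    region = ifelse(is.na(siteAt), NA_character_, sites$region[siteAt]),
    position = ifelse(is.na(siteAt), NA_integer_, sites$position[siteAt]),
    expected_E = ifelse(isTarget, config@enrichmentFold, 1),
    expected_R = ifelse(isTarget, config@repressionFold, 1),
    stringsAsFactors = FALSE)
  list(experiment = experiment, truth = truth)
}

#' Simulate a complete profiling study
#'
#' Runs [simulateTranscriptome()] and [simulateAbundances()] together.
#'
#' @inheritParams simulateTranscriptome
#' @return a list with `models`, `sites`, `experiment` and `truth`.
#' @examples
#' sim <- simulateStudy(simulationConfig(nGenes = 60, nTargets = 6,
#'                                       rngSeed = 7))
#' table(scoreTargets(sim$experiment)$is_target)
#' @export
simulateStudy <- function(config, mirna = mir191(),
                          seed = seedDefinition(mirna)) {
  tx <- simulateTranscriptome(config, mirna, seed)
  ab <- simulateAbundances(config, tx$models, tx$sites)
  c(tx, ab)
}
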