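# Readers and writers for the interchange formats (transcript FASTA,
# region/abundance/design TSVs, result tables) and the end-to-end
# pipeline runner.
#
# All tables are tab-separated with a header row, UTF-8, '.' decimal.
# Numbers are serialized with the fewest significant digits that
# round-trip the double exactly, so outputs are byte-deterministic
# and reader/writer pairs are lossless.

fmtNum <- function(x) {
  if (is.integer(x)) return(format(x, trim = TRUE, scientific = FALSE))
  out <- sprintf("%.15g", x)
  for (digits in c(16L, 17L)) {
    bad <- which(is.finite(x) & as.numeric(out) != x)
    if (!length(bad)) break
    out[bad] <- sprintf(paste0("%.", digits, "g"), x[bad])
  }
  out[is.na(x)] <- "NA"
  out
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, no quoting; numeric columns serialized
#' losslessly (shortest round-tripping representation), so identical
#' tables produce byte-identical files.
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x))
    if (is.double(x[[j]]) || is.integer(x[[j]])) x[[j]] <- fmtNum(x[[j]])
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

readTsvChecked <- function(path, required) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

requireNumericColumn <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad))
      stop(path, ": non-numeric value '", v[bad[1L]], "' in column '",
           col, "', line ", bad[1L] + 1L, call. = FALSE)
    num
  } else as.numeric(v)
}

#' Read and write transcript sequences as FASTA
#'
#' Standard FASTA, one record per gene; the first whitespace-delimited
#' header token is the gene id. Duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @param x a [TranscriptModels-class] or named
#'   [Biostrings::DNAStringSet] (for writing).
#' @return `readTranscriptsFasta()`: a named `DNAStringSet`.
#' @name fastaIO
NULL

#' @rdname fastaIO
#' @export
readTranscriptsFasta <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop(path, ": duplicate gene id '", dup[1L], "'", call. = FALSE)
  seqs
}

#' @rdname fastaIO
#' @export
writeTranscriptsFasta <- function(x, path) {
  seqs <- if (is(x, "TranscriptModels")) transcriptSeqs(x) else x
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read and write CDS region tables
#'
#' TSV with header `gene_id  cds_start  cds_end`, coordinates 1-based
#' inclusive on the transcript.
#'
#' @param path TSV file path.
#' @param models a [TranscriptModels-class] (for writing).
#' @return `readRegionTable()`: a data.frame with those three columns.
#' @name regionIO
NULL

#' @rdname regionIO
#' @export
readRegionTable <- function(path) {
  df <- readTsvChecked(path, c("gene_id", "cds_start", "cds_end"))
  df$cds_start <- as.integer(requireNumericColumn(df, "cds_start", path))
  df$cds_end <- as.integer(requireNumericColumn(df, "cds_end", path))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop(path, ": duplicate gene id '", dup[1L], "'", call. = FALSE)
  df
}

#' @rdname regionIO
#' @export
writeRegionTable <- function(models, path) {
  writeTsv(data.frame(gene_id = geneIds(models),
                      cds_start = cdsStart(models),
                      cds_end = cdsEnd(models),
                      stringsAsFactors = FALSE), path)
}

#' Assemble transcript models from FASTA plus region TSV
#'
#' Joins sequences to CDS coordinates by gene id; every sequence must
#' have coordinates and vice versa, and coordinates must fit the
#' transcript (violations name the offending gene).
#'
#' @param fastaPath transcript FASTA path.
#' @param regionPath region TSV path.
#' @return a [TranscriptModels-class] object.
#' @export
readTranscriptModels <- function(fastaPath, regionPath) {
  seqs <- readTranscriptsFasta(fastaPath)
  reg <- readRegionTable(regionPath)
  missSeq <- setdiff(reg$gene_id, names(seqs))
  missReg <- setdiff(names(seqs), reg$gene_id)
  if (length(missSeq))
    stop("gene(s) in region table without FASTA record: ",
         paste(utils::head(missSeq, 3L), collapse = ", "), call. = FALSE)
  if (length(missReg))
    stop("gene(s) in FASTA without region entry: ",
         paste(utils::head(missReg, 3L), collapse = ", "), call. = FALSE)
  at <- match(names(seqs), reg$gene_id)
  TranscriptModels(seqs, cdsStart = reg$cds_start[at],
                   cdsEnd = reg$cds_end[at])
}

#' Read and write gene-by-sample abundance tables
#'
#' TSV with header `gene_id` followed by one column per sample.
#' Values must be numeric and nonnegative; duplicate gene ids are an
#' error.
#'
#' @param path TSV file path.
#' @param x a numeric matrix with gene rownames, or a
#'   [RipExperiment-class] (for writing).
#' @return `readAbundanceTable()`: numeric matrix, rows = genes.
#' @name abundanceIO
NULL

#' @rdname abundanceIO
#' @export
readAbundanceTable <- function(path) {
  df <- readTsvChecked(path, "gene_id")
  if (colnames(df)[1L] != "gene_id")
    stop(path, ": first column must be 'gene_id'", call. = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop(path, ": duplicate gene id '", dup[1L], "'", call. = FALSE)
  sampleCols <- colnames(df)[-1L]
  if (!length(sampleCols))
    stop(path, ": no sample columns", call. = FALSE)
  mat <- vapply(sampleCols, function(cn)
    requireNumericColumn(df, cn, path), numeric(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(df$gene_id, sampleCols))
  if (any(mat < 0, na.rm = TRUE))
    stop(path, ": negative abundance value", call. = FALSE)
  mat
}

#' @rdname abundanceIO
#' @export
writeAbundanceTable <- function(x, path) {
  mat <- if (is(x, "RipExperiment")) abundances(x) else as.matrix(x)
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' Read and write sample design sheets
#'
#' TSV with header `sample_id  assay  condition  replicate`; `assay`
#' is `expression` or `rip`, `condition` is `treatment` or `control`.
#'
#' @param path TSV file path.
#' @param x a design data.frame or a [RipExperiment-class] (for
#'   writing).
#' @return `readDesign()`: the design data.frame.
#' @name designIO
NULL

#' @rdname designIO
#' @export
readDesign <- function(path) {
  df <- readTsvChecked(path, c("sample_id", "assay", "condition",
                               "replicate"))
  badA <- which(!df$assay %in% c("expression", "rip"))
  if (length(badA))
    stop(path, ": invalid assay '", df$assay[badA[1L]], "', line ",
         badA[1L] + 1L, call. = FALSE)
  badC <- which(!df$condition %in% c("treatment", "control"))
  if (length(badC))
    stop(path, ": invalid condition '", df$condition[badC[1L]],
         "', line ", badC[1L] + 1L, call. = FALSE)
  df$replicate <- as.integer(requireNumericColumn(df, "replicate", path))
  df
}

#' @rdname designIO
#' @export
writeDesign <- function(x, path) {
  design <- if (is(x, "RipExperiment")) sampleDesign(x) else x
  writeTsv(design, path)
}

#' Read a profiling experiment from abundance + design TSVs
#'
#' @param abundancePath abundance table path (see [readAbundanceTable()]).
#' @param designPath design sheet path (see [readDesign()]).
#' @return a [RipExperiment-class] object.
#' @export
readRipExperiment <- function(abundancePath, designPath) {
  RipExperiment(readAbundanceTable(abundancePath), readDesign(designPath))
}

#' Write the simulated study to its interchange files
#'
#' Emits the exact inputs the pipeline readers consume -- transcript
#' FASTA, region TSV, abundance TSV, design TSV -- plus the
#' ground-truth table.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulatedStudy <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "transcripts.fasta"),
    regions = file.path(dir, "regions.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  writeTranscriptsFasta(sim$models, paths["fasta"])
  writeRegionTable(sim$models, paths["regions"])
  writeAbundanceTable(sim$experiment, paths["abundance"])
  writeDesign(sim$experiment, paths["design"])
  writeTsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Run the full target-profiling analysis
#'
#' End-to-end pipeline: derive the seed match k-mer, scan and
#' classify transcript matches, score genes (repression, RIP
#' enrichment, combined score, target call), profile seed frequency
#' over ranked bins, tabulate region proportions, compare
#' region-stratified log2 distributions, and run the guide-tiling
#' specificity scan. Analyses operate on the genes present in both
#' the experiment and the transcript models; any gene in only one is
#' dropped and accounted for in the run log.
#'
#' @param experiment a [RipExperiment-class].
#' @param models a [TranscriptModels-class].
#' @param mirna a [MatureMiRNA-class]; default [mir191()].
#' @param guideStart,k seed window on the guide (defaults 2 and 7:
#'   the 7mer-m8 site).
#' @param floor abundance floor, default 1.
#' @param threshold target-call score cutoff, default 1.5.
#' @param binSize ranked-bin size, default 250 genes.
#' @param mode region-group membership for distribution comparisons,
#'   `"exclusive"` (default) or `"inclusive"`.
#' @param tilingK tiling window length, default 6.
#' @param outDir optional directory; when given, all result tables
#'   are written there as TSVs together with a deterministic
#'   `run_log.txt`.
#' @return a list with elements `seed`, `matches`, `scores`, `flags`,
#'   `proportions` (inclusive and exclusive), `bins` (per ranking
#'   statistic), `comparisons`, `tiling` and `log` (character vector).
#' @examples
#' sim <- simulateStudy(simulationConfig(nGenes = 300, nTargets = 30,
#'                                       rngSeed = 3))
#' res <- runTargetProfile(sim$experiment, sim$models, binSize = 50)
#' res$bins$score[1, ]
#' @export
runTargetProfile <- function(experiment, models, mirna = mir191(),
                             guideStart = 2L, k = 7L, floor = 1,
                             threshold = 1.5, binSize = 250L,
                             mode = c("exclusive", "inclusive"),
                             tilingK = 6L, outDir = NULL) {
  mode <- match.arg(mode)
  seed <- seedDefinition(mirna, guideStart = guideStart, k = k)
  logLines <- c(
    paste0("ripTargets version ", as.character(packageVersion("ripTargets"))),
    paste0("miRNA ", mirnaName(mirna), "; seed guide positions ",
           guideStart, "-", guideStart + k - 1L, "; match k-mer ",
           matchKmer(seed)),
    paste0("config: floor=", floor, " threshold=", threshold,
           " bin_size=", binSize, " mode=", mode, " tiling_k=", tilingK))

  profiled <- rownames(experiment)
  modeled <- geneIds(models)
  universe <- intersect(profiled, modeled)
  nDropExpr <- length(setdiff(profiled, modeled))
  nDropModel <- length(setdiff(modeled, profiled))
  logLines <- c(logLines,
    paste0("universe: ", length(universe), " genes; dropped ",
           nDropExpr, " profiled without transcript model ",
           "(reason: no_model), ", nDropModel,
           " modeled without profile (reason: no_profile)"))

  matches <- annotateGeneMatches(models[universe], seed)
  scores <- scoreTargets(experiment[universe, ], floor = floor,
                         threshold = threshold)
  flags <- regionFlags(matches, universe)
  proportions <- list(inclusive = regionProportions(flags, "inclusive"),
                      exclusive = regionProportions(flags, "exclusive"))

  E <- stats::setNames(scores$enrichment, scores$gene_id)
  R <- stats::setNames(scores$repression, scores$gene_id)
  S <- stats::setNames(scores$score, scores$gene_id)
  hasUtr3 <- stats::setNames(flags$UTR3, flags$gene_id)

  bins <- list(
    enrichment = binnedSeedFrequency(rankGenes(E), hasUtr3, binSize),
    repression = binnedSeedFrequency(rankGenes(R), hasUtr3, binSize),
    score = binnedSeedFrequency(rankGenes(S), hasUtr3, binSize))

  comparisons <- list()
  for (statName in c("enrichment", "repression")) {
    stat <- if (statName == "enrichment") E else R
    subsets <- list(all = names(stat),
                    ge_1.5 = names(stat)[stat >= 1.5])
    for (subsetName in names(subsets)) {
      statSub <- stat[subsets[[subsetName]]]
      for (regB in c("UTR3", "UTR5")) {
        cmp <- tryCatch(
          regionDistributionCompare(log2(statSub), flags, "CDS", regB,
                                    mode = mode),
          error = function(e) NULL)
        if (is.null(cmp)) {
          logLines <- c(logLines,
            paste0("comparison skipped (insufficient group size): ",
                   statName, " ", subsetName, " CDS vs ", regB))
        } else {
          comparisons[[length(comparisons) + 1L]] <-
            cbind(data.frame(statistic = statName, subset = subsetName,
                             stringsAsFactors = FALSE), cmp)
        }
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else NULL

  targetIds <- scores$gene_id[scores$is_target]
  tiling <- NULL
  if (length(targetIds)) {
    tiling <- tilingRelativeFrequency(
      tilingWindows(mirna, k = tilingK), targetIds, universe,
      utr3Seqs(models[universe]))
  } else {
    logLines <- c(logLines, "tiling skipped: empty target set")
  }
  logLines <- c(logLines,
    paste0("targets called: ", length(targetIds), " of ",
           nrow(scores), " scored genes"))

  res <- list(seed = seed, matches = matches, scores = scores,
              flags = flags, proportions = proportions, bins = bins,
              comparisons = comparisons, tiling = tiling,
              log = logLines)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeTsv(matches, file.path(outDir, "seed_matches.tsv"))
    writeTsv(scores, file.path(outDir, "target_scores.tsv"))
    writeTsv(proportions$inclusive,
             file.path(outDir, "region_proportions_inclusive.tsv"))
    writeTsv(proportions$exclusive,
             file.path(outDir, "region_proportions_exclusive.tsv"))
    for (nm in names(bins))
      writeTsv(bins[[nm]],
               file.path(outDir, paste0("bins_", nm, ".tsv")))
    if (!is.null(comparisons))
      writeTsv(comparisons, file.path(outDir, "region_comparisons.tsv"))
    if (!is.null(tiling))
      writeTsv(tiling, file.path(outDir, "tiling_profile.tsv"))
    writeLines(logLines, file.path(outDir, "run_log.txt"))
  }
  res
}
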