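#' @import methods
#' @importFrom Biostrings DNAString RNAString DNAStringSet RNAStringSet
#'   reverseComplement matchPattern vmatchPattern vcountPattern
#'   readDNAStringSet writeXStringSet subseq width
#' @importClassesFrom Biostrings DNAString RNAString DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom stats rlnorm rnorm rpois runif pt ecdf cor sd var
#' @importFrom utils read.delim packageVersion
NULL

#' Mature miRNA guide strand
#'
#' Holds the guide-strand sequence of a mature miRNA, the strand loaded
#' into RISC whose complementarity determines target pairing. Input
#' sequences are normalized to the RNA alphabet (case-insensitive;
#' `T` is accepted and mapped to `U`).
#'
#' @slot name single character, e.g. `"miR-191"`.
#' @slot guide an [Biostrings::RNAString] written 5' to 3'.
#'
#' @examples
#' mir191 <- MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")
#' mir191
#' @aliases MatureMiRNA-class
#' @exportClass MatureMiRNA
setClass("MatureMiRNA",
  slots = c(name = "character", guide = "RNAString"))

setValidity("MatureMiRNA", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@guide) < 8L)
    return("guide sequence must be at least 8 nt")
  TRUE
})

#' Seed definition: the guide window and its transcript match k-mer
#'
#' A seed match is the perfect reverse complement, in DNA alphabet, of a
#' window of the guide. The default window is guide positions 2-8
#' (the canonical 7mer-m8 seed); `guideStart` and `k` make the 6-mer
#' (positions 2-7) and 8-mer variants available.
#'
#' @slot guideStart 1-based start of the window on the guide.
#' @slot k window length in nt.
#' @slot guideWindow the guide subsequence ([Biostrings::RNAString]).
#' @slot matchKmer the DNA reverse complement of the window, written
#'   5' to 3' ([Biostrings::DNAString]) -- the k-mer searched for in
#'   transcripts.
#'
#' @seealso [seedDefinition()]
#' @aliases SeedDefinition-class
#' @exportClass SeedDefinition
setClass("SeedDefinition",
  slots = c(guideStart = "integer", k = "integer",
            guideWindow = "RNAString", matchKmer = "DNAString"))

setValidity("SeedDefinition", function(object) {
  if (object@guideStart < 1L) return("'guideStart' must be >= 1")
  if (object@k < 1L) return("'k' must be >= 1")
  if (length(object@guideWindow) != object@k)
    return("guide window length must equal k")
  if (length(object@matchKmer) != object@k)
    return("match k-mer length must equal k")
  TRUE
})

#' Transcript models: sequences partitioned into 5'UTR, CDS and 3'UTR
#'
#' A set of mature (spliced) transcript sequences, one per gene, each
#' partitioned by 1-based inclusive CDS coordinates into
#' `5'UTR = [1, cdsStart - 1]`, `CDS = [cdsStart, cdsEnd]` and
#' `3'UTR = [cdsEnd + 1, length]`. Either UTR may be empty.
#'
#' @slot sequences a named [Biostrings::DNAStringSet], names are gene ids.
#' @slot cdsStart,cdsEnd integer vectors parallel to `sequences`.
#'
#' @seealso [TranscriptModels()], [utr3Seqs()], [annotateGeneMatches()]
#' @aliases TranscriptModels-class
#' @exportClass TranscriptModels
setClass("TranscriptModels",
  slots = c(sequences = "DNAStringSet", cdsStart = "integer",
            cdsEnd = "integer"))

setValidity("TranscriptModels", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    return("sequences must be named by gene id")
  if (anyDuplicated(ids))
    return(paste0("duplicate gene id: ", ids[duplicated(ids)][1L]))
  if (length(object@cdsStart) != n || length(object@cdsEnd) != n)
    return("cdsStart/cdsEnd must be parallel to sequences")
  w <- width(object@sequences)
  bad <- which(object@cdsStart < 1L | object@cdsEnd < object@cdsStart |
               object@cdsEnd > w)
  if (length(bad))
    return(paste0("invalid CDS coordinates for gene '", ids[bad[1L]],
                  "': cds_start=", object@cdsStart[bad[1L]],
                  ", cds_end=", object@cdsEnd[bad[1L]],
                  ", transcript length=", w[bad[1L]]))
  TRUE
})

#' Configuration of the synthetic study generator
#'
#' Parameters of the simulated transcriptome and of the paired
#' RIP/expression abundance tables with planted targets. Defaults are
#' the study conditions the pipeline is validated under: 10,000 genes,
#' 500 true targets with seed sites planted in the 3'UTR, three
#' replicates per library class, 3-fold RIP enrichment and 2-fold
#' expression knockdown on true targets, and log-normal replicate
#' noise with sigma = 0.25 on the natural-log scale.
#'
#' @slot nGenes number of genes.
#' @slot utr5Length,cdsLength,utr3Length mean region lengths (nt);
#'   per-gene lengths are Poisson draws around these means.
#' @slot gcContent GC fraction of the random sequence background.
#' @slot nTargets number of true target genes.
#' @slot plantRegion `"UTR3"`, `"CDS"`, `"UTR5"` or `"mixed"`.
#' @slot plantWeights mixture weights over (UTR5, CDS, UTR3) used when
#'   `plantRegion == "mixed"`.
#' @slot enrichmentFold multiplicative effect on RIP/treatment
#'   abundance of true targets (> 1).
#' @slot repressionFold multiplicative knockdown of
#'   expression/treatment abundance of true targets (> 1).
#' @slot baselineMeanLog,baselineSdLog natural-log mean and sd of the
#'   log-normal baseline abundance distribution.
#' @slot minBaseline lower truncation of baseline abundances
#'   (resampled below it); keeps simulated genes in the
#'   detected/expressed regime where ratios carry information under
#'   the abundance floor.
#' @slot replicateNoiseSd per-replicate log-normal noise sigma
#'   (natural log).
#' @slot nReplicates replicates per (assay, condition) class.
#' @slot backgroundSiteRate fraction of non-target genes that receive
#'   a chance seed site (default 0: non-targets are seed-free).
#' @slot rngSeed integer seed making the whole simulation reproducible.
#'
#' @seealso [simulationConfig()], [simulateStudy()]
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(nGenes = "integer", utr5Length = "numeric",
            cdsLength = "numeric", utr3Length = "numeric",
            gcContent = "numeric", nTargets = "integer",
            plantRegion = "character", plantWeights = "numeric",
            enrichmentFold = "numeric", repressionFold = "numeric",
            baselineMeanLog = "numeric", baselineSdLog = "numeric",
            minBaseline = "numeric", replicateNoiseSd = "numeric",
            nReplicates = "integer", backgroundSiteRate = "numeric",
            rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nGenes < 1L) return("nGenes must be >= 1")
  if (object@nTargets < 0L || object@nTargets > object@nGenes)
    return("nTargets must lie in [0, nGenes]")
  if (object@enrichmentFold <= 1 || object@repressionFold <= 1)
    return("enrichmentFold and repressionFold must be > 1")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    return("gcContent must lie in (0, 1)")
  if (object@replicateNoiseSd < 0 || object@baselineSdLog < 0)
    return("noise standard deviations must be >= 0")
  if (!object@plantRegion %in% c("UTR3", "CDS", "UTR5", "mixed"))
    return("plantRegion must be one of UTR3, CDS, UTR5, mixed")
  if (length(object@plantWeights) != 3L || any(object@plantWeights < 0) ||
      sum(object@plantWeights) <= 0)
    return("plantWeights must be 3 nonnegative weights (UTR5, CDS, UTR3)")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  if (object@backgroundSiteRate < 0 || object@backgroundSiteRate > 1)
    return("backgroundSiteRate must lie in [0, 1]")
  TRUE
})

#' RIP/expression profiling experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one
#' gene-by-sample abundance assay (FPKM-like, named `"abundance"`)
#' whose column annotation describes the two-by-two profiling design:
#' `assayType` (`expression` or `rip`), `condition` (`treatment` or
#' `control`) and `replicate`. All four (assayType, condition) classes
#' must be present with at least one replicate each and the
#' (assayType, condition, replicate) triples must be unique.
#'
#' @seealso [RipExperiment()], [scoreTargets()]
#' @aliases RipExperiment-class
#' @exportClass RipExperiment
setClass("RipExperiment", contains = "SummarizedExperiment")

setValidity("RipExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("assayType", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("colData must contain column(s): ",
                  paste(miss, collapse = ", ")))
  if (!all(cd$assayType %in% c("expression", "rip")))
    return("assayType must be 'expression' or 'rip'")
  if (!all(cd$condition %in% c("treatment", "control")))
    return("condition must be 'treatment' or 'control'")
  key <- paste(cd$assayType, cd$condition, cd$replicate)
  if (anyDuplicated(key))
    return(paste0("duplicate (assayType, condition, replicate) triple: ",
                  key[duplicated(key)][1L]))
  classes <- unique(paste(cd$assayType, cd$condition))
  needClasses <- c("expression treatment", "expression control",
                   "rip treatment", "rip control")
  missing <- setdiff(needClasses, classes)
  if (length(missing))
    return(paste0("design lacks library class(es): ",
                  paste(missing, collapse = "; ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("an assay named 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE))
    return("abundances must be nonnegative")
  TRUE
})
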