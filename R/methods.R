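# Constructors, accessors and show methods for the core classes.

normalizeSeq <- function(x, alphabet = c("RNA", "DNA"), what = "sequence") {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("'", what, "' must be a single non-empty string", call. = FALSE)
  s <- toupper(x)
  s <- if (alphabet == "RNA") chartr("T", "U", s) else chartr("U", "T", s)
  ok <- if (alphabet == "RNA") c("A", "C", "G", "U", "N")
        else c("A", "C", "G", "T", "N")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% ok)
  if (length(bad))
    stop("invalid ", alphabet, " character '", ch[bad[1L]],
         "' at position ", bad[1L], " in ", what, call. = FALSE)
  s
}

#' @describeIn MatureMiRNA-class Construct from a name and a guide
#'   sequence (RNA or DNA letters, case-insensitive).
#' @param name miRNA name.
#' @param sequence guide-strand sequence, 5' to 3'.
#' @export
MatureMiRNA <- function(name, sequence) {
  s <- normalizeSeq(sequence, "RNA", "guide sequence")
  if (grepl("N", s, fixed = TRUE))
    stop("guide sequence may not contain N", call. = FALSE)
  new("MatureMiRNA", name = name, guide = RNAString(s))
}

#' Accessors for core classes
#'
#' `guideSequence()` returns the guide strand as a character string;
#' `mirnaName()` the miRNA name; `matchKmer()` and `guideWindow()` the
#' two faces of a seed definition; `geneIds()`, `cdsStart()`,
#' `cdsEnd()` and `transcriptSeqs()` the components of a
#' [TranscriptModels-class] object.
#'
#' @param x the object.
#' @return character scalars/vectors, integer vectors, or a
#'   [Biostrings::DNAStringSet] for `transcriptSeqs()`.
#' @examples
#' mir <- MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")
#' guideSequence(mir)
#' matchKmer(seedDefinition(mir))
#' @name accessors
NULL

#' @rdname accessors
#' @export
guideSequence <- function(x) as.character(x@guide)

#' @rdname accessors
#' @export
mirnaName <- function(x) x@name

#' @export
setMethod("length", "MatureMiRNA", function(x) length(x@guide))

setMethod("show", "MatureMiRNA", function(object) {
  cat("MatureMiRNA ", object@name, " (", length(object@guide), " nt)\n",
      "  guide 5'-", as.character(object@guide), "-3'\n", sep = "")
})

#' @rdname accessors
#' @export
matchKmer <- function(x) as.character(x@matchKmer)

#' @rdname accessors
#' @export
guideWindow <- function(x) as.character(x@guideWindow)

setMethod("show", "SeedDefinition", function(object) {
  cat("SeedDefinition: guide positions ", object@guideStart, "-",
      object@guideStart + object@k - 1L, " (k = ", object@k, ")\n",
      "  guide window 5'-", as.character(object@guideWindow), "-3'\n",
      "  match k-mer  5'-", as.character(object@matchKmer), "-3' (DNA)\n",
      sep = "")
})

#' @describeIn TranscriptModels-class Construct from a named
#'   [Biostrings::DNAStringSet] (or named character vector) and CDS
#'   coordinates (1-based, inclusive).
#' @param sequences named DNAStringSet or character vector of
#'   transcript sequences.
#' @param cdsStart,cdsEnd integer vectors of CDS coordinates, parallel
#'   to `sequences`.
#' @export
TranscriptModels <- function(sequences, cdsStart, cdsEnd) {
  if (is.character(sequences)) {
    nm <- names(sequences)
    sequences <- DNAStringSet(vapply(
      seq_along(sequences),
      function(i) normalizeSeq(sequences[[i]], "DNA",
                               paste0("transcript '", nm[i], "'")),
      character(1L)))
    names(sequences) <- nm
  }
  new("TranscriptModels", sequences = sequences,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' @rdname accessors
#' @export
geneIds <- function(x) names(x@sequences)

#' @rdname accessors
#' @export
transcriptSeqs <- function(x) x@sequences

#' @rdname accessors
#' @export
cdsStart <- function(x) x@cdsStart

#' @rdname accessors
#' @export
cdsEnd <- function(x) x@cdsEnd

#' @export
setMethod("length", "TranscriptModels", function(x) length(x@sequences))

#' @export
setMethod("names", "TranscriptModels", function(x) names(x@sequences))

#' @export
setMethod("[", "TranscriptModels", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("TranscriptModels", sequences = x@sequences[i],
      cdsStart = x@cdsStart[i], cdsEnd = x@cdsEnd[i])
})

setMethod("show", "TranscriptModels", function(object) {
  w <- width(object@sequences)
  cat("TranscriptModels with ", length(object@sequences), " transcripts\n",
      "  lengths: ", min(w), "-", max(w), " nt (median ",
      stats::median(w), ")\n", sep = "")
})

#' Region sequences of transcript models
#'
#' Extract the 5'UTR, CDS or 3'UTR portion of every transcript as a
#' [Biostrings::DNAStringSet]; empty regions yield zero-width entries.
#'
#' @param x a [TranscriptModels-class] object.
#' @return a named `DNAStringSet` parallel to `geneIds(x)`.
#' @examples
#' tm <- TranscriptModels(c(g1 = "AAACCCGGGTTT"), cdsStart = 4, cdsEnd = 9)
#' utr3Seqs(tm)
#' @name regionSeqs
NULL

#' @rdname regionSeqs
#' @export
utr5Seqs <- function(x) subseq(x@sequences, start = 1L, end = x@cdsStart - 1L)

#' @rdname regionSeqs
#' @export
cdsSeqs <- function(x) subseq(x@sequences, start = x@cdsStart, end = x@cdsEnd)

#' @rdname regionSeqs
#' @export
utr3Seqs <- function(x)
  subseq(x@sequences, start = x@cdsEnd + 1L, end = width(x@sequences))

# Region containing a 1-based transcript position of gene i.
regionOfPosition <- function(models, geneIndex, position) {
  cs <- models@cdsStart[geneIndex]
  ce <- models@cdsEnd[geneIndex]
  ifelse(position < cs, "UTR5", ifelse(position <= ce, "CDS", "UTR3"))
}

#' @describeIn RipExperiment-class Construct from a gene-by-sample
#'   abundance matrix and a sample design table.
#' @param abundance numeric matrix, rows = genes, columns = samples;
#'   rownames and colnames required.
#' @param design data.frame with columns `sample_id`, `assay`
#'   (`expression`/`rip`), `condition` (`treatment`/`control`) and
#'   `replicate`; rows map abundance columns to the profiling design.
#' @export
RipExperiment <- function(abundance, design) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have gene rownames and sample colnames",
         call. = FALSE)
  design <- as.data.frame(design)
  need <- c("sample_id", "assay", "condition", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(design$sample_id, colnames(abundance))
  if (length(absent))
    stop("design references missing abundance column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  abundance <- abundance[, design$sample_id, drop = FALSE]
  cd <- DataFrame(assayType = as.character(design$assay),
                  condition = as.character(design$condition),
                  replicate = as.integer(design$replicate),
                  row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  new("RipExperiment", se)
}

#' @rdname accessors
#' @export
sampleDesign <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd), assay = cd$assayType,
             condition = cd$condition, replicate = cd$replicate,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")
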