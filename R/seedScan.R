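# Seed-match derivation and transcript scanning.

#' Reverse complement of a nucleotide sequence
#'
#' Accepts DNA or RNA letters (case-insensitive, `T`/`U`
#' interchangeable, `N` allowed and preserved) and returns the reverse
#' complement written 5' to 3' in the requested output alphabet.
#'
#' @param seq a single nucleotide sequence string.
#' @param output output alphabet, `"DNA"` (default) or `"RNA"`.
#' @return a character string.
#' @examples
#' reverseComplementSeq("AACGGAA")           # "TTCCGTT"
#' reverseComplementSeq("AACGGAA", "RNA")    # "UUCCGUU"
#' @export
reverseComplementSeq <- function(seq, output = c("DNA", "RNA")) {
  output <- match.arg(output)
  s <- normalizeSeq(seq, "DNA", "sequence")
  rc <- as.character(reverseComplement(DNAString(s)))
  if (output == "RNA") chartr("T", "U", rc) else rc
}

#' Derive the seed-match k-mer of a miRNA
#'
#' The seed region of a miRNA is the guide window starting (by
#' default) at position 2; target transcripts carry its perfect DNA
#' reverse complement. With the defaults (`guideStart = 2`, `k = 7`)
#' this is the 7mer-m8 site: the reverse complement of guide positions
#' 2-8. For miR-191 (guide `CAACGGAAUCCCAAAAGCAGCUG`) the match k-mer
#' is `TTCCGTT`.
#'
#' @param mirna a [MatureMiRNA-class] object.
#' @param guideStart 1-based start of the seed window on the guide.
#' @param k window length.
#' @return a [SeedDefinition-class] object.
#' @examples
#' mir191 <- MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")
#' seedDefinition(mir191)
#' @export
seedDefinition <- function(mirna, guideStart = 2L, k = 7L) {
  stopifnot(is(mirna, "MatureMiRNA"))
  guideStart <- as.integer(guideStart)
  k <- as.integer(k)
  if (guideStart < 1L || guideStart + k - 1L > length(mirna@guide))
    stop("seed window [", guideStart, ", ", guideStart + k - 1L,
         "] lies outside the ", length(mirna@guide), "-nt guide",
         call. = FALSE)
  win <- subseq(mirna@guide, start = guideStart, width = k)
  kmer <- DNAString(reverseComplementSeq(as.character(win)))
  new("SeedDefinition", guideStart = guideStart, k = k,
      guideWindow = RNAString(win), matchKmer = kmer)
}

#' Find all occurrences of a k-mer in a sequence
#'
#' Exact matching, overlapping occurrences included; positions are
#' 1-based match starts in ascending order. `N` in the sequence never
#' matches. A k-mer longer than the sequence yields no positions.
#'
#' @param seq DNA sequence (string or [Biostrings::DNAString]).
#' @param kmer DNA k-mer to search for.
#' @return integer vector of 1-based start positions.
#' @examples
#' scanSequence("TTCCGTTACGTTCCGTT", "TTCCGTT")  # 1, 11
#' scanSequence("AAAAA", "AAA")                  # 1, 2, 3 (overlaps)
#' @export
scanSequence <- function(seq, kmer) {
  s <- if (is(seq, "DNAString")) seq
       else DNAString(normalizeSeq(seq, "DNA", "sequence"))
  p <- if (is(kmer, "DNAString")) kmer
       else DNAString(normalizeSeq(kmer, "DNA", "k-mer"))
  if (length(p) > length(s)) return(integer(0))
  as.integer(Biostrings::start(matchPattern(p, s, fixed = TRUE)))
}

#' Locate and classify seed matches in transcript models
#'
#' Scans every transcript for the seed match k-mer and assigns each
#' occurrence to the region (5'UTR, CDS or 3'UTR) containing its
#' start position. A match whose span crosses a region boundary keeps
#' the region of its start and is flagged `spans_boundary`.
#'
#' @param models a [TranscriptModels-class] object.
#' @param seed a [SeedDefinition-class] object.
#' @return a data.frame with columns `gene_id`, `region`, `position`
#'   (1-based transcript coordinate of the match start), `kmer` and
#'   `spans_boundary`, ordered by gene then position.
#' @examples
#' tm <- TranscriptModels(c(g = "AATTCCGTTAATTCCGTTAA"),
#'                        cdsStart = 5, cdsEnd = 14)
#' mir191 <- MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")
#' annotateGeneMatches(tm, seedDefinition(mir191))
#' @export
annotateGeneMatches <- function(models, seed) {
  stopifnot(is(models, "TranscriptModels"), is(seed, "SeedDefinition"))
  hits <- vmatchPattern(seed@matchKmer, models@sequences, fixed = TRUE)
  starts <- lapply(seq_along(models@sequences),
                   function(i) Biostrings::start(hits[[i]]))
  n <- lengths(starts)
  geneIndex <- rep.int(seq_along(n), n)
  position <- unlist(starts, use.names = FALSE)
  if (is.null(position)) position <- integer(0)
  region <- regionOfPosition(models, geneIndex, position)
  endRegion <- regionOfPosition(models, geneIndex, position + seed@k - 1L)
  data.frame(gene_id = geneIds(models)[geneIndex],
             region = as.character(region),
             position = as.integer(position),
             kmer = rep(as.character(seed@matchKmer), length(position)),
             spans_boundary = region != endRegion,
             stringsAsFactors = FALSE)
}

#' Tile a miRNA guide with k-mer windows
#'
#' Enumerates every k-mer window along the guide, 5' to 3', with the
#' DNA reverse complement each window pairs to. Used for the
#' specificity scan that asks which part of the miRNA the target set's
#' sequence signal pairs to: windows inside the seed region should
#' dominate when targeting is seed-driven.
#'
#' @param mirna a [MatureMiRNA-class] object.
#' @param k window length, default 6.
#' @return a data.frame with columns `guide_start`, `guide_window`
#'   (RNA) and `match_kmer` (DNA), one row per window in guide order.
#' @examples
#' mir191 <- MatureMiRNA("miR-191", "CAACGGAAUCCCAAAAGCAGCUG")
#' head(tilingWindows(mir191))   # 18 windows for a 23-nt guide
#' @export
tilingWindows <- function(mirna, k = 6L) {
  stopifnot(is(mirna, "MatureMiRNA"))
  k <- as.integer(k)
  L <- length(mirna@guide)
  if (k < 1L || k > L)
    stop("window length k = ", k, " exceeds the ", L, "-nt guide",
         call. = FALSE)
  starts <- seq_len(L - k + 1L)
  g <- as.character(mirna@guide)
  windows <- substring(g, starts, starts + k - 1L)
  data.frame(guide_start = starts,
             guide_window = windows,
             match_kmer = vapply(windows, reverseComplementSeq,
                                 character(1L), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
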