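test_that("reverse complement handles both alphabets and N", {
  expect_identical(reverseComplementSeq("AACGGAA"), "TTCCGTT")
  expect_identical(reverseComplementSeq("AACGGAA", "RNA"), "UUCCGUU")
  expect_identical(reverseComplementSeq("AAAA"), "TTTT")
  expect_identical(reverseComplementSeq("ACGT"), "ACGT")
  expect_identical(reverseComplementSeq("ANT"), "ANT")
  expect_error(reverseComplementSeq("ACXGT"), "'X' at position 3")
  expect_error(reverseComplementSeq(""), "non-empty")
})

test_that("reverse complement is an involution", {
  set.seed(41)
  for (i in 1:25) {
    s <- randomDna(sample(1:60, 1), nProb = 0.05)
    expect_identical(reverseComplementSeq(reverseComplementSeq(s)), s)
    # DNA -> RNA -> DNA round trip
    expect_identical(
      reverseComplementSeq(reverseComplementSeq(s, "RNA")), s)
  }
})

test_that("seed match k-mer is the DNA rc of the guide window", {
  mir <- mir191()
  expect_identical(matchKmer(seedDefinition(mir)), "TTCCGTT")
  expect_identical(guideWindow(seedDefinition(mir)), "AACGGAA")
  ctl2 <- MatureMiRNA("Control RNA 2", "AAUUCUCCGAACGUGUCACGUUA")
  expect_identical(matchKmer(seedDefinition(ctl2)), "GGAGAAT")
  polyA <- MatureMiRNA("polyA", "AAAAAAAA")
  expect_identical(matchKmer(seedDefinition(polyA)), "TTTTTTT")
  # configurable variants: 6-mer (2-7) and 8-mer
  expect_identical(matchKmer(seedDefinition(mir, 2, 6)), "TCCGTT")
  expect_identical(nchar(matchKmer(seedDefinition(mir, 1, 8))), 8L)
  expect_error(seedDefinition(polyA, guideStart = 3, k = 7), "outside")
})

test_that("guide sequences are normalized and validated", {
  m <- MatureMiRNA("x", "caacggaatcccaaaagcagctg")  # DNA letters, lower
  expect_identical(guideSequence(m), "CAACGGAAUCCCAAAAGCAGCUG")
  expect_identical(length(m), 23L)
  expect_error(MatureMiRNA("x", "ACGUACG"), "at least 8")
  expect_error(MatureMiRNA("x", "ACGUACGUNN"), "N")
})

test_that("scanSequence reports overlapping matches, N never matches", {
  expect_identical(scanSequence("TTCCGTTACGTTCCGTT", "TTCCGTT"),
                   c(1L, 11L))
  expect_identical(scanSequence("AAAAA", "AAA"), c(1L, 2L, 3L))
  expect_identical(scanSequence("TTCCGNT", "TTCCGTT"), integer(0))
  expect_identical(scanSequence("ACG", "ACGT"), integer(0))
})

test_that("scanSequence agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:150) {
    s <- randomDna(300, nProb = if (i %% 3 == 0) 0.03 else 0)
    k <- sample(2:8, 1)
    kmer <- randomDna(k)
    expect_identical(scanSequence(s, kmer), as.integer(naiveScan(s, kmer)))
  }
})

test_that("matches are assigned to the region of their start", {
  kmer <- "TTCCGTT"
  mir <- mir191()
  tm <- TranscriptModels(
    c(g1 = plantedTranscript(30, kmer, c(3, 12, 24)),
      g2 = plantedTranscript(30, kmer, 8),
      g3 = strrep("A", 30)),
    cdsStart = c(11, 11, 11), cdsEnd = c(20, 20, 20))
  ann <- annotateGeneMatches(tm, seedDefinition(mir))
  g1 <- ann[ann$gene_id == "g1", ]
  expect_identical(g1$position, c(3L, 12L, 24L))
  expect_identical(g1$region, c("UTR5", "CDS", "UTR3"))
  expect_false(any(g1$spans_boundary))
  # match spanning the UTR5/CDS boundary keeps its start region
  g2 <- ann[ann$gene_id == "g2", ]
  expect_identical(g2$region, "UTR5")
  expect_true(g2$spans_boundary)
  # gene without matches contributes no records
  expect_false("g3" %in% ann$gene_id)
  # positions truly carry the k-mer
  seqs <- as.character(transcriptSeqs(tm))
  for (r in seq_len(nrow(ann)))
    expect_identical(substr(seqs[[ann$gene_id[r]]], ann$position[r],
                            ann$position[r] + 6L), kmer)
})

test_that("per-region match counts sum to the transcript total", {
  set.seed(13)
  mir <- mir191()
  sd7 <- seedDefinition(mir)
  n <- 40
  seqs <- vapply(1:n, function(i) randomDna(300), character(1))
  # sprinkle sites so several genes have multiple matches
  for (i in sample(n, 25))
    seqs[i] <- plantedTranscript(300, matchKmer(sd7),
                                 sample(seq(1, 280, by = 15), 3))
  names(seqs) <- paste0("g", 1:n)
  tm <- TranscriptModels(seqs, cdsStart = rep(100, n), cdsEnd = rep(220, n))
  ann <- annotateGeneMatches(tm, sd7)
  total <- vapply(names(seqs), function(g)
    length(scanSequence(seqs[[g]], matchKmer(sd7))), integer(1))
  perRegion <- table(factor(ann$gene_id, levels = names(seqs)))
  expect_identical(as.integer(perRegion), unname(total))
})

test_that("tiling windows cover the guide with k-1 overlaps", {
  mir <- mir191()
  tw <- tilingWindows(mir)
  expect_identical(nrow(tw), 18L)
  expect_identical(tw$guide_start, 1:18)
  expect_identical(tw$guide_window[2], "AACGGA")
  expect_identical(tw$match_kmer[2], "TCCGTT")
  for (i in 2:nrow(tw))
    expect_identical(substring(tw$guide_window[i - 1], 2, 6),
                     substring(tw$guide_window[i], 1, 5))
  # full-length window is the whole-guide reverse complement
  full <- tilingWindows(mir, k = 23)
  expect_identical(nrow(full), 1L)
  expect_identical(full$match_kmer,
                   reverseComplementSeq(guideSequence(mir)))
  expect_error(tilingWindows(mir, k = 24), "exceeds")
})
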