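# Independent oracles and fixture builders shared across tests.

# brute-force overlapping k-mer scan by position-wise string equality
naiveScan <- function(seq, kmer) {
  n <- nchar(seq)
  k <- nchar(kmer)
  if (k > n) return(integer(0))
  starts <- seq_len(n - k + 1L)
  which(substring(seq, starts, starts + k - 1L) == kmer)
}

randomDna <- function(len, nProb = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - nProb) / 4, 4), nProb)),
        collapse = "")
}

# build a RipExperiment from per-class gene-by-replicate matrices
# (vectors are treated as single-replicate columns)
expFromClasses <- function(expr_trt, expr_ctl, rip_trt, rip_ctl,
                           geneIds = NULL) {
  mats <- lapply(list(expr_trt = expr_trt, expr_ctl = expr_ctl,
                      rip_trt = rip_trt, rip_ctl = rip_ctl), as.matrix)
  n <- nrow(mats[[1L]])
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(n))
  assayOf <- c(expr_trt = "expression", expr_ctl = "expression",
               rip_trt = "rip", rip_ctl = "rip")
  condOf <- c(expr_trt = "treatment", expr_ctl = "control",
              rip_trt = "treatment", rip_ctl = "control")
  cols <- list()
  des <- list()
  for (cl in names(mats)) {
    m <- mats[[cl]]
    for (r in seq_len(ncol(m))) {
      sid <- paste(cl, r, sep = "_")
      cols[[sid]] <- m[, r]
      des[[sid]] <- data.frame(sample_id = sid, assay = assayOf[[cl]],
                               condition = condOf[[cl]], replicate = r,
                               stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- geneIds
  RipExperiment(mat, do.call(rbind, des))
}

# plant a k-mer into an A-homopolymer backbone (which cannot contain
# the planted k-mer by accident for any k-mer with a non-A base)
plantedTranscript <- function(len, kmer, positions) {
  s <- strrep("A", len)
  for (p in positions)
    substr(s, p, p + nchar(kmer) - 1L) <- kmer
  s
}
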