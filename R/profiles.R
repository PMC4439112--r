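# Seed-centric validation analyses over ranked or grouped gene sets.

#' Rank genes by a per-gene statistic
#'
#' Deterministic ordering: by value in the requested direction, ties
#' broken by ascending gene id.
#'
#' @param values named numeric vector (enrichment, repression or
#'   score per gene); must be finite.
#' @param direction `"descending"` (default; most enriched first) or
#'   `"ascending"`.
#' @return a data.frame with columns `gene_id` and `value` in rank
#'   order.
#' @export
rankGenes <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (is.null(names(values)))
    stop("values must be named by gene id", call. = FALSE)
  if (any(!is.finite(values)))
    stop("ranking values must be finite", call. = FALSE)
  ord <- if (direction == "descending") order(-values, names(values))
         else order(values, names(values))
  data.frame(gene_id = names(values)[ord], value = unname(values)[ord],
             stringsAsFactors = FALSE)
}

#' Seed-match frequency over consecutive ranked gene bins
#'
#' Splits a ranked gene list into consecutive bins (default 250
#' genes) and reports, per bin, the fraction of genes carrying a seed
#' match relative to the same fraction over a background universe.
#' A declining profile from the top bins down indicates that the
#' ranking captures seed-driven targeting. The final bin may be
#' partial and is flagged.
#'
#' @param ranked a ranked gene list from [rankGenes()] (or a character
#'   vector of gene ids in rank order).
#' @param hasMatch named logical vector over the background universe:
#'   does the gene carry a seed match (in the region of interest,
#'   typically the 3'UTR)?
#' @param binSize genes per bin, default 250.
#' @return a data.frame with columns `bin_index`, `bin_size`,
#'   `n_match`, `relative_frequency` (bin match fraction / background
#'   match fraction) and `partial`.
#' @examples
#' hm <- setNames(rep(c(TRUE, FALSE), c(100, 400)), paste0("g", 1:500))
#' rk <- rankGenes(setNames(500:1, paste0("g", 1:500)))
#' head(binnedSeedFrequency(rk, hm), 1)   # top bin: (100/250)/(100/500) = 2
#' @export
binnedSeedFrequency <- function(ranked, hasMatch, binSize = 250L) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  if (is.null(names(hasMatch)))
    stop("hasMatch must be named by gene id", call. = FALSE)
  miss <- setdiff(ids, names(hasMatch))
  if (length(miss))
    stop("ranked gene(s) absent from hasMatch universe: ",
         paste(utils::head(miss, 3L), collapse = ", "), call. = FALSE)
  background <- mean(hasMatch)
  if (background == 0)
    stop("background seed-match fraction is 0; relative frequencies ",
         "are undefined -- check the seed definition and universe",
         call. = FALSE)
  binSize <- as.integer(binSize)
  n <- length(ids)
  bin <- ((seq_len(n) - 1L) %/% binSize) + 1L
  m <- hasMatch[ids]
  sizes <- tabulate(bin)
  nMatch <- vapply(seq_along(sizes), function(b) sum(m[bin == b]),
                   integer(1L))
  data.frame(bin_index = seq_along(sizes), bin_size = sizes,
             n_match = nMatch,
             relative_frequency = (nMatch / sizes) / background,
             partial = sizes < binSize)
}

#' Per-gene region match flags
#'
#' Collapses seed-match records to one row per gene of the universe
#' with a logical per region: does the gene carry at least one match
#' starting in that region?
#'
#' @param matches match records from [annotateGeneMatches()].
#' @param universe character vector of gene ids (the profiled genes).
#' @return a data.frame with columns `gene_id`, `UTR5`, `CDS`, `UTR3`.
#' @export
regionFlags <- function(matches, universe) {
  bad <- setdiff(unique(matches$gene_id), universe)
  if (length(bad))
    stop("match record gene(s) absent from universe: ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (r in c("UTR5", "CDS", "UTR3"))
    out[[r]] <- universe %in% matches$gene_id[matches$region == r]
  out
}

#' Proportions of genes with seed matches per transcript region
#'
#' Inclusive mode counts a gene in every region where it has at least
#' one match (categories can overlap; an `any` row gives genes with a
#' match anywhere). Exclusive mode categorizes only genes whose
#' matches fall in exactly one region and adds `multiple` and `none`
#' rows, so the counts partition the universe.
#'
#' @param flags region flags from [regionFlags()].
#' @param mode `"inclusive"` or `"exclusive"`.
#' @return a data.frame with columns `category`, `n_genes`,
#'   `proportion` (of the universe).
#' @export
regionProportions <- function(flags, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  n <- nrow(flags)
  regions <- c("UTR5", "CDS", "UTR3")
  k <- rowSums(as.matrix(flags[, regions]))
  if (mode == "inclusive") {
    counts <- c(vapply(regions, function(r) sum(flags[[r]]), integer(1L)),
                any = sum(k > 0), none = sum(k == 0))
  } else {
    counts <- c(vapply(regions, function(r) sum(flags[[r]] & k == 1L),
                       integer(1L)),
                multiple = sum(k > 1L), none = sum(k == 0L))
  }
  data.frame(category = names(counts), n_genes = unname(counts),
             proportion = unname(counts) / n, stringsAsFactors = FALSE)
}

#' Points of an empirical cumulative distribution function
#'
#' Right-continuous ECDF evaluated at the sorted unique values;
#' duplicated values collapse into a single step of proportional
#' height and the last point reaches 1. Ratio statistics should be
#' log2-transformed by the caller before plotting or testing.
#'
#' @param values numeric vector with at least one finite value.
#' @return a data.frame with columns `value` and `cumulative_fraction`.
#' @export
ecdfPoints <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values))
    stop("need at least one finite value", call. = FALSE)
  x <- sort(unique(values))
  data.frame(value = x, cumulative_fraction = ecdf(values)(x))
}

exclusiveIds <- function(flags, region) {
  k <- rowSums(as.matrix(flags[, c("UTR5", "CDS", "UTR3")]))
  flags$gene_id[flags[[region]] & k == 1L]
}

#' Compare a per-gene statistic between two seed-match location groups
#'
#' Tests whether genes with a seed match in one transcript region are
#' more enriched/repressed than genes with a match in another, via
#' Welch's t-test on the (log2-transformed) statistic. By default
#' groups are exclusive -- genes with matches in exactly one region --
#' since multi-region genes confound the location attribution;
#' inclusive grouping is available.
#'
#' @param stat named per-gene numeric statistic (e.g. `log2(E)` or
#'   `log2(R)`).
#' @param flags region flags from [regionFlags()].
#' @param regionA,regionB regions to compare (`"UTR5"`, `"CDS"`,
#'   `"UTR3"`).
#' @param mode `"exclusive"` (default) or `"inclusive"` group
#'   membership.
#' @param alternative passed to [welchTTest()]; `"a_greater"` tests
#'   that the `regionA` group has the larger mean.
#' @param minSize minimum group size, default 2.
#' @return a one-row data.frame: `groupA`, `groupB`, `nA`, `nB`,
#'   `meanA`, `meanB`, `t`, `df`, `p`, `alternative`, `degenerate`.
#' @export
regionDistributionCompare <- function(stat, flags, regionA, regionB,
                                      mode = c("exclusive", "inclusive"),
                                      alternative = "two_sided",
                                      minSize = 2L) {
  mode <- match.arg(mode)
  pick <- function(region) {
    ids <- if (mode == "exclusive") exclusiveIds(flags, region)
           else flags$gene_id[flags[[region]]]
    intersect(ids, names(stat))
  }
  idsA <- pick(regionA)
  idsB <- pick(regionB)
  if (length(idsA) < minSize || length(idsB) < minSize)
    stop("insufficient data: group sizes ", length(idsA), " (", regionA,
         ") and ", length(idsB), " (", regionB, ")", call. = FALSE)
  res <- welchTTest(stat[idsA], stat[idsB], alternative = alternative)
  cbind(data.frame(groupA = regionA, groupB = regionB,
                   stringsAsFactors = FALSE), res)
}

#' Relative 3'UTR frequency of every guide-tiling k-mer
#'
#' For each k-mer window along the guide (from [tilingWindows()]),
#' computes the fraction of target-set genes whose 3'UTR contains the
#' window's match k-mer, divided by the same fraction over the
#' background universe. When targeting is seed-driven, only windows
#' lying inside the seed region stand out -- the specificity signature
#' of a genuine target set.
#'
#' @param windows a data.frame from [tilingWindows()].
#' @param targetSet character vector of target gene ids (non-empty).
#' @param background character vector of background gene ids.
#' @param utr3 named [Biostrings::DNAStringSet] of 3'UTR sequences
#'   covering both sets (e.g. `utr3Seqs(models)`).
#' @return `windows` with added columns `target_fraction`,
#'   `background_fraction` and `relative_frequency` (`NA` where the
#'   background fraction is 0).
#' @export
tilingRelativeFrequency <- function(windows, targetSet, background, utr3) {
  if (!length(targetSet))
    stop("target set is empty", call. = FALSE)
  miss <- setdiff(c(targetSet, background), names(utr3))
  if (length(miss))
    stop("gene(s) lacking a 3'UTR sequence: ",
         paste(utils::head(miss, 3L), collapse = ", "), call. = FALSE)
  tgt <- utr3[targetSet]
  bg <- utr3[background]
  tf <- bf <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    kmer <- DNAString(windows$match_kmer[i])
    tf[i] <- mean(vcountPattern(kmer, tgt, fixed = TRUE) > 0)
    bf[i] <- mean(vcountPattern(kmer, bg, fixed = TRUE) > 0)
  }
  rf <- ifelse(bf > 0, tf / bf, NA_real_)
  if (anyNA(rf))
    warning(sum(is.na(rf)), " window(s) have background fraction 0; ",
            "relative frequency reported as NA")
  cbind(windows, target_fraction = tf, background_fraction = bf,
        relative_frequency = rf)
}
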