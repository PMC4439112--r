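# Repression, RIP enrichment and combined target scores.
#
# All ratios operate on floored abundances: abundances below the floor
# (default 1 FPKM) are raised to it, which bounds denominators away
# from zero and keeps ratios of undetected genes at 1.

#' Floor an abundance matrix
#'
#' Replaces every abundance below `floor` by `floor`. Applied before
#' any ratio is formed so that genes undetected in one library cannot
#' inflate a ratio through a near-zero denominator. Idempotent.
#'
#' @param x a numeric matrix or a [RipExperiment-class].
#' @param floor the floor constant, default 1 (FPKM units).
#' @return an object of the same class with floored abundances; for a
#'   `RipExperiment` the flag `metadata(x)$floored` is set.
#' @examples
#' floorAbundances(matrix(c(0, 0.5, 1, 2.7), 2))
#' @export
setGeneric("floorAbundances",
           function(x, floor = 1) standardGeneric("floorAbundances"))

#' @rdname floorAbundances
#' @export
setMethod("floorAbundances", "matrix", function(x, floor = 1) {
  if (any(x < 0, na.rm = TRUE))
    stop("abundances must be nonnegative", call. = FALSE)
  x[!is.na(x) & x < floor] <- floor
  x
})

#' @rdname floorAbundances
#' @export
setMethod("floorAbundances", "RipExperiment", function(x, floor = 1) {
  SummarizedExperiment::assay(x, "abundance") <-
    floorAbundances(abundances(x), floor)
  metadata(x)$floored <- TRUE
  metadata(x)$floor <- floor
  x
})

#' Per-gene condition summaries of a profiling experiment
#'
#' Collapses replicates to an arithmetic mean per (assay, condition)
#' class, then floors, yielding the four per-gene quantities the
#' ratio formulas need: expression and RIP abundance under treatment
#' and control. Genes with a missing value in any class are dropped
#' (with a message giving the count).
#'
#' @param experiment a [RipExperiment-class].
#' @param floor the abundance floor, default 1.
#' @return a data.frame with rownames = gene ids and columns
#'   `expr_trt`, `expr_ctl`, `rip_trt`, `rip_ctl`, all `>= floor`.
#' @export
summarizeConditions <- function(experiment, floor = 1) {
  stopifnot(is(experiment, "RipExperiment"))
  validObject(experiment)
  a <- abundances(experiment)
  cd <- SummarizedExperiment::colData(experiment)
  classCols <- function(at, cond)
    which(cd$assayType == at & cd$condition == cond)
  classes <- list(expr_trt = classCols("expression", "treatment"),
                  expr_ctl = classCols("expression", "control"),
                  rip_trt  = classCols("rip", "treatment"),
                  rip_ctl  = classCols("rip", "control"))
  out <- do.call(cbind, lapply(classes, function(cols)
    rowMeans(a[, cols, drop = FALSE])))
  rownames(out) <- rownames(a)
  out <- as.data.frame(out)
  keep <- stats::complete.cases(out)
  if (any(!keep))
    message(sum(!keep), " gene(s) dropped: missing abundance in ",
            "at least one library class")
  out <- out[keep, , drop = FALSE]
  as.data.frame(floorAbundances(as.matrix(out), floor))
}

#' Gene-expression repression ratio
#'
#' `R = expression(control) / expression(treatment)` on replicate-mean,
#' floored abundances. `R > 1` means the gene's expression is lower
#' after the miRNA transfection, i.e. the gene is repressed.
#'
#' @param summary a condition summary from [summarizeConditions()].
#' @return named numeric vector of per-gene repression ratios.
#' @export
repression <- function(summary) {
  checkSummary(summary, c("expr_trt", "expr_ctl"))
  stats::setNames(summary$expr_ctl / summary$expr_trt, rownames(summary))
}

#' RISC-immunoprecipitation enrichment ratio
#'
#' RIP abundances are first normalized to the matched expression
#' abundances, then the treatment ratio is divided by the control
#' ratio:
#' `E = (rip_trt / expr_trt) / (rip_ctl / expr_ctl)`.
#' `E > 1` indicates miRNA-dependent RISC association of the gene.
#'
#' @inheritParams repression
#' @return named numeric vector of per-gene enrichment ratios.
#' @export
ripEnrichment <- function(summary) {
  checkSummary(summary, c("expr_trt", "expr_ctl", "rip_trt", "rip_ctl"))
  stats::setNames((summary$rip_trt / summary$expr_trt) /
                  (summary$rip_ctl / summary$expr_ctl),
                  rownames(summary))
}

checkSummary <- function(summary, cols) {
  miss <- setdiff(cols, colnames(summary))
  if (length(miss))
    stop("condition summary lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  vals <- as.matrix(summary[, cols])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("condition summary must be floored: all values positive ",
         "and finite", call. = FALSE)
  invisible(TRUE)
}

#' Combine enrichment and repression into target scores
#'
#' The target score of a gene is the mean of its RIP enrichment and
#' its expression repression, `S = (E + R) / 2`; genes with
#' `S >= threshold` (default 1.5, inclusive) form the target set.
#' Genes present in only one of the two vectors are dropped with a
#' message.
#'
#' @param enrichment named per-gene enrichment ratios `E`.
#' @param repression named per-gene repression ratios `R`.
#' @param threshold target-call cutoff on the score, default 1.5.
#' @return a data.frame with columns `gene_id`, `repression`,
#'   `enrichment`, `score`, `is_target`, ordered by descending score
#'   (ties broken by gene id).
#' @examples
#' callTargets(c(g1 = 2, g2 = 1), c(g1 = 1, g2 = 1))  # g1: S = 1.5, target
#' @export
callTargets <- function(enrichment, repression, threshold = 1.5) {
  if (is.null(names(enrichment)) || is.null(names(repression)))
    stop("enrichment and repression must be named by gene id",
         call. = FALSE)
  if (any(!is.finite(enrichment)) || any(enrichment <= 0) ||
      any(!is.finite(repression)) || any(repression <= 0))
    stop("enrichment and repression ratios must be positive and finite",
         call. = FALSE)
  common <- intersect(names(enrichment), names(repression))
  dropped <- length(enrichment) + length(repression) - 2L * length(common)
  if (dropped > 0L)
    message(dropped, " gene(s) dropped: present in only one of ",
            "enrichment/repression")
  E <- enrichment[common]
  R <- repression[common]
  S <- (E + R) / 2
  out <- data.frame(gene_id = common, repression = unname(R),
                    enrichment = unname(E), score = unname(S),
                    is_target = unname(S >= threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a profiling experiment and call the target set
#'
#' One-stop pipeline: replicate means per library class, abundance
#' floor, repression and RIP enrichment ratios, combined score and
#' target call.
#'
#' @param experiment a [RipExperiment-class].
#' @param floor abundance floor, default 1.
#' @param threshold target-call score cutoff, default 1.5.
#' @return the target table of [callTargets()].
#' @examples
#' sim <- simulateStudy(simulationConfig(nGenes = 50, nTargets = 5,
#'                                       replicateNoiseSd = 0))
#' head(scoreTargets(sim$experiment))
#' @export
scoreTargets <- function(experiment, floor = 1, threshold = 1.5) {
  cs <- summarizeConditions(experiment, floor = floor)
  callTargets(ripEnrichment(cs), repression(cs), threshold = threshold)
}
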