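#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' Paired expression/methylation study container
#'
#' Holds a gene-level integer count matrix and a CpG beta-value matrix over
#' the same samples, together with the sample sheet, gene and CpG
#' annotation as `GRanges`, and (for simulated studies) a truth ledger of
#' planted effects.
#'
#' @slot counts integer matrix, genes x samples.
#' @slot betas numeric matrix in \[0,1\], CpGs x samples.
#' @slot samples `DataFrame` with at least `sample_id`, `condition`
#'   (factor, levels `control`, `DS`) and `sex` (factor `F`/`M`); optional
#'   `batch`.
#' @slot geneAnno `GRanges`, one range per gene (1-based inclusive), with
#'   metadata columns `gene_id`, `symbol`, `marker_class`
#'   (`thyroid`/`muscle`/`none`) and `thyroid_related`.
#' @slot cpgAnno `GRanges` of width 1, one per CpG, with `probe_id` and
#'   logical flags `flag_allosomal`, `flag_chr21`, `flag_polymorphic`,
#'   `flag_crossreactive`.
#' @slot truth list describing planted effects (empty for real data): data
#'   frames `de_genes`, `dmrs`, `cis_pairs`, `samples`, plus the `batch`
#'   assignment.
#' @slot metadata list (e.g. the simulation config and seed).
#'
#' @exportClass TrisomyStudy
setClass("TrisomyStudy",
  representation(
    counts = "matrix",
    betas = "matrix",
    samples = "DataFrame",
    geneAnno = "GRanges",
    cpgAnno = "GRanges",
    truth = "list",
    metadata = "list"
  )
)

setValidity("TrisomyStudy", function(object) {
  msg <- character()
  cnt <- object@counts
  bet <- object@betas
  smp <- object@samples
  if (!identical(colnames(cnt), colnames(bet)))
    msg <- c(msg, "counts and betas must share identical sample columns")
  if (!identical(colnames(cnt), as.character(smp$sample_id)))
    msg <- c(msg, "sample sheet order must match matrix columns")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (any(bet < 0 | bet > 1))
    msg <- c(msg, "beta values must lie in [0,1]")
  if (length(object@geneAnno) != nrow(cnt))
    msg <- c(msg, "gene annotation must cover every count row")
  if (length(object@cpgAnno) != nrow(bet))
    msg <- c(msg, "CpG annotation must cover every beta row")
  tr <- object@truth
  if (!is.null(tr$de_genes) && nrow(tr$de_genes) &&
      !all(tr$de_genes$gene_id %in% rownames(cnt)))
    msg <- c(msg, "truth ledger references unknown genes")
  if (!is.null(tr$samples) && nrow(tr$samples) &&
      !all(tr$samples$sample_id %in% colnames(cnt)))
    msg <- c(msg, "truth ledger references unknown samples")
  if (length(msg)) msg else TRUE
})

#' Construct a TrisomyStudy
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param betas numeric matrix in \[0,1\], CpGs x samples (rownames = probe
#'   ids), same columns as `counts`.
#' @param samples data.frame/DataFrame with `sample_id`, `condition`, `sex`.
#' @param geneAnno `GRanges` gene annotation (see class docs).
#' @param cpgAnno `GRanges` CpG annotation.
#' @param truth optional truth ledger list.
#' @param metadata optional metadata list.
#' @return A [TrisomyStudy-class] object.
#' @export
TrisomyStudy <- function(counts, betas, samples, geneAnno, cpgAnno,
                         truth = list(), metadata = list()) {
  samples <- as(as.data.frame(samples), "DataFrame")
  new("TrisomyStudy", counts = counts, betas = betas, samples = samples,
      geneAnno = geneAnno, cpgAnno = cpgAnno, truth = truth,
      metadata = metadata)
}

setMethod("show", "TrisomyStudy", function(object) {
  smp <- object@samples
  cat("TrisomyStudy object\n")
  cat(sprintf("  %d genes x %d samples (counts); %d CpGs (betas)\n",
              nrow(object@counts), ncol(object@counts), nrow(object@betas)))
  cat(sprintf("  condition: %s\n",
              paste(sprintf("%s=%d", names(table(smp$condition)),
                            as.integer(table(smp$condition))),
                    collapse = ", ")))
  if (length(object@truth))
    cat(sprintf(
      "  truth ledger: %d DE genes, %d DMRs, %d cis pairs, %d flagged samples\n",
      NROW(object@truth$de_genes), NROW(object@truth$dmrs),
      NROW(object@truth$cis_pairs), NROW(object@truth$samples)))
})

#' @describeIn TrisomyStudy-class gene-level count matrix
#' @param object,x a `TrisomyStudy`
#' @export
setGeneric("studyCounts", function(object) standardGeneric("studyCounts"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("studyCounts", "TrisomyStudy", function(object) object@counts)

#' @describeIn TrisomyStudy-class CpG beta-value matrix
#' @export
setGeneric("studyBetas", function(object) standardGeneric("studyBetas"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("studyBetas", "TrisomyStudy", function(object) object@betas)

#' @describeIn TrisomyStudy-class sample sheet as `DataFrame`
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("sampleSheet", "TrisomyStudy", function(object) object@samples)

#' @describeIn TrisomyStudy-class gene annotation `GRanges`
#' @export
setGeneric("geneAnnotation", function(object) standardGeneric("geneAnnotation"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("geneAnnotation", "TrisomyStudy", function(object) object@geneAnno)

#' @describeIn TrisomyStudy-class CpG annotation `GRanges`
#' @export
setGeneric("cpgAnnotation", function(object) standardGeneric("cpgAnnotation"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("cpgAnnotation", "TrisomyStudy", function(object) object@cpgAnno)

#' @describeIn TrisomyStudy-class truth ledger of planted effects
#' @export
setGeneric("truthLedger", function(object) standardGeneric("truthLedger"))
#' @rdname TrisomyStudy-class
#' @export
setMethod("truthLedger", "TrisomyStudy", function(object) object@truth)
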