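#' Pipeline configuration
#'
#' All stage parameters of [runPipeline()] with the study defaults:
#' differential expression at FDR 0.05, DMRs at FDR 0.01 with a 0.05
#' beta-area cutoff, at least 3 CpGs and 100 permutations, the 2000 bp
#' cis window, eQTM significance at permutation p 0.05, and GSEA at FDR
#' 0.01 with Jaccard clustering threshold 0.25. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated `trisomicsPipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    qc_enabled = TRUE, qc_k = 2L, qc_quantile = 0.99,
    de_min_count = 10, de_min_samples = 4, de_alpha = 0.05,
    dmp_alpha = 0.05, n_sv = 1L,
    dmr_cutoff = 0.05, dmr_min_cpgs = 3L, dmr_maxgap = 500L,
    dmr_n_perm = 100L, dmr_alpha = 0.01,
    eqtm_window = 2000L, eqtm_scope = "deg-pairs",
    eqtm_n_boot = 100000L, eqtm_n_perm = 10000L, eqtm_alpha = 0.05,
    gsea_enabled = TRUE, gsea_n_perm = 1000L, gsea_min_size = 15L,
    gsea_max_size = 500L, gsea_alpha = 0.01, gsea_jaccard = 0.25)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown pipeline config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("de_alpha", "dmp_alpha", "dmr_alpha", "eqtm_alpha", "gsea_alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stopf("threshold '%s' must lie in (0,1)", f)
  if (!cfg$eqtm_scope %in% c("deg-pairs", "all-dmr-genes"))
    stopf("eqtm_scope must be 'deg-pairs' or 'all-dmr-genes'")
  class(cfg) <- "trisomicsPipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates sample QC, differential expression with chromosome
#' enrichment, differential methylation at position and region level,
#' cis DMR-gene pairing with the integrative methylation-expression
#' analysis, and (when a gene-set collection is supplied) preranked GSEA
#' with set clustering. Every stage output is written as TSV under
#' `outdir` together with a JSON manifest of versions, parameters, seeds,
#' input checksums and per-stage feature counts.
#'
#' @param study a [TrisomyStudy-class] (e.g. from [simulateStudy()] or
#'   [readStudy()]).
#' @param config list from [pipelineConfig()].
#' @param outdir output directory; `NULL` skips writing.
#' @param collection optional named gene-set list for the GSEA stage.
#' @return list with `qc`, `de`, `enrichment`, `dmp`, `dmrs`, `eqtm`,
#'   `gsea`, `clusters`, `manifest`.
#' @export
runPipeline <- function(study, config = pipelineConfig(), outdir = NULL,
                        collection = NULL) {
  stopifnot(is(study, "TrisomyStudy"))
  cfg <- if (inherits(config, "trisomicsPipelineConfig")) config
         else do.call(pipelineConfig, config)
  counts <- studyCounts(study); betas <- studyBetas(study)
  samples <- as.data.frame(sampleSheet(study))
  geneAnno <- geneAnnotation(study); cpgAnno <- cpgAnnotation(study)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))

  ## QC ----------------------------------------------------------------
  qc <- NULL; keep <- samples$sample_id
  if (cfg$qc_enabled) {
    qc <- stage("qc", runSampleQC(counts, samples, geneAnno,
                                  k = cfg$qc_k, quantile = cfg$qc_quantile))
    keep <- qc$keep
  }
  counts <- counts[, keep, drop = FALSE]
  betas <- betas[, keep, drop = FALSE]
  samples <- samples[match(keep, samples$sample_id), , drop = FALSE]

  ## differential expression -------------------------------------------
  de <- stage("diffexpr", {
    kept <- prefilterGenes(counts, cfg$de_min_count, cfg$de_min_samples)
    sf <- medianRatioSizeFactors(counts[kept, , drop = FALSE])
    nbWaldTest(counts[kept, , drop = FALSE], samples, sf,
               geneAnno = geneAnno, alpha = cfg$de_alpha)
  })
  sf <- medianRatioSizeFactors(
    counts[prefilterGenes(counts, cfg$de_min_count, cfg$de_min_samples), ,
           drop = FALSE])
  enr <- stage("chrom_enrichment", chromosomeEnrichment(de, cfg$de_alpha))

  ## methylation --------------------------------------------------------
  kept_probes <- stage("probe_filter", filterProbes(betas, cpgAnno))
  bet <- betas[kept_probes, , drop = FALSE]
  svs <- stage("surrogates",
               if (cfg$n_sv > 0)
                 estimateSurrogates(betaToM(bet), samples, n_sv = cfg$n_sv)
               else NULL)
  dmp <- stage("dmp", dmpTest(bet, samples, svs, alpha = cfg$dmp_alpha))
  dmrs <- stage("dmr", findDMRs(bet, samples, cpgAnno, svs,
                                cutoff = cfg$dmr_cutoff,
                                min_cpgs = cfg$dmr_min_cpgs,
                                maxgap = cfg$dmr_maxgap,
                                n_perm = cfg$dmr_n_perm,
                                alpha = cfg$dmr_alpha,
                                seed = childSeed(cfg$seed, 11)))

  ## integration --------------------------------------------------------
  eqtm <- stage("eqtm", runIntegration(
    dmrs, de, bet, counts[rownames(counts) %in% de$gene_id, , drop = FALSE],
    size_factors = sf, geneAnno = geneAnno, window = cfg$eqtm_window,
    scope = cfg$eqtm_scope, n_boot = cfg$eqtm_n_boot,
    n_perm = cfg$eqtm_n_perm, seed = childSeed(cfg$seed, 12),
    alpha = cfg$eqtm_alpha))

  ## GSEA ----------------------------------------------------------------
  gsea <- clusters <- NULL
  if (cfg$gsea_enabled && !is.null(collection)) {
    gsea <- stage("gsea", gseaPreranked(rankGenes(de), collection,
                                        n_perm = cfg$gsea_n_perm,
                                        min_size = cfg$gsea_min_size,
                                        max_size = cfg$gsea_max_size,
                                        alpha = cfg$gsea_alpha,
                                        seed = childSeed(cfg$seed, 13)))
    sig <- gsea[gsea$signif, , drop = FALSE]
    clusters <- stage("gsea_clusters",
                      clusterGeneSets(sig, collection, cfg$gsea_jaccard))
  }

  manifest <- list(
    package = "trisomics",
    package_version = as.character(utils::packageVersion("trisomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = unclass(cfg),
    seeds = list(root = cfg$seed, dmr = childSeed(cfg$seed, 11),
                 eqtm = childSeed(cfg$seed, 12), gsea = childSeed(cfg$seed, 13)),
    input_checksums = list(
      counts = digestMatrix(studyCounts(study)),
      betas = digestMatrix(studyBetas(study))),
    counts = list(
      samples_total = nrow(as.data.frame(sampleSheet(study))),
      samples_after_qc = length(keep),
      genes_after_prefilter = nrow(de),
      degs = sum(de$signif, na.rm = TRUE),
      probes_after_filter = length(kept_probes),
      dmps = sum(dmp$signif, na.rm = TRUE),
      dmrs = sum(dmrs$signif %||% logical(0)),
      candidate_pairs = nrow(eqtm),
      significant_associations = sum(eqtm$significant, na.rm = TRUE),
      eqtm_distinct_cpgs = attr(eqtm, "n_distinct_cpgs") %||% 0L,
      significant_sets = if (is.null(gsea)) NA_integer_
                         else sum(gsea$signif, na.rm = TRUE)))

  out <- list(qc = qc, de = de, enrichment = enr, dmp = dmp, dmrs = dmrs,
              eqtm = eqtm, gsea = gsea, clusters = clusters,
              manifest = manifest)
  if (!is.null(outdir)) writePipelineOutputs(out, outdir)
  out
}

## stable checksum of a numeric matrix (content-addressed, text-based)
digestMatrix <- function(m) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.table(m, tmp, sep = "\t", quote = FALSE)
  unname(tools::md5sum(tmp))
}

writePipelineOutputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(out$qc$report, "qc_report.tsv")
  wt(out$de, "de.tsv")
  wt(out$dmp, "dmp.tsv")
  wt(out$dmrs, "dmrs.tsv")
  if (!is.null(out$dmrs)) writeRegionsBED(out$dmrs[out$dmrs$signif, ,
                                                   drop = FALSE],
                                          file.path(outdir, "dmrs.bed"))
  wt(out$eqtm, "eqtm.tsv")
  wt(out$gsea, "gsea.tsv")
  wt(out$clusters, "gsea_clusters.tsv")
  enr <- out$enrichment
  wt(data.frame(test = names(enr),
                statistic = vapply(enr, function(e) e$statistic %||% NA_real_, 0),
                df = vapply(enr, function(e) (e$df %||% NA_real_) + 0, 0),
                p = vapply(enr, function(e) e$p, 0)),
     "chromosome_enrichment.tsv")
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
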