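#' Read a feature-by-sample matrix from TSV
#'
#' Expects features as rows (first column = feature id), samples as
#' columns with a header row of sample ids. `kind = "counts"` enforces
#' non-negative integer cells; `kind = "beta"` enforces values in \[0,1\].
#' Row and column order of the file is preserved.
#'
#' @param path TSV file path.
#' @param kind `"counts"` or `"beta"`.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readMatrixTSV <- function(path, kind = c("counts", "beta")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicate feature id '%s' in %s", ids[duplicated(ids)][1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stopf("non-numeric cell at row '%s', column '%s' in %s",
          ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path)
  }
  rownames(m) <- ids
  if (kind == "counts") {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stopf("count cell at row '%s', column '%s' is not a non-negative integer",
            ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
    storage.mode(m) <- "integer"
  } else {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad))
      stopf("beta cell at row '%s', column '%s' is outside [0,1]",
            ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  }
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [readMatrixTSV()]: first column `feature_id`, then one
#' column per sample.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes.
#' Duplicate members within a set are dropped; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stopf("GMT line %d has fewer than 3 fields", which(short)[1L])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name '%s'", nm[duplicated(nm)][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (recycled `"na"`).
#' @export
writeGMT <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, d, s) paste(c(nm, d, s), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Annotate a genomic region to nearby genes
#'
#' Pairs a region with every gene whose span, extended by `window` bp on
#' both sides, overlaps it by at least 1 bp (1-based inclusive
#' coordinates, as in the cis-window rule of the integrative analysis).
#' Each pair is categorised: `"promoter"` if the region overlaps the
#' strand-aware interval \[TSS - 2000, TSS\], else `"gene_body"` if it
#' overlaps the gene span, else `"flanking"`. When a region overlaps both
#' promoter and body, promoter wins.
#'
#' @param regions `GRanges` or data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally a region id column (`dmr_id` or
#'   `name`).
#' @param genes `GRanges` gene annotation with `gene_id` metadata (as in
#'   [geneAnnotation()]).
#' @param window flank in bp added to each gene span (default 2000).
#' @return data.frame with `region_id`, `gene_id`, `category`.
#' @export
annotateRegionToGenes <- function(regions, genes, window = 2000) {
  gr <- .asRegionGRanges(regions)
  if (!length(gr))
    return(data.frame(region_id = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(GenomicRanges::start(genes) - window, 1L),
                     GenomicRanges::end(genes) + window))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, ext, ignore.strand = TRUE))
  if (!length(hits))
    return(data.frame(region_id = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  plus <- as.character(GenomicRanges::strand(genes)[si]) != "-"
  tss <- ifelse(plus, GenomicRanges::start(genes)[si],
                GenomicRanges::end(genes)[si])
  prom_lo <- ifelse(plus, pmax(tss - 2000L, 1L), tss)
  prom_hi <- ifelse(plus, tss, tss + 2000L)
  rs <- GenomicRanges::start(gr)[qi]; re <- GenomicRanges::end(gr)[qi]
  in_prom <- re >= prom_lo & rs <= prom_hi
  in_body <- re >= GenomicRanges::start(genes)[si] &
             rs <= GenomicRanges::end(genes)[si]
  category <- ifelse(in_prom, "promoter",
                     ifelse(in_body, "gene_body", "flanking"))
  data.frame(region_id = names(gr)[qi] %||% as.character(qi),
             gene_id = genes$gene_id[si], category = category,
             stringsAsFactors = FALSE)
}

.asRegionGRanges <- function(regions) {
  if (is(regions, "GRanges")) {
    if (is.null(names(regions))) {
      nm <- regions$dmr_id %||% regions$name %||%
        as.character(seq_along(regions))
      names(regions) <- nm
    }
    return(regions)
  }
  regions <- as.data.frame(regions)
  if (!nrow(regions))
    return(GenomicRanges::GRanges())
  id <- regions$dmr_id %||% regions$name %||% regions$region_id %||%
    as.character(seq_len(nrow(regions)))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  names(gr) <- id
  gr
}

#' Export regions as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end`). The name column carries the
#' region id and the score column `-log10(fdr)` capped at 1000 (0 when no
#' `fdr` column is present).
#'
#' @param regions data.frame with `chrom`, `start`, `end`, a region id
#'   column and optionally `fdr`.
#' @param path output path.
#' @export
writeRegionsBED <- function(regions, path) {
  regions <- as.data.frame(regions)
  if (!nrow(regions)) {
    file.create(path)
    return(invisible(path))
  }
  id <- regions$dmr_id %||% regions$name %||% as.character(seq_len(nrow(regions)))
  score <- if (!is.null(regions$fdr)) pmin(-log10(regions$fdr), 1000)
           else regions$score %||% 0
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end, id, score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back to the internal 1-based inclusive convention
#' @param path BED path (first 5 columns used).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`.
#' @export
readRegionsBED <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(chrom = df[[1L]], start = df[[2L]] + 1L, end = df[[3L]],
             name = if (ncol(df) >= 4) as.character(df[[4L]]) else NA_character_,
             score = if (ncol(df) >= 5) df[[5L]] else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read a sample sheet TSV
#' @param path TSV with columns `sample_id`, `condition`, `sex`, optional
#'   `batch`.
#' @return `DataFrame` with `condition` releveled to `control` reference.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "sex")
  if (!all(need %in% names(df)))
    stopf("sample sheet must contain columns: %s", paste(need, collapse = ", "))
  df$condition <- factor(df$condition, levels = c("control", "DS"))
  df$sex <- factor(df$sex)
  if (!is.null(df$batch)) df$batch <- factor(df$batch)
  as(df, "DataFrame")
}

#' Read gene annotation TSV into GRanges
#' @param path TSV with `gene_id`, `chrom`, `start`, `end`, `strand` and
#'   optional `symbol`, `marker_class`, `thyroid_related`.
#' @return `GRanges` as used by [geneAnnotation()].
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
    strand = df$strand, gene_id = df$gene_id,
    symbol = df$symbol %||% df$gene_id,
    marker_class = df$marker_class %||% "none",
    thyroid_related = df$thyroid_related %||% FALSE)
  names(gr) <- df$gene_id
  gr
}

#' Read CpG annotation TSV into GRanges
#' @param path TSV with `probe_id`, `chrom`, `position` and the four
#'   filter flags.
#' @return `GRanges` as used by [cpgAnnotation()].
#' @export
readCpGAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$position, df$position),
    probe_id = df$probe_id,
    flag_allosomal = df$flag_allosomal %||% FALSE,
    flag_chr21 = df$flag_chr21 %||% FALSE,
    flag_polymorphic = df$flag_polymorphic %||% FALSE,
    flag_crossreactive = df$flag_crossreactive %||% FALSE)
  names(gr) <- df$probe_id
  gr
}

#' Write a simulated study to a directory of TSV files
#'
#' Writes `counts.tsv`, `betas.tsv`, `samples.tsv`, `genes.tsv`,
#' `cpgs.tsv` and the truth ledger tables (`truth_*.tsv`).
#'
#' @param study a [TrisomyStudy-class].
#' @param dir output directory (created if needed).
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTSV(studyCounts(study), file.path(dir, "counts.tsv"))
  writeMatrixTSV(studyBetas(study), file.path(dir, "betas.tsv"))
  utils::write.table(as.data.frame(sampleSheet(study)),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- geneAnnotation(study)
  utils::write.table(
    data.frame(gene_id = g$gene_id,
               chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g), end = GenomicRanges::end(g),
               strand = as.character(GenomicRanges::strand(g)),
               symbol = g$symbol, marker_class = g$marker_class,
               thyroid_related = g$thyroid_related),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- cpgAnnotation(study)
  utils::write.table(
    data.frame(probe_id = cp$probe_id,
               chrom = as.character(GenomicRanges::seqnames(cp)),
               position = GenomicRanges::start(cp),
               flag_allosomal = cp$flag_allosomal,
               flag_chr21 = cp$flag_chr21,
               flag_polymorphic = cp$flag_polymorphic,
               flag_crossreactive = cp$flag_crossreactive),
    file.path(dir, "cpgs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("de_genes", "dmrs", "cis_pairs", "samples")) {
    tab <- truthLedger(study)[[nm]]
    if (!is.null(tab))
      utils::write.table(tab, file.path(dir, paste0("truth_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study back from a directory written by [writeStudy()]
#' @param dir directory path.
#' @return [TrisomyStudy-class] (truth ledger not restored).
#' @export
readStudy <- function(dir) {
  TrisomyStudy(
    counts = readMatrixTSV(file.path(dir, "counts.tsv"), "counts"),
    betas = readMatrixTSV(file.path(dir, "betas.tsv"), "beta"),
    samples = readSampleSheet(file.path(dir, "samples.tsv")),
    geneAnno = readGeneAnnotation(file.path(dir, "genes.tsv")),
    cpgAnno = readCpGAnnotation(file.path(dir, "cpgs.tsv")))
}
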