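#' Simulation configuration for a paired trisomy 21 study
#'
#' Builds and validates the parameter list for [simulateStudy()]. Defaults
#' describe a small two-group fetal-tissue study: 6 trisomic (DS) and 6
#' control samples of which two DS samples are contaminated with a
#' skeletal-muscle-like expression profile and one control sample is a
#' gross expression outlier, leaving 4 DS vs 5 controls after quality
#' control. All chromosome-21 genes carry a 1.5x dosage effect; additional
#' differential expression, differentially methylated regions (DMRs) and
#' cis methylation-to-expression effects of both signs are planted and
#' recorded in a truth ledger.
#'
#' @param n_ds,n_control samples per group.
#' @param n_genes,n_chr21_genes total genes and genes placed on chr21.
#' @param dosage_factor multiplicative expression effect of the extra
#'   chromosome on affected chr21 genes in DS samples (default 1.5, the
#'   three-copy dosage expectation).
#' @param frac_chr21_dosage_affected fraction of chr21 genes carrying the
#'   dosage effect (default 1: trisomy acts chromosome-wide).
#' @param n_planted_de number of non-chr21 genes with a planted log2 fold
#'   change drawn from `planted_lfc_range` (random sign).
#' @param planted_lfc_range length-2 numeric, |log2FC| interval.
#' @param nb_dispersion negative-binomial dispersion alpha (Var =
#'   mu + alpha mu^2).
#' @param library_size_range length-2 numeric, per-sample library scale
#'   drawn uniformly.
#' @param n_cpgs total CpG probes.
#' @param n_planted_dmrs,dmr_n_cpgs,dmr_delta_beta planted DMRs: count,
#'   CpGs per DMR (>= 3) and group beta difference (DS - control;
#'   hyper/hypo sign assigned per DMR).
#' @param beta_noise_sd per-sample methylation noise SD on the logit
#'   (M-value) scale; beta values are back-transformed so they stay in
#'   \[0,1\].
#' @param n_cis_effects number of planted DMRs whose median methylation is
#'   coupled to a nearby gene's expression.
#' @param cis_effect_slope_signs signs used (recycled) for the cis slopes.
#' @param cis_effect_slope |slope| of the coupling, log2 expression units
#'   per beta unit.
#' @param sex_effect_sd SD of per-feature additive sex effects (log2 scale
#'   for expression, logit scale for methylation).
#' @param batch_effect_sd SD of the per-CpG surrogate batch effect (logit
#'   scale); batches are balanced across condition.
#' @param n_contaminant_samples DS samples whose thyroid/muscle marker
#'   expression is swapped (plus a tissue-mixture perturbation).
#' @param n_outlier_samples control samples given an inflated-variance
#'   expression profile (`outlier_noise_sd` log2 units per gene).
#' @param outlier_noise_sd,contaminant_shift_sd perturbation magnitudes.
#' @param seed integer root seed; all randomness flows from it.
#' @return A validated `trisomicsSimConfig` list.
#' @export
simulationConfig <- function(n_ds = 6L, n_control = 6L,
                             n_genes = 2000L, n_chr21_genes = 70L,
                             dosage_factor = 1.5,
                             frac_chr21_dosage_affected = 1,
                             n_planted_de = 140L,
                             planted_lfc_range = c(0.5, 2),
                             nb_dispersion = 0.02,
                             library_size_range = c(5e5, 1e6),
                             n_cpgs = 5000L,
                             n_planted_dmrs = 10L,
                             dmr_n_cpgs = 5L,
                             dmr_delta_beta = 0.15,
                             beta_noise_sd = 0.3,
                             n_cis_effects = 4L,
                             cis_effect_slope_signs = c(-1, 1),
                             cis_effect_slope = 6,
                             sex_effect_sd = 0.1,
                             batch_effect_sd = 0.5,
                             n_contaminant_samples = 2L,
                             n_outlier_samples = 1L,
                             outlier_noise_sd = 1.5,
                             contaminant_shift_sd = 1,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_ds", "n_control", "n_genes", "n_chr21_genes",
              "n_planted_de", "n_cpgs", "n_planted_dmrs", "dmr_n_cpgs",
              "n_cis_effects", "n_contaminant_samples", "n_outlier_samples")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stopf("config field '%s' must be a single non-negative integer", f)
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$n_chr21_genes > cfg$n_genes)
    stopf("n_chr21_genes exceeds n_genes")
  if (cfg$frac_chr21_dosage_affected < 0 || cfg$frac_chr21_dosage_affected > 1)
    stopf("frac_chr21_dosage_affected must lie in [0,1]")
  if (cfg$dosage_factor <= 0) stopf("dosage_factor must be positive")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$beta_noise_sd < 0) stopf("beta_noise_sd must be non-negative")
  if (cfg$dmr_n_cpgs < 3L && cfg$n_planted_dmrs > 0L)
    stopf("dmr_n_cpgs must be >= 3 (region definition)")
  if (cfg$n_cis_effects > cfg$n_planted_dmrs)
    stopf("n_cis_effects cannot exceed n_planted_dmrs")
  if (!all(cfg$cis_effect_slope_signs %in% c(-1, 1)))
    stopf("cis_effect_slope_signs must be a subset of {-1, +1}")
  needed <- cfg$n_planted_de + cfg$n_cis_effects + 6L + cfg$n_chr21_genes
  if (needed > cfg$n_genes)
    stopf("n_genes too small for the requested planted structure (%d needed)",
          needed)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "trisomicsSimConfig"
  cfg
}

# lay genes out on a toy genome of 24 chromosomes, non-overlapping spans
.layoutGenes <- function(cfg) {
  n <- cfg$n_genes
  n_y <- max(5L, round(0.005 * n))
  n_x <- round(0.02 * n)
  autos <- paste0("chr", setdiff(1:22, 21))
  n_rest <- n - cfg$n_chr21_genes - n_x - n_y
  chrom <- c(rep("chr21", cfg$n_chr21_genes),
             rep("chrX", n_x), rep("chrY", n_y),
             rep(autos, length.out = n_rest))
  chrom <- factor(chrom, levels = paste0("chr", c(1:22, "X", "Y")))
  len <- sample(2000:20000, n, replace = TRUE)
  gap <- sample(5000:30000, n, replace = TRUE)
  start <- integer(n); end <- integer(n)
  for (ch in levels(chrom)) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    s <- 100000L + cumsum(c(0L, (len + gap)[idx[-length(idx)]]))
    start[idx] <- s
    end[idx] <- s + len[idx] - 1L
  }
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = as.character(chrom), start = start, end = end,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a paired expression + methylation trisomy study
#'
#' Generates a [TrisomyStudy-class] with negative-binomial counts and
#' logit-normal beta values carrying the statistical structure the
#' downstream analysis assumes: a chromosome-wide dosage effect on chr21,
#' planted non-chr21 differentially expressed genes, planted DMRs (runs of
#' consecutive CpGs with a group beta shift), cis DMR-to-gene couplings of
#' both signs, balanced sex and surrogate-batch covariates, and
#' contaminant/outlier samples. Every planted effect is recorded in the
#' truth ledger.
#'
#' @param config a list from [simulationConfig()].
#' @return A [TrisomyStudy-class]; `truthLedger(x)` holds `de_genes`
#'   (gene_id, true_log2fc, type), `dmrs` (dmr_id, chrom, start, end,
#'   probe_ids `;`-joined, true_delta_beta, is_cis), `cis_pairs` (dmr_id,
#'   gene_id, slope_sign), `samples` (sample_id, role) and `batch`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  cfg <- if (inherits(config, "trisomicsSimConfig")) config
         else do.call(simulationConfig, config)
  set.seed(cfg$seed)

  ## ---- samples -------------------------------------------------------
  n_s <- cfg$n_ds + cfg$n_control
  sample_id <- c(sprintf("DS%02d", seq_len(cfg$n_ds)),
                 sprintf("C%02d", seq_len(cfg$n_control)))
  condition <- factor(rep(c("DS", "control"), c(cfg$n_ds, cfg$n_control)),
                      levels = c("control", "DS"))
  sex <- factor(unlist(lapply(c(cfg$n_ds, cfg$n_control), function(k)
    rep_len(c("F", "M"), k))), levels = c("F", "M"))
  batch <- factor(unlist(lapply(c(cfg$n_ds, cfg$n_control), function(k)
    rep_len(c("A", "A", "B", "B"), k))), levels = c("A", "B"))

  contam <- if (cfg$n_contaminant_samples > 0)
    sample_id[seq_len(min(cfg$n_contaminant_samples, cfg$n_ds))] else character()
  outlier <- if (cfg$n_outlier_samples > 0)
    sample_id[cfg$n_ds + seq_len(min(cfg$n_outlier_samples, cfg$n_control))]
    else character()

  ## ---- genes ---------------------------------------------------------
  genes <- .layoutGenes(cfg)
  n_g <- cfg$n_genes
  genes$symbol <- toupper(genes$gene_id)
  genes$marker_class <- "none"
  autosomal <- !(genes$chrom %in% c("chr21", "chrX", "chrY"))
  marker_idx <- sample(which(autosomal), 6L)
  thy <- c("TPO", "TG", "TSHR", "SLC5A5"); mus <- c("MYH1", "MYOD1")
  genes$symbol[marker_idx] <- c(thy, mus)
  genes$marker_class[marker_idx] <- rep(c("thyroid", "muscle"), c(4L, 2L))
  genes$thyroid_related <- genes$marker_class == "thyroid"
  free <- which(autosomal & genes$marker_class == "none")
  genes$thyroid_related[sample(free, min(10L, length(free)))] <- TRUE

  q <- stats::rlnorm(n_g, log(150), 1.2)          # baseline expression
  q[marker_idx] <- c(rep(3000, 4L), rep(2, 2L))
  q[genes$chrom == "chrY"] <- pmin(q[genes$chrom == "chrY"], 50)

  ## planted non-chr21 DE genes
  pool <- setdiff(which(autosomal), marker_idx)
  de_idx <- sample(pool, cfg$n_planted_de)
  de_lfc <- stats::runif(cfg$n_planted_de, cfg$planted_lfc_range[1],
                         cfg$planted_lfc_range[2]) *
            sample(c(-1, 1), cfg$n_planted_de, replace = TRUE)

  ## cis genes (non-chr21, expressed, long enough to host a promoter DMR)
  cis_pool <- setdiff(pool, de_idx)
  cis_pool <- cis_pool[genes$end[cis_pool] - genes$start[cis_pool] >= 6000]
  cis_idx <- sample(cis_pool, cfg$n_cis_effects)
  q[cis_idx] <- pmax(q[cis_idx], 200)
  cis_sign <- rep_len(cfg$cis_effect_slope_signs, cfg$n_cis_effects)

  ## chr21 dosage-affected genes
  chr21_idx <- which(genes$chrom == "chr21")
  n_aff <- round(cfg$frac_chr21_dosage_affected * length(chr21_idx))
  aff_idx <- if (n_aff > 0 && cfg$dosage_factor != 1)
    sort(sample(chr21_idx, n_aff)) else integer()

  b_sex_g <- stats::rnorm(n_g, 0, cfg$sex_effect_sd)

  ## ---- CpGs ----------------------------------------------------------
  n_dmr <- cfg$n_planted_dmrs
  k_cpg <- cfg$dmr_n_cpgs
  ## DMR hosts: cis genes (promoter clusters) + non-DE gene bodies
  host_pool <- setdiff(pool, c(de_idx, cis_idx))
  host_pool <- host_pool[genes$end[host_pool] - genes$start[host_pool] >= 12000]
  body_hosts <- sample(host_pool, max(0L, n_dmr - cfg$n_cis_effects))

  cpg <- list(); dmr_truth <- list(); dmr_probes <- list()
  cpg_counter <- 0L
  addCluster <- function(ch, pos, beta0, delta) {
    ids <- sprintf("cg%06d", cpg_counter + seq_along(pos))
    cpg_counter <<- cpg_counter + length(pos)
    list(df = data.frame(probe_id = ids, chrom = ch, position = pos,
                         beta0 = beta0, delta = delta,
                         stringsAsFactors = FALSE), ids = ids)
  }
  for (d in seq_len(n_dmr)) {
    is_cis <- d <= cfg$n_cis_effects
    g <- if (is_cis) cis_idx[d] else body_hosts[d - cfg$n_cis_effects]
    if (is_cis) {
      ## promoter cluster: strand-aware, within 1200 bp upstream of TSS
      tss <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      dirn <- if (genes$strand[g] == "+") -1L else 1L
      pos <- tss + dirn * as.integer(seq(200, by = 150, length.out = k_cpg))
      pos <- sort(pos)
    } else {
      mid <- as.integer((genes$start[g] + genes$end[g]) / 2)
      pos <- mid + as.integer(seq(0, by = 150, length.out = k_cpg))
    }
    beta0 <- if (is_cis) stats::runif(1, 0.2, 0.4) else stats::runif(1, 0.4, 0.7)
    sgn <- if (is_cis) 1 else sample(c(-1, 1), 1)   # cis DMRs hypermethylated in DS
    cl <- addCluster(genes$chrom[g], pos, rep(beta0, k_cpg),
                     rep(sgn * cfg$dmr_delta_beta, k_cpg))
    cpg[[length(cpg) + 1L]] <- cl$df
    dmr_probes[[d]] <- cl$ids
    dmr_truth[[d]] <- data.frame(
      dmr_id = sprintf("trueDMR%02d", d), chrom = genes$chrom[g],
      start = min(pos), end = max(pos),
      probe_ids = paste(cl$ids, collapse = ";"),
      true_delta_beta = sgn * cfg$dmr_delta_beta,
      is_cis = is_cis, host_gene = genes$gene_id[g],
      stringsAsFactors = FALSE)
  }

  ## background CpGs scattered across the genome (includes flagged probes)
  n_bg <- cfg$n_cpgs - cpg_counter
  if (n_bg < 0) stopf("n_cpgs too small for the planted DMR geometry")
  bg_gene <- sample(n_g, n_bg, replace = TRUE)
  bg_pos <- genes$start[bg_gene] +
    as.integer(stats::runif(n_bg, -3000, 3000 +
                            genes$end[bg_gene] - genes$start[bg_gene]))
  bg_pos <- pmax(bg_pos, 1L)
  bg <- addCluster(genes$chrom[bg_gene], bg_pos,
                   stats::rbeta(n_bg, 2, 2) * 0.8 + 0.1, rep(0, n_bg))
  cpg[[length(cpg) + 1L]] <- bg$df
  cpg <- do.call(rbind, cpg)
  ord <- order(factor(cpg$chrom, levels = paste0("chr", c(1:22, "X", "Y"))),
               cpg$position, cpg$probe_id)
  cpg <- cpg[ord, , drop = FALSE]

  cpg$flag_allosomal <- cpg$chrom %in% c("chrX", "chrY")
  cpg$flag_chr21 <- cpg$chrom == "chr21"
  planted <- cpg$delta != 0
  cpg$flag_polymorphic <- !planted & stats::runif(nrow(cpg)) < 0.02
  cpg$flag_crossreactive <- !planted & stats::runif(nrow(cpg)) < 0.02

  ## ---- methylation matrix -------------------------------------------
  n_c <- nrow(cpg)
  ds <- condition == "DS"
  mean_beta <- matrix(rep(cpg$beta0, n_s), n_c, n_s)
  mean_beta[, ds] <- mean_beta[, ds] + cpg$delta
  mean_beta <- pmin(pmax(mean_beta, 0.02), 0.98)
  b_sex_c <- stats::rnorm(n_c, 0, cfg$sex_effect_sd)
  b_bat_c <- stats::rnorm(n_c, 0, cfg$batch_effect_sd)
  ## biological methylation state (drives cis expression coupling) vs
  ## measured beta values, which additionally carry the technical batch
  ## effect the surrogate-variable step is meant to capture
  logit_bio <- stats::qlogis(mean_beta) +
    outer(b_sex_c, as.numeric(sex == "M")) +
    matrix(stats::rnorm(n_c * n_s, 0, cfg$beta_noise_sd), n_c, n_s)
  betas_bio <- stats::plogis(logit_bio)
  betas <- stats::plogis(logit_bio + outer(b_bat_c, as.numeric(batch == "B")))
  dimnames(betas) <- dimnames(betas_bio) <- list(cpg$probe_id, sample_id)

  ## ---- expression matrix --------------------------------------------
  lfc <- matrix(0, n_g, n_s)            # per-gene, per-sample log2 modifier
  if (length(aff_idx))
    lfc[aff_idx, ds] <- lfc[aff_idx, ds] + log2(cfg$dosage_factor)
  lfc[de_idx, ds] <- lfc[de_idx, ds] + de_lfc
  ## cis coupling: gene expression follows realized DMR median methylation
  cis_true_lfc <- numeric(cfg$n_cis_effects)
  for (d in seq_len(cfg$n_cis_effects)) {
    med <- apply(betas_bio[dmr_probes[[d]], , drop = FALSE], 2, stats::median)
    slope <- cis_sign[d] * cfg$cis_effect_slope
    lfc[cis_idx[d], ] <- lfc[cis_idx[d], ] + slope * (med - mean(med))
    cis_true_lfc[d] <- slope * (mean(med[ds]) - mean(med[!ds]))
  }
  lfc <- lfc + outer(b_sex_g, as.numeric(sex == "M"))
  chrY <- genes$chrom == "chrY"
  lfc[chrY, sex == "F"] <- lfc[chrY, sex == "F"] + log2(0.02)
  ## sample perturbations
  qmat <- matrix(rep(q, n_s), n_g, n_s)
  for (s in match(contam, sample_id)) {
    qmat[marker_idx[1:4], s] <- 2      # thyroid markers off
    qmat[marker_idx[5:6], s] <- 3000   # muscle markers on
    lfc[-marker_idx, s] <- lfc[-marker_idx, s] +
      stats::rnorm(n_g - 6L, 0, cfg$contaminant_shift_sd)
  }
  for (s in match(outlier, sample_id))
    lfc[, s] <- lfc[, s] + stats::rnorm(n_g, 0, cfg$outlier_noise_sd)

  lib <- stats::runif(n_s, cfg$library_size_range[1], cfg$library_size_range[2])
  L <- lib / mean(cfg$library_size_range)
  mu <- qmat * 2^lfc * rep(L, each = n_g)
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu,
                                  size = 1 / cfg$nb_dispersion), n_g, n_s)
  dimnames(counts) <- list(genes$gene_id, sample_id)

  ## ---- annotation objects -------------------------------------------
  geneGR <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id, symbol = genes$symbol,
    marker_class = genes$marker_class, thyroid_related = genes$thyroid_related)
  names(geneGR) <- genes$gene_id
  cpgGR <- GenomicRanges::GRanges(
    cpg$chrom, IRanges::IRanges(cpg$position, cpg$position),
    probe_id = cpg$probe_id, flag_allosomal = cpg$flag_allosomal,
    flag_chr21 = cpg$flag_chr21, flag_polymorphic = cpg$flag_polymorphic,
    flag_crossreactive = cpg$flag_crossreactive)
  names(cpgGR) <- cpg$probe_id

  ## ---- truth ledger --------------------------------------------------
  de_truth <- rbind(
    if (length(aff_idx)) data.frame(gene_id = genes$gene_id[aff_idx],
      true_log2fc = log2(cfg$dosage_factor), type = "chr21_dosage",
      stringsAsFactors = FALSE),
    if (cfg$n_planted_de > 0) data.frame(gene_id = genes$gene_id[de_idx],
      true_log2fc = de_lfc, type = "planted", stringsAsFactors = FALSE),
    if (cfg$n_cis_effects > 0) data.frame(gene_id = genes$gene_id[cis_idx],
      true_log2fc = cis_true_lfc, type = "cis", stringsAsFactors = FALSE))
  if (is.null(de_truth))
    de_truth <- data.frame(gene_id = character(), true_log2fc = numeric(),
                           type = character(), stringsAsFactors = FALSE)
  dmr_truth <- if (length(dmr_truth)) do.call(rbind, dmr_truth) else
    data.frame(dmr_id = character(), chrom = character(), start = integer(),
               end = integer(), probe_ids = character(),
               true_delta_beta = numeric(), is_cis = logical(),
               host_gene = character(), stringsAsFactors = FALSE)
  cis_pairs <- if (cfg$n_cis_effects > 0) data.frame(
    dmr_id = dmr_truth$dmr_id[seq_len(cfg$n_cis_effects)],
    gene_id = genes$gene_id[cis_idx], slope_sign = cis_sign,
    stringsAsFactors = FALSE) else
    data.frame(dmr_id = character(), gene_id = character(),
               slope_sign = numeric(), stringsAsFactors = FALSE)
  sample_truth <- data.frame(
    sample_id = c(contam, outlier),
    role = rep(c("contaminant", "outlier"), c(length(contam), length(outlier))),
    stringsAsFactors = FALSE)

  TrisomyStudy(
    counts = counts, betas = betas,
    samples = S4Vectors::DataFrame(sample_id = sample_id,
                                   condition = condition, sex = sex,
                                   batch = batch),
    geneAnno = geneGR, cpgAnno = cpgGR,
    truth = list(de_genes = de_truth, dmrs = dmr_truth,
                 cis_pairs = cis_pairs, samples = sample_truth,
                 batch = stats::setNames(as.character(batch), sample_id)),
    metadata = list(config = unclass(cfg), seed = cfg$seed))
}
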