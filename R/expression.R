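#' RPKM normalization
#'
#' `RPKM_gs = counts_gs / (length_g/1000 * total_s/1e6)` — reads per kilobase
#' of exonic model per million mapped reads.
#'
#' @param counts gene x sample count matrix.
#' @param lengths exonic length (bp) per gene, aligned to rows.
#' @param totals mapped reads per sample; default the column sums.
#' @return RPKM matrix of the same shape.
#' @export
rpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("lengths must align with the rows of counts")
  }
  if (any(lengths <= 0)) stop("gene exonic lengths must be > 0")
  if (any(totals <= 0)) stop("sample totals must be > 0")
  sweep(counts / (lengths / 1000), 2L, totals / 1e6, "/")
}

#' Expressed-gene filter
#'
#' A gene is kept iff its RPKM reaches `threshold` in at least one sample
#' ("below threshold in all samples" is discarded; equality counts as
#' expressed). When `gene_type` is supplied, non-protein-coding genes are
#' removed first.
#'
#' @param rpkm_matrix gene x sample RPKM matrix with gene rownames.
#' @param threshold RPKM cutoff (default 1.2).
#' @param gene_type optional per-gene type labels aligned to rows; only
#'   `"protein_coding"` genes are considered when given.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(rpkm_matrix, threshold = 1.2, gene_type = NULL) {
  m <- as.matrix(rpkm_matrix)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(gene_type)) keep <- keep & gene_type == "protein_coding"
  keep <- keep & apply(m, 1L, max) >= threshold
  rownames(m)[keep]
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the per-gene geometric mean,
#' computed over genes with all-positive counts.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(exp(sweep(logc, 1L, geo, "-")), 2L, stats::median)
}

#' Negative-binomial Wald test of differential expression
#'
#' A compact NB differential test for small designs: counts are normalized
#' by [size_factors()]; the per-gene NB dispersion is estimated by the
#' method of moments from the within-condition variability and shrunk 50/50
#' toward a trend (the median dispersion of genes in the same
#' mean-expression decile); the log2 fold change of normalized condition
#' means (MUT over WT) is tested against zero with a Wald z statistic whose
#' standard error comes from the NB variance function
#' `Var = mu + dispersion * mu^2` via the delta method; p-values are
#' BH-adjusted across tested genes. When a condition mean is zero a
#' pseudo-mean of 0.5 is used inside the log.
#'
#' @param counts gene x sample matrix of non-negative integers (expressed
#'   genes only), with gene rownames.
#' @param condition factor/character vector aligned to columns with exactly
#'   two levels; the first level encountered is the reference (WT).
#' @return `data.frame`: `gene_id`, `base_mean`, `mean_ref`, `mean_alt`,
#'   `dispersion`, `log2fc` (alt minus ref in log2), `se`, `p_value`,
#'   `adj_p`.
#' @export
nb_differential <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  condition <- as.character(condition)
  levs <- unique(condition)
  if (length(levs) != 2L) stop("exactly two conditions are required")
  n_by <- table(condition)
  if (any(n_by < 2L)) {
    stop("each condition needs >= 2 replicates (found ",
         paste(n_by, collapse = ", "), ")")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  ref <- condition == levs[1L]
  mu_ref <- rowMeans(norm[, ref, drop = FALSE])
  mu_alt <- rowMeans(norm[, !ref, drop = FALSE])
  n_ref <- sum(ref); n_alt <- sum(!ref)

  # method-of-moments dispersion from pooled within-condition moments
  var_within <- (apply(norm[, ref, drop = FALSE], 1L, stats::var) * (n_ref - 1) +
                 apply(norm[, !ref, drop = FALSE], 1L, stats::var) * (n_alt - 1)) /
    (n_ref + n_alt - 2)
  mu_bar <- (mu_ref * n_ref + mu_alt * n_alt) / (n_ref + n_alt)
  # raw moment estimate, deliberately unfloored: with 2 replicates it is
  # unbiased in expectation but extremely noisy, so it is only trusted in
  # aggregate (trend) or when it exceeds the trend
  disp_mom <- (var_within - mu_bar) / mu_bar^2
  disp_mom[!is.finite(disp_mom)] <- 0

  # trend: mean moment dispersion within deciles of mean expression (the
  # mean, unlike the median, is unbiased for few-replicate designs)
  decile <- cut(rank(mu_bar, ties.method = "first"),
                breaks = seq(0, length(mu_bar), length.out = 11L),
                labels = FALSE, include.lowest = TRUE)
  trend <- pmax(1e-8, stats::ave(disp_mom, decile, FUN = mean))
  # 50/50 blend of the per-gene estimate with the trend, floored at the
  # trend: per-gene information can raise the dispersion (outlier guard)
  # but never pushes the standard error below the trend
  dispersion <- pmax(0.5 * disp_mom + 0.5 * trend, trend)

  m_ref <- ifelse(mu_ref > 0, mu_ref, 0.5)
  m_alt <- ifelse(mu_alt > 0, mu_alt, 0.5)
  log2fc <- log2(m_alt) - log2(m_ref)
  # delta method on log2 of NB means: Var(log2 muhat) ~= Var(muhat)/(mu ln2)^2
  se2 <- ((1 / m_ref + dispersion) / n_ref +
          (1 / m_alt + dispersion) / n_alt) / log(2)^2
  se <- sqrt(se2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(counts),
             base_mean = mu_bar, mean_ref = mu_ref, mean_alt = mu_alt,
             dispersion = dispersion, log2fc = log2fc, se = se,
             p_value = p, adj_p = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Call up/down/unchanged genes
#'
#' `up` iff `log2fc >= fc_threshold` and `adj_p <= alpha`; `down` iff
#' `log2fc <= -fc_threshold` and `adj_p <= alpha`; `unchanged` otherwise
#' (non-strict inequalities).
#'
#' @param results output of [nb_differential()].
#' @param fc_threshold absolute log2 fold-change cutoff (default 0.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return `results` with a `status` column appended.
#' @export
call_changing <- function(results, fc_threshold = 0.5, alpha = 0.05) {
  status <- rep("unchanged", nrow(results))
  sig <- !is.na(results$adj_p) & results$adj_p <= alpha
  status[sig & results$log2fc >= fc_threshold] <- "up"
  status[sig & results$log2fc <= -fc_threshold] <- "down"
  results$status <- status
  results
}

#' Full expression analysis: RPKM filter plus NB differential test
#'
#' Applies the protein-coding and expressed-gene filters, tests the
#' expressed genes with [nb_differential()], calls changing genes with
#' [call_changing()], and reports every input gene with `status`
#' `"not_expressed"` for the filtered-out ones.
#'
#' @param counts gene x sample count matrix (all genes).
#' @param lengths exonic lengths (bp) aligned to rows.
#' @param condition per-sample condition labels (two levels, first = WT).
#' @param gene_type optional per-gene type labels.
#' @param expressed_threshold RPKM cutoff (default 1.2).
#' @param fc_threshold,alpha cutoffs for [call_changing()].
#' @return list with `results` (per-gene table incl. `status` and per-sample
#'   RPKM attached as `rpkm`), `expressed` (gene ids), `rpkm` (full matrix).
#' @export
expression_pipeline <- function(counts, lengths, condition, gene_type = NULL,
                                expressed_threshold = 1.2, fc_threshold = 0.5,
                                alpha = 0.05) {
  counts <- as.matrix(counts)
  rk <- rpkm(counts, lengths)
  expressed <- filter_expressed(rk, threshold = expressed_threshold,
                                gene_type = gene_type)
  de <- nb_differential(counts[expressed, , drop = FALSE], condition)
  de <- call_changing(de, fc_threshold = fc_threshold, alpha = alpha)
  all_genes <- rownames(counts)
  res <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  res <- merge(res, de, by = "gene_id", all.x = TRUE, sort = FALSE)
  res$status[is.na(res$status)] <- "not_expressed"
  res <- res[match(all_genes, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, expressed = expressed, rpkm = rk)
}
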