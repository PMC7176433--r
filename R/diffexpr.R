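# Gene-level expression from poly(A)-site counts and a SIMPLIFIED
# negative-binomial differential-expression test. The test is a documented
# stand-in for a full NB GLM package: median-of-ratios size factors,
# method-of-moments dispersion, Wald statistic with a normal reference --
# no dispersion shrinkage, no outlier or independent filtering.

#' Aggregate site counts to gene counts
#'
#' Gene count = exact integer sum of reads over all annotated sites of the
#' gene (pre-APA-filter, post-annotation table).
#'
#' @param counts site-count table.
#' @return data.frame: `gene_id` plus one integer column per sample.
#' @export
aggregate_gene_counts <- function(counts) {
  samples <- sample_columns(counts)
  dt <- data.table::as.data.table(counts[, c("gene_id", samples)])
  agg <- dt[, lapply(.SD, sum), by = "gene_id", .SDcols = samples]
  data.table::setorderv(agg, "gene_id")
  as.data.frame(agg)
}

#' Drop genes below an average-count threshold
#'
#' Keeps genes whose mean raw count across ALL samples (conditions pooled)
#' is at least `min_avg`.
#'
#' @param gene_counts output of [aggregate_gene_counts()].
#' @param min_avg minimum mean count (default 2).
#' @return Filtered gene-count table.
#' @export
filter_low_expression <- function(gene_counts, min_avg = 2) {
  samples <- setdiff(names(gene_counts), "gene_id")
  m <- as.matrix(gene_counts[, samples, drop = FALSE])
  out <- gene_counts[rowMeans(m) >= min_avg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of count / geometric-mean pseudo
#' reference; genes with a zero anywhere (zero geometric mean) are skipped.
#'
#' @param m genes-by-samples count matrix.
#' @return Named size-factor vector.
#' @export
size_factors <- function(m) {
  m <- as.matrix(m)
  if (any(colSums(m) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no gene has nonzero counts in every sample")
  apply(m, 2L, function(x) exp(median(log(x[use]) - loggeo[use])))
}

#' Simplified negative-binomial differential expression
#'
#' Counts are normalised by [size_factors()]; per-gene dispersion is
#' estimated by method of moments on the normalised counts (within-condition
#' residual variance, floored at 1e-8, reported per gene) and pooled by
#' averaging across genes for the Wald variance -- at 3 samples per
#' condition a per-gene second moment is too noisy for a calibrated normal
#' reference. The Wald statistic on the log2 fold change (treated vs
#' control, with a 0.5 pseudocount on condition means) is referred to the
#' standard normal and BH-adjusted.
#'
#' @param gene_counts gene-count table (`gene_id` + sample columns).
#' @param design two-condition design.
#' @return data.frame: `gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `adj_pvalue`, `dispersion` (per-gene method-of-moments
#'   estimate; simplified stand-in test).
#' @export
nb_differential_expression <- function(gene_counts, design) {
  samples <- setdiff(names(gene_counts), "gene_id")
  design <- validate_design(design, samples)
  m <- as.matrix(gene_counts[, samples, drop = FALSE])
  rownames(m) <- gene_counts$gene_id
  sf <- size_factors(m)
  q <- sweep(m, 2L, sf, "/")

  ctrl <- condition_samples(design, "control")
  trt <- condition_samples(design, "treated")
  base_mean <- rowMeans(q)
  m1 <- rowMeans(q[, ctrl, drop = FALSE])
  m2 <- rowMeans(q[, trt, drop = FALSE])

  # within-condition residual variance (between-condition contrast excluded)
  d <- length(ctrl) + length(trt) - 2L
  v_within <- (rowSums((q[, ctrl, drop = FALSE] - m1)^2) +
                 rowSums((q[, trt, drop = FALSE] - m2)^2)) / d
  inv_sf_mean <- mean(1 / sf)
  disp <- pmax((v_within - base_mean * inv_sf_mean) / base_mean^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  disp_pooled <- max(mean(disp[is.finite(base_mean) & base_mean > 0]), 1e-8)
  eps <- 0.5
  log2fc <- log2((m2 + eps) / (m1 + eps))
  # Var(mean of normalised counts) under NB with per-sample size factors
  var_mean <- function(mu_c, cols) {
    (mu_c * sum(1 / sf[cols]) / length(cols)^2) +
      disp_pooled * mu_c^2 / length(cols)
  }
  v1 <- var_mean(m1, ctrl)
  v2 <- var_mean(m2, trt)
  lfc_se <- sqrt((v1 / (m1 + eps)^2 + v2 / (m2 + eps)^2) / log(2)^2)
  stat <- ifelse(lfc_se > 0, log2fc / lfc_se, 0)
  pvalue <- ifelse(lfc_se > 0, 2 * pnorm(-abs(stat)), 1)
  data.frame(gene_id = gene_counts$gene_id, baseMean = base_mean,
             log2FoldChange = log2fc, lfcSE = lfc_se, stat = stat,
             pvalue = pvalue, adj_pvalue = bh_adjust(pvalue),
             dispersion = disp,
             stringsAsFactors = FALSE)
}

#' Sample PCA coordinates for separation checks
#'
#' PCA of log2(normalised counts + 1), samples as observations.
#'
#' @param gene_counts gene-count table.
#' @param design optional design; adds a `condition` column.
#' @return data.frame of sample coordinates (`PC1`, `PC2`, ...) with
#'   attribute `variance_explained`.
#' @export
pca_samples <- function(gene_counts, design = NULL) {
  samples <- setdiff(names(gene_counts), "gene_id")
  m <- as.matrix(gene_counts[, samples, drop = FALSE])
  q <- sweep(m, 2L, size_factors(m), "/")
  pc <- prcomp(t(log2(q + 1)), center = TRUE, scale. = FALSE)
  out <- data.frame(sample = samples, pc$x[, seq_len(min(4L, ncol(pc$x))),
                                           drop = FALSE])
  if (!is.null(design)) {
    design <- validate_design(design, samples)
    out$condition <- design$condition[match(out$sample, design$sample)]
  }
  attr(out, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  rownames(out) <- NULL
  out
}
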