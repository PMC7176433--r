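# Weighted mRNA length score: per-gene, per-sample weighted sum of site cpm
# with weights decreasing linearly from 1 (most distal site) to 0 (most
# proximal), and the derived relative length change treated - control.

#' Linear distal-first site weights
#'
#' `W_i = 1 - (i - 1) / (NS - 1)` for a gene with NS poly(A) sites indexed
#' distal-first (i = 1 the most distal). A single-site gene gets the single
#' weight 1 (such genes never enter APA testing).
#'
#' @param ns number of poly(A) sites (>= 1).
#' @return Numeric weight vector of length `ns`.
#' @export
site_weights <- function(ns) {
  if (length(ns) != 1L || !is.finite(ns) || ns <= 0)
    stop("ns must be a positive integer")
  ns <- as.integer(ns)
  if (ns == 1L) return(1)
  1 - (seq_len(ns) - 1) / (ns - 1)
}

#' Per-sample mRNA length score of one gene
#'
#' `score[sample] = sum_i W_i * cpm[i, sample]` with rows ordered
#' distal-first.
#'
#' @param cpm sites-by-samples cpm matrix, rows ordered distal-first.
#' @param weights weight vector from [site_weights()] (defaults to
#'   `site_weights(nrow(cpm))`).
#' @return Named per-sample score vector.
#' @export
gene_length_score <- function(cpm, weights = site_weights(nrow(cpm))) {
  m <- as.matrix(cpm)
  if (length(weights) != nrow(m))
    stop("weights length must equal the number of sites")
  colSums(m * weights)
}

#' Length scores for every gene in a cpm table
#'
#' By default the score is the weighted cpm sum exactly as defined (so
#' expression changes leak into it). `proportion = TRUE` is an optional
#' normalised variant using within-gene usage fractions instead of cpm,
#' bounding scores in `[0, 1]`; it is the scale on which the motif module's
#' non-target cutoff of 0.05 is interpreted.
#'
#' @param cpm site-level cpm table (from [cpm_normalize()]); raw counts are
#'   equally valid when `proportion = TRUE`.
#' @param proportion use per-sample within-gene usage fractions.
#' @return data.frame: `gene_id`, `ns`, one score column per sample.
#' @export
length_scores <- function(cpm, proportion = FALSE) {
  samples <- sample_columns(cpm)
  rows <- lapply(unique(cpm$gene_id), function(g) {
    sub <- cpm[cpm$gene_id == g, , drop = FALSE]
    sub <- sub[order(sub$site_index), , drop = FALSE]
    m <- as.matrix(sub[, samples, drop = FALSE])
    if (proportion) {
      tot <- colSums(m)
      m <- sweep(m, 2L, ifelse(tot > 0, tot, 1), "/")
    }
    sc <- gene_length_score(m)
    row <- data.frame(gene_id = g, ns = nrow(sub), stringsAsFactors = FALSE)
    row[samples] <- as.list(sc)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative mRNA length change per gene
#'
#' Mean score over treated samples minus mean over control samples;
#' negative values indicate 3'-UTR shortening. When APA test results are
#' supplied the table is joined and each gene called `shortened`,
#' `lengthened` (significant at `alpha`) or `ns`.
#'
#' @param scores per-gene score table from [length_scores()].
#' @param design two-condition design.
#' @param apa_results optional output of [lrt_apa()].
#' @param alpha adjusted-p significance threshold for the call.
#' @return data.frame: `gene_id`, `ns`, `mean_control`, `mean_treated`,
#'   `length_change`, and (with results) `lr`, `p_value`, `p_adjusted`,
#'   `call`.
#' @export
relative_length_change <- function(scores, design, apa_results = NULL,
                                   alpha = 0.05) {
  design <- validate_design(design, setdiff(names(scores), c("gene_id", "ns")))
  ctrl <- condition_samples(design, "control")
  trt <- condition_samples(design, "treated")
  out <- data.frame(
    gene_id = scores$gene_id,
    ns = scores$ns,
    mean_control = rowMeans(as.matrix(scores[, ctrl, drop = FALSE])),
    mean_treated = rowMeans(as.matrix(scores[, trt, drop = FALSE])),
    stringsAsFactors = FALSE)
  out$length_change <- out$mean_treated - out$mean_control
  if (!is.null(apa_results)) {
    keep <- c("gene_id", "lr", "df", "p_value", "p_adjusted")
    out <- merge(out, apa_results[, keep], by = "gene_id", all.x = TRUE)
    out$call <- ifelse(is.na(out$p_adjusted) | out$p_adjusted >= alpha, "ns",
                       ifelse(out$length_change < 0, "shortened",
                              ifelse(out$length_change > 0, "lengthened",
                                     "ns")))
    out <- out[order(out$p_value), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Chi-square enrichment of shortening among significant APA genes
#'
#' Goodness-of-fit of (n_short, n_long) against equal expectation among
#' genes with `p_adjusted < alpha`; significant genes with exactly zero
#' length change are excluded and counted.
#'
#' @param results output of [relative_length_change()] joined with APA
#'   results (needs `p_adjusted` and `length_change`).
#' @param alpha significance threshold (default 0.05).
#' @return list: `statistic` (chi-square, df = 1), `df`, `p_value` (two
#'   tailed), `n_short`, `n_long`, `n_zero`.
#' @export
shortening_enrichment <- function(results, alpha = 0.05) {
  sig <- results[!is.na(results$p_adjusted) & results$p_adjusted < alpha, ,
                 drop = FALSE]
  n_zero <- sum(sig$length_change == 0)
  n_short <- sum(sig$length_change < 0)
  n_long <- sum(sig$length_change > 0)
  if (n_short + n_long == 0L) {
    warning("no significant genes with non-zero length change")
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                n_short = n_short, n_long = n_long, n_zero = n_zero))
  }
  gof <- chisq_gof(c(n_short, n_long))
  list(statistic = gof$statistic, df = gof$df, p_value = gof$p_value,
       n_short = n_short, n_long = n_long, n_zero = n_zero)
}
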