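# Count-level filtering of poly(A)-site tables, mirroring the three-stage
# rule: low-support sites, minor-usage sites, unexpressed genes; then cpm.

#' Filter sites without minimal read support
#'
#' A site is retained iff, in at least one condition with n samples, the
#' n-1 best-covered samples each have >= `min_major` reads and the remaining
#' sample has >= `min_minor` reads (for n = 3: "five reads in two samples
#' and one read in the remaining sample").
#'
#' @param counts site-count table.
#' @param design two-condition design (`sample`, `condition`).
#' @param min_major read threshold for the n-1 best-covered samples.
#' @param min_minor read threshold for the remaining sample.
#' @return Filtered site-count table.
#' @export
filter_low_support_sites <- function(counts, design, min_major = 5L,
                                     min_minor = 1L) {
  design <- validate_design(design, sample_columns(counts))
  conds <- c("control", "treated")
  for (cc in conds)
    if (length(condition_samples(design, cc)) < 2L)
      stop("filter_low_support_sites requires >= 2 samples per condition")
  keep <- logical(nrow(counts))
  for (cc in conds) {
    m <- as.matrix(counts[, condition_samples(design, cc), drop = FALSE])
    ok <- apply(m, 1L, function(x) {
      x <- sort(x, decreasing = TRUE)
      n <- length(x)
      all(x[seq_len(n - 1L)] >= min_major) && x[n] >= min_minor
    })
    keep <- keep | ok
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter sites carrying a minor share of their gene's reads
#'
#' A site is removed iff its share of the gene's condition-summed reads is
#' below `min_fraction` in BOTH conditions; a condition with zero gene total
#' contributes a share of 0.
#'
#' @inheritParams filter_low_support_sites
#' @param min_fraction minimum within-gene read share (default 0.10).
#' @return Filtered site-count table.
#' @export
filter_minor_usage_sites <- function(counts, design, min_fraction = 0.10) {
  design <- validate_design(design, sample_columns(counts))
  keep <- logical(nrow(counts))
  for (g in unique(counts$gene_id)) {
    rows <- which(counts$gene_id == g)
    below_both <- rep(TRUE, length(rows))
    for (cc in c("control", "treated")) {
      m <- as.matrix(counts[rows, condition_samples(design, cc), drop = FALSE])
      site_sum <- rowSums(m)
      gene_sum <- sum(site_sum)
      frac <- if (gene_sum > 0) site_sum / gene_sum else rep(0, length(rows))
      below_both <- below_both & (frac < min_fraction)
    }
    keep[rows] <- !below_both
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter genes not expressed in both conditions
#'
#' A gene is retained iff the mean (over samples) of its total site count is
#' >= `min_mean` in BOTH conditions. Genes reduced to a single retained site
#' are additionally removed from the APA-testing table (they are untestable)
#' and reported via the `single_site_genes` attribute.
#'
#' @inheritParams filter_low_support_sites
#' @param min_mean minimum per-condition mean of gene totals (default 5).
#' @return Filtered site-count table with attribute `single_site_genes`.
#' @export
filter_unexpressed_genes <- function(counts, design, min_mean = 5) {
  design <- validate_design(design, sample_columns(counts))
  samples <- sample_columns(counts)
  keep_gene <- character(0)
  for (g in unique(counts$gene_id)) {
    rows <- which(counts$gene_id == g)
    ok <- TRUE
    for (cc in c("control", "treated")) {
      m <- as.matrix(counts[rows, condition_samples(design, cc), drop = FALSE])
      if (mean(colSums(m)) < min_mean) { ok <- FALSE; break }
    }
    if (ok) keep_gene <- c(keep_gene, g)
  }
  out <- counts[counts$gene_id %in% keep_gene, , drop = FALSE]
  ns <- table(out$gene_id)
  single <- names(ns)[ns == 1L]
  if (length(single)) {
    message(length(single), " gene(s) reduced to a single site; excluded ",
            "from APA testing (expression analysis only)")
    out <- out[!out$gene_id %in% single, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "single_site_genes") <- single
  out
}

#' Apply the full three-stage APA filter in its fixed order
#'
#' Low-support sites, then minor-usage sites, then unexpressed genes.
#'
#' @inheritParams filter_low_support_sites
#' @param min_fraction,min_mean see the individual filters.
#' @return Filtered site-count table ready for APA testing.
#' @export
apa_filter <- function(counts, design, min_major = 5L, min_minor = 1L,
                       min_fraction = 0.10, min_mean = 5) {
  counts <- filter_low_support_sites(counts, design, min_major, min_minor)
  counts <- filter_minor_usage_sites(counts, design, min_fraction)
  filter_unexpressed_genes(counts, design, min_mean)
}

#' Counts-per-million normalisation
#'
#' cpm[site, sample] = count * 1e6 / (sample's total reads over all retained
#' sites). With `per_gene = TRUE` the denominator is instead the sample's
#' within-gene total (sensitivity-analysis variant).
#'
#' @param counts filtered site-count table.
#' @param per_gene use per-gene denominators instead of library totals.
#' @return Site table with sample columns replaced by cpm values.
#' @export
cpm_normalize <- function(counts, per_gene = FALSE) {
  samples <- sample_columns(counts)
  m <- as.matrix(counts[, samples, drop = FALSE])
  if (per_gene) {
    for (g in unique(counts$gene_id)) {
      rows <- which(counts$gene_id == g)
      tot <- colSums(m[rows, , drop = FALSE])
      if (any(tot == 0))
        tot[tot == 0] <- 1  # empty gene-sample: leave zeros as zeros
      m[rows, ] <- sweep(m[rows, , drop = FALSE], 2L, tot, "/") * 1e6
    }
  } else {
    tot <- colSums(m)
    if (any(tot == 0))
      stop("zero library total for sample(s): ",
           paste(samples[tot == 0], collapse = ", "))
    m <- sweep(m, 2L, tot, "/") * 1e6
  }
  out <- counts
  out[, samples] <- m
  out
}
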