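# Proteomics arm: per-sample median normalisation, consistency filtering,
# downshifted-Gaussian imputation of missing values (Perseus-style),
# empirical-Bayes moderated t-test, and the conditional chi-square battery
# relating protein change to mRNA length change.

#' Median-normalise a linear-scale intensity matrix
#'
#' Each sample's quantified values are scaled so that its median equals the
#' grand median of the pre-scaling per-sample medians; missing entries are
#' untouched.
#'
#' @param intensity proteins-by-samples matrix, NA = missing.
#' @return Normalised matrix.
#' @export
median_normalize <- function(intensity) {
  med <- apply(intensity, 2L, median, na.rm = TRUE)
  if (any(is.na(med)))
    stop("sample(s) with no quantified values: ",
         paste(colnames(intensity)[is.na(med)], collapse = ", "))
  target <- median(med)
  sweep(intensity, 2L, target / med, "*")
}

#' Keep proteins quantified in every sample of at least one condition
#'
#' @param intensity proteins-by-samples matrix, NA = missing.
#' @param design two-condition design matching the columns.
#' @return Row-filtered matrix.
#' @export
filter_consistent <- function(intensity, design) {
  design <- validate_design(design, colnames(intensity))
  keep <- rep(FALSE, nrow(intensity))
  for (cc in c("control", "treated")) {
    cols <- condition_samples(design, cc)
    keep <- keep | apply(!is.na(intensity[, cols, drop = FALSE]), 1L, all)
  }
  intensity[keep, , drop = FALSE]
}

#' Impute missing log2 intensities from a downshifted Gaussian
#'
#' Draws each missing entry independently from
#' `Normal(mean(measured) - downshift * sd(measured), width * sd(measured))`
#' with mean and SD taken over ALL measured log2 values of the matrix.
#' Measured entries are returned bit-identical.
#'
#' @param log2m proteins-by-samples log2 matrix, NA = missing.
#' @param downshift downshift in global SD units (default 2).
#' @param width imputation-width scaling factor (default 1).
#' @param seed RNG seed for the draws.
#' @return list: `log2` (complete matrix), `imputed` (logical mask).
#' @export
impute_missing <- function(log2m, downshift = 2, width = 1, seed = 1L) {
  measured <- log2m[!is.na(log2m)]
  if (length(measured) < 2L) stop("need >= 2 measured values to impute")
  mu <- mean(measured)
  s <- sd(measured)
  if (s == 0) stop("zero SD of measured values; cannot impute")
  miss <- is.na(log2m)
  out <- log2m
  with_seed(seed, {
    out[miss] <- rnorm(sum(miss), mu - downshift * s, width * s)
  })
  list(log2 = out, imputed = miss)
}

# Solve trigamma(x) = y by Newton iteration (y > 0).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t-test (two conditions)
#'
#' Per protein: `log2FC = mean(treated) - mean(control)`; pooled residual
#' variance s^2 with `d = n1 + n2 - 2` df. The prior `(d0, s0^2)` is
#' estimated by moments on `log(s^2)` via digamma/trigamma inversion across
#' proteins; the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated t has `d0 + d` df
#' (`d0 = Inf` encodes no detected variance heterogeneity).
#'
#' @param log2m complete proteins-by-samples log2 matrix.
#' @param design two-condition design.
#' @param prior optional list `(d0, s0_sq)` pinning the prior instead of
#'   estimating it (useful for closed-form checks; `d0 = Inf` allowed).
#' @return list: `table` (data.frame `gene_id`, `log2fc`, `t_mod`,
#'   `df_total`, `p_value`, `p_adjusted`) and `prior` (`d0`, `s0_sq`).
#' @export
moderated_t <- function(log2m, design, prior = NULL) {
  design <- validate_design(design, colnames(log2m))
  if (is.null(rownames(log2m)))
    rownames(log2m) <- paste0("p", seq_len(nrow(log2m)))
  ctrl <- condition_samples(design, "control")
  trt <- condition_samples(design, "treated")
  n1 <- length(ctrl); n2 <- length(trt)
  d <- n1 + n2 - 2L
  if (d <= 0L) stop("zero residual degrees of freedom")
  mc <- rowMeans(log2m[, ctrl, drop = FALSE])
  mt <- rowMeans(log2m[, trt, drop = FALSE])
  log2fc <- mt - mc
  rss <- rowSums((log2m[, ctrl, drop = FALSE] - mc)^2) +
    rowSums((log2m[, trt, drop = FALSE] - mt)^2)
  s2 <- rss / d

  if (!is.null(prior)) {
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
    stopifnot(d0 > 0, s0_sq > 0)
  } else {
    ok <- s2 > 0
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- var(e)
    gap <- evar - trigamma(d / 2)
    if (is.finite(gap) && gap > 0) {
      d0 <- 2 * trigamma_inverse(gap)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  }

  s2_post <- if (is.finite(d0)) (d0 * s0_sq + d * s2) / (d0 + d)
             else rep(s0_sq, length(s2))
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_mod), df = df_total)
  tab <- data.frame(gene_id = rownames(log2m), log2fc = log2fc,
                    t_mod = t_mod, df_total = df_total, p_value = p,
                    p_adjusted = bh_adjust(p), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, prior = list(d0 = d0, s0_sq = s0_sq))
}

#' Conditional chi-square battery on length change vs protein change
#'
#' Step 1: goodness-of-fit of (n_short, n_long) among all significant APA
#' genes (delegates to [shortening_enrichment()]). Steps 2-3 use only
#' significant genes with a quantified protein: step 2 tests the four
#' quadrant counts (length sign x protein sign) against uniform (df = 3);
#' step 3 conditions on shortened genes and tests (protein up, protein
#' down) against equal (df = 1). Genes with zero length or protein change
#' are excluded from the affected steps and counted.
#'
#' @param results [relative_length_change()] output with APA results joined.
#' @param protein [moderated_t()] result table (or any data.frame with
#'   `gene_id` and `log2fc`).
#' @param alpha adjusted-p threshold selecting APA-significant genes.
#' @return list with `step1`, `step2`, `step3` (each `statistic`, `df`,
#'   `p_value`, `counts`) and `n_excluded_zero`.
#' @export
quadrant_tests <- function(results, protein, alpha = 0.05) {
  step1 <- shortening_enrichment(results, alpha = alpha)

  sig <- results[!is.na(results$p_adjusted) & results$p_adjusted < alpha, ,
                 drop = FALSE]
  joined <- merge(sig, protein[, c("gene_id", "log2fc")], by = "gene_id")
  nz <- joined$length_change != 0 & joined$log2fc != 0
  n_excluded <- sum(!nz)
  joined <- joined[nz, , drop = FALSE]

  empty <- list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                counts = NULL)
  if (!nrow(joined)) {
    warning("no significant genes with quantified, non-zero protein change")
    return(list(step1 = step1, step2 = empty, step3 = empty,
                n_excluded_zero = n_excluded))
  }
  short <- joined$length_change < 0
  up <- joined$log2fc > 0
  quad <- c(short_up = sum(short & up), short_down = sum(short & !up),
            long_up = sum(!short & up), long_down = sum(!short & !up))
  g2 <- chisq_gof(quad)
  step2 <- list(statistic = g2$statistic, df = g2$df, p_value = g2$p_value,
                counts = quad)

  if (!any(short)) {
    warning("no shortened genes for the conditional test")
    step3 <- empty
  } else {
    cond <- c(up = sum(short & up), down = sum(short & !up))
    g3 <- chisq_gof(cond)
    step3 <- list(statistic = g3$statistic, df = g3$df, p_value = g3$p_value,
                  counts = cond)
  }
  list(step1 = step1, step2 = step2, step3 = step3,
       n_excluded_zero = n_excluded)
}

#' Full proteomics arm on a raw intensity matrix
#'
#' Median normalisation, consistency filter, log2, downshifted-Gaussian
#' imputation, moderated t-test with BH adjustment.
#'
#' @param intensity linear-scale proteins-by-samples matrix, NA = missing.
#' @param design two-condition design.
#' @param downshift,width,seed imputation parameters, see
#'   [impute_missing()].
#' @return list: `table` (moderated-t results plus `n_imputed` per
#'   protein), `prior`, `log2` (imputed matrix), `imputed` mask.
#' @export
proteome_pipeline <- function(intensity, design, downshift = 2, width = 1,
                              seed = 1L) {
  norm <- median_normalize(intensity)
  cons <- filter_consistent(norm, design)
  imp <- impute_missing(log2(cons), downshift = downshift, width = width,
                        seed = seed)
  mt <- moderated_t(imp$log2, design)
  mt$table$n_imputed <- rowSums(imp$imputed)[match(mt$table$gene_id,
                                                   rownames(imp$log2))]
  list(table = mt$table, prior = mt$prior, log2 = imp$log2,
       imputed = imp$imputed)
}
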