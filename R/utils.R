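#' @importFrom stats pchisq pnorm pt qnorm rbinom rnbinom rnorm runif
#'   median optimize prcomp p.adjust setNames var sd rmultinom rgamma plogis
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Metadata columns of a poly(A)-site count table; everything else is a sample.
PAS_META_COLS <- c("gene_id", "site_index", "contig", "strand",
                   "start", "end", "site_pos")

#' Sample (count) columns of a site-count table
#'
#' A site-count table carries one row per poly(A) site with fixed metadata
#' columns (`gene_id`, `site_index`, `contig`, `strand`, `start`, `end`,
#' `site_pos`) followed by one numeric column per sample.
#'
#' @param x site-count data.frame.
#' @return Character vector of sample column names.
#' @export
sample_columns <- function(x) {
  setdiff(names(x), PAS_META_COLS)
}

#' Validate a two-condition design
#'
#' @param design data.frame with columns `sample` and `condition`; conditions
#'   must be exactly `"control"` and `"treated"`.
#' @param samples optional character vector that `design$sample` must cover.
#' @return The design, with `condition` as character, invisibly checked.
#' @export
validate_design <- function(design, samples = NULL) {
  stopifnot(is.data.frame(design), all(c("sample", "condition") %in% names(design)))
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample))
    stop("duplicated sample ids in design")
  if (!setequal(unique(design$condition), c("control", "treated")))
    stop("design must contain exactly the conditions 'control' and 'treated'")
  if (!is.null(samples) && !all(samples %in% design$sample))
    stop("samples missing from design: ",
         paste(setdiff(samples, design$sample), collapse = ", "))
  design
}

condition_samples <- function(design, condition) {
  design$sample[design$condition == condition]
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a per-artifact sub-seed from the master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  (abs(seed) %% 100000L) * 17761L + k * 7919L
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over the step-up procedure so every module adjusts p-values
#' through one audited entry point.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return Adjusted p-values (FDR), same length.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

# Chi-square goodness-of-fit of observed counts against equal expectation.
chisq_gof <- function(observed) {
  observed <- as.numeric(observed)
  if (any(observed < 0) || all(observed == 0)) {
    return(list(statistic = NA_real_, df = length(observed) - 1L, p_value = NA_real_))
  }
  expected <- rep(sum(observed) / length(observed), length(observed))
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}
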