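# UGUA (CFIm25-binding) motif frequency profiling in +/- 200 nt
# strand-specific windows around per-gene maximum-loss and maximum-gain
# cleavage sites, with width-5 match averaging and Gaussian smoothing.

#' Per-gene maximum-loss / maximum-gain cleavage sites
#'
#' Per site, change = mean treated cpm - mean control cpm; the loss site is
#' the argmin and the gain site the argmax; ties go to the more distal site
#' (smaller distal-first index). A gene where all sites change equally is
#' flagged degenerate (loss = gain = most distal site).
#'
#' @param cpm site-level cpm table (genes with >= 2 sites are used).
#' @param design two-condition design.
#' @return data.frame: `gene_id`, `contig`, `strand`, loss/gain site
#'   position, index and change, `degenerate`.
#' @export
select_shift_sites <- function(cpm, design) {
  design <- validate_design(design, sample_columns(cpm))
  ctrl <- condition_samples(design, "control")
  trt <- condition_samples(design, "treated")
  rows <- lapply(unique(cpm$gene_id), function(g) {
    sub <- cpm[cpm$gene_id == g, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    sub <- sub[order(sub$site_index), , drop = FALSE]  # distal first
    change <- rowMeans(as.matrix(sub[, trt, drop = FALSE])) -
      rowMeans(as.matrix(sub[, ctrl, drop = FALSE]))
    loss <- which(change == min(change))[1L]   # first = most distal on ties
    gain <- which(change == max(change))[1L]
    data.frame(
      gene_id = g, contig = sub$contig[1L], strand = sub$strand[1L],
      loss_pos = sub$site_pos[loss], loss_index = sub$site_index[loss],
      loss_change = change[loss],
      gain_pos = sub$site_pos[gain], gain_index = sub$site_index[gain],
      gain_change = change[gain],
      degenerate = min(change) == max(change),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Strand-specific flanking sequences around cleavage positions
#'
#' For "+" sites the genomic window `[pos - flank, pos + flank]` (0-based,
#' inclusive) is returned as-is; for "-" sites its reverse complement, so
#' that negative profile offsets are always transcript-5' of the cleavage
#' position. Sites whose window would cross a contig edge yield `NA`
#' (dropped; count in attribute `n_dropped`).
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param contig,position,strand parallel vectors (0-based positions).
#' @param flank half-window in nt (default 200; window length 2*flank+1).
#' @return Character vector of sequences (NA = dropped) with attribute
#'   `n_dropped`.
#' @export
extract_flanks <- function(genome, contig, position, strand, flank = 200L) {
  n <- length(position)
  contig <- rep_len(contig, n)
  strand <- rep_len(strand, n)
  widths <- setNames(Biostrings::width(genome), names(genome))
  out <- rep(NA_character_, length(position))
  for (i in seq_along(position)) {
    if (!contig[i] %in% names(genome))
      stop("contig not in genome: ", contig[i])
    lo <- position[i] - flank          # 0-based
    hi <- position[i] + flank
    if (lo < 0L || hi >= widths[[contig[i]]]) next  # truncated: drop
    s <- Biostrings::subseq(genome[[contig[i]]], lo + 1L, hi + 1L)
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  attr(out, "n_dropped") <- sum(is.na(out))
  out
}

#' UGUA match frequency profile with a width-5 sliding window
#'
#' Per offset, the fraction of sequences with a UGUA (DNA: TGTA) match
#' starting there is computed, then mean-filtered with a centred window of
#' `window` offsets (truncated at the profile ends). Positions within 3 of
#' the end cannot start a match and are 0 by construction. U and T are
#' equivalent; N never matches; other letters are an error.
#'
#' @param sequences equal-length character vector (NA entries are ignored).
#' @param window moving-average width in offsets (default 5).
#' @return data.frame: `offset` (centred at 0), `match_freq` (raw
#'   match-start fraction), `raw` (window-averaged frequency),
#'   `n_sequences`.
#' @export
ugua_frequency <- function(sequences, window = 5L) {
  sequences <- sequences[!is.na(sequences)]
  if (!length(sequences)) stop("no sequences")
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must have equal length")
  if (any(grepl("[^ACGTN]", sequences)))
    stop("sequences may contain only A/C/G/T/U/N")
  L <- lens
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sequences), byrow = TRUE)
  match_freq <- numeric(L)
  if (L >= 4L) {
    p <- seq_len(L - 3L)
    hits <- (chars[, p, drop = FALSE] == "T") &
      (chars[, p + 1L, drop = FALSE] == "G") &
      (chars[, p + 2L, drop = FALSE] == "T") &
      (chars[, p + 3L, drop = FALSE] == "A")
    match_freq[p] <- colMeans(hits)
  }
  half <- window %/% 2L
  raw <- vapply(seq_len(L), function(i) {
    j <- max(1L, i - half):min(L, i + half)
    mean(match_freq[j])
  }, numeric(1))
  center <- (L + 1L) %/% 2L
  data.frame(offset = seq_len(L) - center, match_freq = match_freq,
             raw = raw, n_sequences = length(sequences))
}

#' One-dimensional Gaussian smoothing
#'
#' Convolution with a discrete Gaussian kernel truncated at +/- 4 sigma,
#' normalised to sum 1, with reflect boundary handling (edge value
#' duplicated, as in common 1-D Gaussian filters); this preserves the
#' profile mean.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in offsets (> 0, default 20).
#' @return Smoothed numeric vector, same length.
#' @export
gaussian_smooth <- function(x, sigma = 20) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- length(x)
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # reflect index mapping: 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1, ...
  reflect <- function(i) {
    while (any(bad <- i < 1L | i > n)) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > n] <- 2L * n + 1L - i[i > n]
    }
    i
  }
  vapply(seq_len(n), function(i)
    sum(k * x[reflect(i + seq(-r, r))]), numeric(1))
}

#' Grouped UGUA profiles around loss and gain sites
#'
#' Genes are grouped from APA results: `shortened` (p_adjusted < alpha and
#' negative length change), `lengthened` (significant, positive), and
#' `non_target` (non-significant with |length change| <= `nontarget_max`).
#' The cutoff is interpreted on the proportion-based length-change scale
#' (see [length_scores()] with `proportion = TRUE`). For each non-empty
#' group a profile is emitted for the loss site and the gain site.
#'
#' @param results output of [relative_length_change()] with APA results
#'   joined (columns `gene_id`, `p_adjusted`, `length_change`).
#' @param shift_sites output of [select_shift_sites()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank,window,sigma profiling parameters (defaults 200, 5, 20).
#' @param alpha significance threshold (default 0.05).
#' @param nontarget_max maximum |length change| of a non-target (default
#'   0.05).
#' @return Long data.frame: `group`, `site_class` (loss/gain), `offset`,
#'   `match_freq`, `raw`, `smoothed`, `n_sequences`.
#' @export
group_motif_profiles <- function(results, shift_sites, genome, flank = 200L,
                                 window = 5L, sigma = 20,
                                 alpha = 0.05, nontarget_max = 0.05) {
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < alpha
  groups <- list(
    shortened = results$gene_id[sig & results$length_change < 0],
    lengthened = results$gene_id[sig & results$length_change > 0],
    non_target = results$gene_id[!sig &
                                   abs(results$length_change) <= nontarget_max])
  out <- list()
  for (gname in names(groups)) {
    ss <- shift_sites[shift_sites$gene_id %in% groups[[gname]], , drop = FALSE]
    if (!nrow(ss)) {
      warning("empty motif group: ", gname)
      next
    }
    for (cls in c("loss", "gain")) {
      seqs <- extract_flanks(genome, ss$contig, ss[[paste0(cls, "_pos")]],
                             ss$strand, flank = flank)
      if (all(is.na(seqs))) {
        warning("all flanks dropped for group ", gname, " / ", cls)
        next
      }
      prof <- ugua_frequency(seqs, window = window)
      prof$smoothed <- gaussian_smooth(prof$raw, sigma = sigma)
      prof$group <- gname
      prof$site_class <- cls
      out[[paste(gname, cls)]] <- prof
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("group", "site_class", "offset", "match_freq", "raw", "smoothed",
          "n_sequences")]
}
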