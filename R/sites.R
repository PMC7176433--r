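# Cleavage-evidence processing: per-read 3'-end extraction, 15-nt
# single-linkage merging into poly(A)-site features, annotation mapping,
# and genic region classification.

#' Extract per-read cleavage events
#'
#' Each primary, mapped alignment contributes one event at the read's
#' transcriptional 3' end: with `orientation = "forward"` (PAC-seq style)
#' that is the rightmost aligned reference base for "+" alignments and the
#' leftmost for "-"; `orientation = "reverse"` flips both the position rule
#' and the event strand.
#'
#' @param input a cleavage-event data.frame (validated and passed through),
#'   a BED6 path, or a BAM path (requires Rsamtools/GenomicAlignments).
#' @param orientation `"forward"` or `"reverse"` library orientation.
#' @param sample_id sample label for BAM/BED input without per-read names.
#' @return cleavage-event data.frame (`contig`, `position`, `strand`,
#'   `sample_id`).
#' @export
extract_cleavage_events <- function(input, orientation = c("forward", "reverse"),
                                    sample_id = NULL) {
  orientation <- match.arg(orientation)
  if (is.data.frame(input)) {
    ev <- input
  } else if (grepl("\\.bed$", input, ignore.case = TRUE)) {
    ev <- read_cleavage_bed(input, sample_id = sample_id)
  } else if (grepl("\\.[bs]am$", input, ignore.case = TRUE)) {
    ev <- bam_cleavage_events(input, sample_id)
  } else {
    stop("input must be a data.frame, a .bed file or a .bam file")
  }
  stopifnot(all(c("contig", "position", "strand", "sample_id") %in% names(ev)))
  if (any(ev$position < 0)) stop("negative cleavage positions")
  if (!all(ev$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (orientation == "reverse") {
    # the aligned strand is antisense to the transcript
    ev$strand <- ifelse(ev$strand == "+", "-", "+")
  }
  ev
}

bam_cleavage_events <- function(path, sample_id) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("BAM input requires the Rsamtools and GenomicAlignments packages")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                             overwrite = TRUE, indexDestination = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
  total <- Rsamtools::countBam(path)$records
  skipped <- total - length(aln)
  if (skipped > 0)
    warning(skipped, " unmapped/secondary records skipped in ", basename(path))
  strand <- as.character(GenomicAlignments::strand(aln))
  pos <- ifelse(strand == "+",
                GenomicAlignments::end(aln) - 1L,     # rightmost base, 0-based
                GenomicAlignments::start(aln) - 1L)   # leftmost base, 0-based
  data.frame(
    contig = as.character(GenomicAlignments::seqnames(aln)),
    position = as.integer(pos),
    strand = strand,
    sample_id = if (is.null(sample_id))
      sub("\\.bam$", "", basename(path), ignore.case = TRUE) else sample_id,
    stringsAsFactors = FALSE)
}

#' Merge cleavage events within a gap into poly(A)-site features
#'
#' Events from all samples are pooled, then single-linkage clustered per
#' contig and strand: two positions are linked when they are at most `gap`
#' nt apart (inclusive). Each cluster becomes one feature interval
#' `[min, max + 1)` carrying per-sample event counts; counts are conserved.
#'
#' @param events cleavage-event data.frame.
#' @param gap maximum linking distance in nt (default 15).
#' @return An `apa_feature_set`: list with `features` (feature_id, contig,
#'   strand, start, end, one count column per sample) and `position_counts`
#'   (per-position per-sample event counts with their feature_id).
#' @export
merge_cleavage_sites <- function(events, gap = 15L) {
  if (gap < 0) stop("gap must be >= 0")
  stopifnot(all(c("contig", "position", "strand", "sample_id") %in% names(events)))
  dt <- data.table::as.data.table(events)
  samples <- sort(unique(dt$sample_id))
  # per-position per-sample counts, pooled across samples for clustering
  pc <- dt[, list(n = .N), by = c("contig", "strand", "position", "sample_id")]
  data.table::setorderv(pc, c("contig", "strand", "position", "sample_id"))
  pos <- unique(pc[, c("contig", "strand", "position")])
  data.table::setorderv(pos, c("contig", "strand", "position"))
  pos[, cluster := {
    d <- c(0L, diff(position))
    new_grp <- d > gap | c(TRUE, rep(FALSE, .N - 1L))
    cumsum(new_grp)
  }, by = c("contig", "strand")]
  pos[, feature_id := paste0(contig, ":", strand, ":", cluster)]
  pc <- merge(pc, pos, by = c("contig", "strand", "position"), sort = TRUE)
  feat <- pc[, list(start = min(position), end = max(position) + 1L),
             by = c("feature_id", "contig", "strand")]
  wide <- data.table::dcast(pc, feature_id ~ sample_id,
                            value.var = "n", fun.aggregate = sum, fill = 0L)
  for (s in setdiff(samples, names(wide))) wide[[s]] <- 0L
  feat <- merge(feat, wide[, c("feature_id", samples), with = FALSE],
                by = "feature_id", sort = TRUE)
  data.table::setorderv(feat, c("contig", "strand", "start"))
  out <- list(features = as.data.frame(feat),
              position_counts = as.data.frame(
                pc[, c("feature_id", "contig", "strand", "position",
                       "sample_id", "n"), with = FALSE]),
              samples = samples)
  class(out) <- "apa_feature_set"
  out
}

#' Map merged features to an annotated poly(A)-site database
#'
#' Features overlapping at least one annotated 1-bp site on the same strand
#' are kept and assigned that site's gene; non-overlapping features are
#' dropped (count attached as attribute `n_dropped`). A feature overlapping
#' several annotated sites is split: each event goes to the nearest
#' annotated site, ties to the transcript-5'-most site. Within each gene the
#' retained sites get `site_index` 1..NS with 1 = most distal in
#' transcription direction.
#'
#' @param feature_set an `apa_feature_set` from [merge_cleavage_sites()].
#' @param annotation annotation data.frame from [read_pas_annotation()] (or
#'   equivalent: `contig`, `position`, `strand`, `gene_id`).
#' @return site-count table (one row per retained annotated site, metadata
#'   columns plus per-sample counts), ordered by gene and site_index.
#' @export
map_to_annotation <- function(feature_set, annotation) {
  stopifnot(inherits(feature_set, "apa_feature_set"))
  stopifnot(all(c("contig", "position", "strand", "gene_id") %in% names(annotation)))
  if (!all(annotation$strand %in% c("+", "-")))
    stop("annotation strand must be + or - (no '.')")
  feats <- feature_set$features
  pcs <- data.table::as.data.table(feature_set$position_counts)
  samples <- feature_set$samples

  assign_rows <- vector("list", nrow(feats))
  n_dropped <- 0L
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    hit <- annotation[annotation$contig == f$contig &
                      annotation$strand == f$strand &
                      annotation$position >= f$start &
                      annotation$position < f$end, , drop = FALSE]
    if (nrow(hit) == 0L) { n_dropped <- n_dropped + 1L; next }
    ev <- pcs[pcs$feature_id == f$feature_id, ]
    if (nrow(hit) == 1L) {
      ev$site_key <- 1L
    } else {
      # nearest annotated site; ties to the transcript-5'-most site
      hit <- hit[order(hit$position), , drop = FALSE]
      d <- abs(outer(ev$position, hit$position, "-"))
      pick <- apply(d, 1L, function(r) {
        cand <- which(r == min(r))
        if (length(cand) == 1L) return(cand)
        if (f$strand == "+") min(cand) else max(cand)
      })
      ev$site_key <- as.integer(pick)
    }
    ev$gene_id <- hit$gene_id[ev$site_key]
    ev$site_pos <- hit$position[ev$site_key]
    assign_rows[[i]] <- ev
  }
  if (n_dropped > 0L)
    message(n_dropped, " merged feature(s) had no annotated site overlap and were dropped")
  ev_all <- data.table::rbindlist(assign_rows[!vapply(assign_rows, is.null, logical(1))])
  if (!nrow(ev_all)) stop("no feature overlapped the annotation")

  agg <- ev_all[, list(start = min(position), end = max(position) + 1L),
                by = c("gene_id", "contig", "strand", "site_pos")]
  wide <- data.table::dcast(ev_all, gene_id + site_pos ~ sample_id,
                            value.var = "n", fun.aggregate = sum, fill = 0L)
  for (s in setdiff(samples, names(wide))) wide[[s]] <- 0L
  agg <- merge(agg, wide[, c("gene_id", "site_pos", samples), with = FALSE],
               by = c("gene_id", "site_pos"), sort = TRUE)
  # distal-first index: on "+" larger coordinate = more distal
  agg[, site_index := {
    if (strand[1] == "+") rank(-site_pos) else rank(site_pos)
  }, by = "gene_id"]
  agg[, site_index := as.integer(site_index)]
  out <- as.data.frame(agg[, c("gene_id", "site_index", "contig", "strand",
                               "start", "end", "site_pos", samples),
                           with = FALSE])
  out <- out[order(out$gene_id, out$site_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Classify annotated site positions into genic regions
#'
#' Labels each site by the region of its gene model containing it:
#' `5'UTR`, `CDS` or `3'UTR` when inside an exon block (relative to the
#' thick/CDS interval, strand-aware), `intron` inside the gene span but
#' outside all blocks, `intergenic` outside the span. The summary is the
#' read-weighted fraction over the four genic regions (intergenic and
#' unmatched genes excluded).
#'
#' @param pas site-count table from [map_to_annotation()].
#' @param gene_models gene-model data.frame from [read_gene_models()].
#' @return list with `sites` (input plus a `region` column) and `summary`
#'   (named read-weighted fractions over 5'UTR/CDS/intron/3'UTR).
#' @export
classify_site_regions <- function(pas, gene_models) {
  samples <- sample_columns(pas)
  region <- character(nrow(pas))
  for (i in seq_len(nrow(pas))) {
    g <- gene_models[gene_models$gene_id == pas$gene_id[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      warning("gene ", pas$gene_id[i], " absent from gene models; site excluded")
      region[i] <- NA_character_
      next
    }
    p <- pas$site_pos[i]
    if (p < g$start || p >= g$end) { region[i] <- "intergenic"; next }
    in_block <- any(p >= g$block_starts[[1]] & p < g$block_ends[[1]])
    if (!in_block) { region[i] <- "intron"; next }
    if (g$strand == "+") {
      region[i] <- if (p < g$thick_start) "5'UTR"
        else if (p >= g$thick_end) "3'UTR" else "CDS"
    } else {
      region[i] <- if (p >= g$thick_end) "5'UTR"
        else if (p < g$thick_start) "3'UTR" else "CDS"
    }
  }
  reads <- rowSums(as.matrix(pas[, samples, drop = FALSE]))
  keep <- region %in% c("5'UTR", "CDS", "intron", "3'UTR")
  tot <- sum(reads[keep])
  summary <- vapply(c("5'UTR", "CDS", "intron", "3'UTR"), function(r)
    if (tot > 0) sum(reads[keep & region == r]) / tot else NA_real_,
    numeric(1))
  pas$region <- region
  list(sites = pas, summary = summary)
}
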