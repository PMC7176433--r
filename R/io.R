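#' Read a BED6 file of per-read cleavage positions
#'
#' Each record is one read's inferred mRNA 3' end: a 1-bp (or point) interval
#' whose start is the 0-based cleavage position. The `name` field carries the
#' sample id unless `sample_id` is given.
#'
#' @param path BED6 file.
#' @param sample_id optional sample label overriding the BED name field.
#' @return data.frame with columns `contig`, `position` (0-based), `strand`,
#'   `sample_id` (a cleavage-event table).
#' @export
read_cleavage_bed <- function(path, sample_id = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("cleavage-event BED requires explicit +/- strand")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = strand,
    sample_id = if (is.null(sample_id)) as.character(gr$name) else sample_id,
    stringsAsFactors = FALSE
  )
}

#' Write cleavage events as per-sample BED6 files
#'
#' @param events cleavage-event data.frame (`contig`, `position`, `strand`,
#'   `sample_id`).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths (one per sample).
#' @export
write_cleavage_bed <- function(events, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in sort(unique(events$sample_id))) {
    ev <- events[events$sample_id == s, , drop = FALSE]
    ev <- ev[order(ev$contig, ev$position, ev$strand), , drop = FALSE]
    gr <- GenomicRanges::GRanges(ev$contig,
                                 IRanges::IRanges(ev$position + 1L, width = 1L),
                                 strand = ev$strand,
                                 name = rep(s, nrow(ev)), score = 0L)
    path <- file.path(dir, paste0(prefix, "_", s, ".bed"))
    rtracklayer::export(gr, path, format = "bed")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a BED6 poly(A)-site annotation
#'
#' One record per annotated site; intervals must be exactly 1 bp wide and the
#' name field must carry the gene id (an optional `|`-suffix such as
#' `gene|siteIndex` is tolerated and stripped).
#'
#' @param path BED6 file.
#' @return data.frame with `contig`, `position` (0-based site), `strand`,
#'   `gene_id`, `name`.
#' @export
read_pas_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  w <- GenomicRanges::width(gr)
  if (any(w != 1L))
    stop("annotation intervals must be single-base poly(A) sites; ",
         "collapse records to site positions first")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("annotation records must have +/- strand")
  name <- as.character(gr$name)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = strand,
    gene_id = sub("\\|.*$", "", name),
    name = name,
    stringsAsFactors = FALSE
  )
}

write_pas_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(annotation$position + 1L, width = 1L),
    strand = annotation$strand, name = annotation$name, score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED12 gene models
#'
#' @param path BED12 file with thick (CDS) and block (exon) structure.
#' @return data.frame with one row per gene: `contig`, `start`, `end`
#'   (0-based half-open gene span), `gene_id`, `strand`, `thick_start`,
#'   `thick_end` (CDS, 0-based half-open) and list-columns `block_starts`,
#'   `block_ends` (absolute 0-based half-open exon intervals).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  blocks <- gr$blocks
  abs_blocks <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    list(starts = start0[i] + IRanges::start(b) - 1L,
         ends = start0[i] + IRanges::end(b))
  })
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = GenomicRanges::end(gr),
    gene_id = as.character(gr$name),
    strand = as.character(GenomicRanges::strand(gr)),
    thick_start = IRanges::start(gr$thick) - 1L,
    thick_end = IRanges::end(gr$thick),
    block_starts = I(lapply(abs_blocks, `[[`, "starts")),
    block_ends = I(lapply(abs_blocks, `[[`, "ends")),
    stringsAsFactors = FALSE
  )
}

write_gene_models <- function(models, path) {
  rel <- IRanges::IRangesList(lapply(seq_len(nrow(models)), function(i) {
    IRanges::IRanges(start = models$block_starts[[i]] - models$start[i] + 1L,
                     end = models$block_ends[[i]] - models$start[i])
  }))
  gr <- GenomicRanges::GRanges(
    models$contig,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand,
    name = models$gene_id, score = 0L,
    thick = IRanges::IRanges(models$thick_start + 1L, models$thick_end),
    blocks = rel)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write a site-count table
#'
#' Plain TSV with the metadata columns `gene_id`, `site_index`, `contig`,
#' `strand`, `start`, `end`, `site_pos` followed by one integer column per
#' sample.
#'
#' @param path TSV file.
#' @return data.frame site-count table.
#' @export
read_site_counts <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  miss <- setdiff(PAS_META_COLS, names(x))
  if (length(miss))
    stop("site-count table lacks columns: ", paste(miss, collapse = ", "))
  x
}

#' @rdname read_site_counts
#' @param x site-count table.
#' @export
write_site_counts <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a sample design TSV (`sample`, `condition`)
#' @param path TSV file.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  validate_design(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' Read a protein intensity TSV
#'
#' Rows are proteins (first column the gene/protein id), remaining columns
#' linear-scale intensities; blank or NA cells are missing values.
#'
#' @param path TSV file.
#' @return list with `intensity` (numeric matrix, rownames = ids) and
#'   `samples` (column names).
#' @export
read_protein_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  list(intensity = m, samples = colnames(m))
}
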