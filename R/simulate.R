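# Synthetic two-condition 3'-end sequencing study with a matched proteome.
#
# The generator states one "world": genes with 1-4 poly(A) sites in the
# 3' UTR of a terminal exon, Dirichlet-multinomial site-usage counts, a
# distal->proximal usage shift in a target subset, UGUA blocks planted
# upstream of the distal site of target genes on an otherwise UGUA-depleted
# background, cleavage-position jitter, and a log-normal proteome with
# abundance-dependent missingness.

# Fixed world constants (documented in the methods vignette):
SIM_SITE_SPACING <- 60L       # nt between adjacent true sites (>= 40 required)
SIM_NB_DISPERSION <- 0.05     # NB dispersion of per-gene totals
SIM_BASELINE_LOG2_MEAN <- 25  # log2 iBAQ-like baseline
SIM_BASELINE_LOG2_SD <- 2
SIM_GENE_WEIGHT_SDLOG <- 0.5  # log-normal gene expression weights, mean 1
SIM_JITTER_MAX <- 7L          # hard truncation so 15-nt merging cannot fuse
                              # sites >= 40 nt apart (7 + 7 < 15)

#' Configuration of the synthetic study
#'
#' @param n_genes number of genes.
#' @param sites_per_gene_range integer pair (min, max) poly(A) sites per gene.
#' @param n_target_genes genes (with >= 2 sites) given a distal-to-proximal
#'   usage shift under treatment.
#' @param shift_magnitude fraction in `[0, 1]` of usage mass moved from the
#'   most distal to the most proximal site in target genes.
#' @param precision Dirichlet-multinomial precision (concentration) of the
#'   count generator; larger means less overdispersed.
#' @param depth_per_sample expected reads per gene per sample (scaled by a
#'   per-gene log-normal weight of mean 1).
#' @param n_per_condition samples per condition.
#' @param jitter_scale scale (nt) of the discretised symmetric Laplace
#'   cleavage jitter, truncated at +/- 7 nt.
#' @param motif_offset nt upstream (transcript 5') of the distal site at
#'   which a block of 4 tandem UGUA is planted in target genes.
#' @param protein_slope treated-vs-control log2 protein change per unit of
#'   (negated) true length-change sign in target genes.
#' @param protein_noise_sd per-cell Gaussian noise SD on log2 intensities.
#' @param missingness_steepness,missingness_midpoint parameters of the MNAR
#'   logistic: P(missing) = plogis(-steepness * (log2 value - midpoint)).
#' @param utr3_length optional fixed 3'-UTR length (nt); `NULL` sizes each
#'   UTR to hold its sites at the default spacing.
#' @param seed master seed; every output artifact draws from its own stream
#'   derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       sites_per_gene_range = c(1L, 4L),
                       n_target_genes = 40L,
                       shift_magnitude = 0.2,
                       precision = 50,
                       depth_per_sample = 300L,
                       n_per_condition = 3L,
                       jitter_scale = 2,
                       motif_offset = 40L,
                       protein_slope = 0.8,
                       protein_noise_sd = 0.25,
                       missingness_steepness = 1,
                       missingness_midpoint = 21,
                       utr3_length = NULL,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sites_per_gene_range = as.integer(sites_per_gene_range),
              n_target_genes = as.integer(n_target_genes),
              shift_magnitude = shift_magnitude,
              precision = precision,
              depth_per_sample = as.integer(depth_per_sample),
              n_per_condition = as.integer(n_per_condition),
              jitter_scale = jitter_scale,
              motif_offset = as.integer(motif_offset),
              protein_slope = protein_slope,
              protein_noise_sd = protein_noise_sd,
              missingness_steepness = missingness_steepness,
              missingness_midpoint = missingness_midpoint,
              utr3_length = if (is.null(utr3_length)) NULL else as.integer(utr3_length),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L,
            length(cfg$sites_per_gene_range) == 2L,
            cfg$sites_per_gene_range[1] >= 1L,
            cfg$sites_per_gene_range[2] >= cfg$sites_per_gene_range[1],
            cfg$n_target_genes >= 0L, cfg$n_target_genes <= cfg$n_genes,
            cfg$shift_magnitude >= 0, cfg$shift_magnitude <= 1,
            cfg$precision > 0,
            cfg$depth_per_sample >= 1L, cfg$n_per_condition >= 1L,
            cfg$jitter_scale >= 0, cfg$motif_offset >= 0L,
            cfg$protein_noise_sd > 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_design <- function(config) {
  n <- config$n_per_condition
  data.frame(
    sample = c(paste0("ctrl_", seq_len(n)), paste0("trt_", seq_len(n))),
    condition = rep(c("control", "treated"), each = n),
    stringsAsFactors = FALSE)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Remove every UGUA occurrence from a base vector: TGTA on the sense strand
# and TACA (its reverse complement, i.e. transcript-space UGUA of "-" genes),
# by re-drawing the final base of each hit until no match remains.
deplete_ugua <- function(bases) {
  n <- length(bases)
  if (n < 4L) return(bases)
  repeat {
    i <- seq_len(n - 3L)
    hit <- (bases[i] == "T" & bases[i + 1L] == "G" &
            bases[i + 2L] == "T" & bases[i + 3L] == "A") |
           (bases[i] == "T" & bases[i + 1L] == "A" &
            bases[i + 2L] == "C" & bases[i + 3L] == "A")
    idx <- which(hit)
    if (!length(idx)) break
    bases[idx + 3L] <- sample(c("C", "G"), length(idx), replace = TRUE)
  }
  bases
}

#' Generate the synthetic reference: genome, gene models, annotation, truth
#'
#' Genes are laid out on two contigs with alternating strands. Each gene has
#' a 5'UTR/CDS first exon, one intron, and a terminal exon whose 3' UTR
#' carries the poly(A) sites in transcription order at >= 40 nt spacing.
#' Background sequence is UGUA-depleted; target genes carry a block of four
#' tandem UGUA ending `motif_offset` nt transcript-5' of the distal site.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]),
#'   `gene_models` (BED12-style data.frame, see [read_gene_models()]),
#'   `pas_annotation` (data.frame of 1-bp sites with `gene_id`), and `truth`
#'   (list with `genes`, `sites` data.frames and the config).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    ng <- config$n_genes
    rng <- config$sites_per_gene_range
    ns <- sample(seq(rng[1], rng[2]), ng, replace = TRUE)
    eligible <- which(ns >= 2L)
    if (config$n_target_genes > length(eligible))
      stop("n_target_genes exceeds the number of multi-site genes (",
           length(eligible), ")")
    targets <- sort(sample(eligible, config$n_target_genes))
    is_target <- seq_len(ng) %in% targets
    gene_id <- sprintf("gene%04d", seq_len(ng))
    strand <- rep(c("+", "-"), length.out = ng)
    contig <- rep(c("ctgA", "ctgB"), length.out = ng)

    # local gene layout (plus-strand coordinates within the gene):
    # exon1 [0,300) = 100 nt 5'UTR + 200 nt CDS; intron [300,500);
    # terminal exon [500, L) = 100 nt CDS + 3' UTR holding the sites.
    exon1 <- 300L; intron <- 200L; cds2 <- 100L
    utr3 <- integer(ng); spacing <- integer(ng)
    for (i in seq_len(ng)) {
      if (is.null(config$utr3_length)) {
        spacing[i] <- SIM_SITE_SPACING
        utr3[i] <- 50L + spacing[i] * (ns[i] - 1L) + 100L
      } else {
        utr3[i] <- config$utr3_length
        spacing[i] <- if (ns[i] > 1L)
          (utr3[i] - 150L) %/% (ns[i] - 1L) else 0L
        if (ns[i] > 1L && spacing[i] < 40L)
          stop("gene ", gene_id[i], ": 3'UTR of ", utr3[i],
               " nt cannot hold ", ns[i], " sites at >= 40 nt spacing")
      }
    }
    glen <- exon1 + intron + cds2 + utr3

    pad <- 500L; edge <- 300L
    gstart <- integer(ng)
    cursor <- c(ctgA = edge, ctgB = edge)
    for (i in seq_len(ng)) {
      gstart[i] <- cursor[[contig[i]]]
      cursor[[contig[i]]] <- gstart[i] + glen[i] + pad
    }
    contig_len <- cursor + edge

    # site positions: local plus-strand 3'UTR offsets, transcription order
    models <- vector("list", ng)
    site_rows <- vector("list", ng)
    for (i in seq_len(ng)) {
      L <- glen[i]; g0 <- gstart[i]
      site_local <- (exon1 + intron + cds2 + 50L) +
        spacing[i] * (seq_len(ns[i]) - 1L)            # 5'->3' order
      if (strand[i] == "+") {
        bs <- g0 + c(0L, exon1 + intron)
        be <- g0 + c(exon1, L)
        th <- g0 + c(100L, exon1 + intron + cds2)
        pos <- g0 + site_local
      } else {
        # mirrored layout: transcription right-to-left, terminal exon leftmost
        bs <- g0 + c(0L, L - exon1)
        be <- g0 + c(cds2 + utr3[i], L)
        th <- g0 + c(L - (exon1 + intron + cds2), L - 100L)
        pos <- g0 + (L - 1L) - site_local
      }
      models[[i]] <- data.frame(
        contig = contig[i], start = g0, end = g0 + L, gene_id = gene_id[i],
        strand = strand[i], thick_start = th[1], thick_end = th[2],
        block_starts = I(list(bs)), block_ends = I(list(be)),
        stringsAsFactors = FALSE)
      # distal-first index: site farthest along transcription gets index 1
      site_rows[[i]] <- data.frame(
        gene_id = gene_id[i], site_index = rev(seq_len(ns[i])),
        contig = contig[i], strand = strand[i],
        position = pos, stringsAsFactors = FALSE)
    }
    models <- do.call(rbind, models)
    sites <- do.call(rbind, site_rows)
    sites <- sites[order(sites$gene_id, sites$site_index), , drop = FALSE]
    rownames(sites) <- NULL

    # genome: random background, UGUA-depleted, then plant target blocks
    genome_chars <- lapply(contig_len, function(n)
      deplete_ugua(sample(c("A", "C", "G", "T"), n, replace = TRUE)))
    names(genome_chars) <- names(contig_len)
    block <- rep(c("T", "G", "T", "A"), 4L)  # 4 tandem UGUA, DNA space
    block_rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[block])
    off <- config$motif_offset
    for (i in targets) {
      s <- sites[sites$gene_id == gene_id[i] & sites$site_index == 1L, ]
      if (s$strand == "+") {
        at <- s$position - off - 16L + seq_len(16L)  # 0-based -> 1-based
        genome_chars[[s$contig]][at] <- block
      } else {
        at <- s$position + off + 1L + seq_len(16L)
        genome_chars[[s$contig]][at] <- block_rc
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                              character(1), collapse = ""))

    # truth usage proportions (distal-first order within each gene)
    prop_c <- numeric(nrow(sites)); prop_t <- numeric(nrow(sites))
    gene_weight <- exp(rnorm(ng, -SIM_GENE_WEIGHT_SDLOG^2 / 2,
                             SIM_GENE_WEIGHT_SDLOG))
    shift <- config$shift_magnitude
    for (i in seq_len(ng)) {
      sel <- which(sites$gene_id == gene_id[i])   # ordered distal-first
      k <- length(sel)
      if (k == 1L) { prop_c[sel] <- 1; prop_t[sel] <- 1; next }
      p <- rdirichlet1(rep(2, k))
      if (is_target[i] && p[1] < shift + 0.15) {
        # guarantee room for the configured distal->proximal shift
        deficit <- shift + 0.15 - p[1]
        p[-1] <- p[-1] * (1 - deficit / sum(p[-1]))
        p[1] <- shift + 0.15
      }
      q <- p
      if (is_target[i]) {
        q[1] <- q[1] - shift      # distal loses
        q[k] <- q[k] + shift      # most proximal gains
      }
      prop_c[sel] <- p; prop_t[sel] <- q
    }
    sites$prop_control <- prop_c
    sites$prop_treated <- prop_t

    genes <- data.frame(
      gene_id = gene_id, contig = contig, strand = strand,
      start = gstart, end = gstart + glen,
      ns = ns, is_target = is_target, gene_weight = gene_weight,
      length_change_sign = ifelse(is_target & shift > 0, -1L, 0L),
      protein_log2_effect = ifelse(is_target & shift > 0,
                                   config$protein_slope, 0),
      stringsAsFactors = FALSE)

    annotation <- data.frame(
      contig = sites$contig, position = sites$position,
      strand = sites$strand,
      gene_id = sites$gene_id,
      name = paste0(sites$gene_id, "|", sites$site_index),
      stringsAsFactors = FALSE)
    annotation <- annotation[order(annotation$contig, annotation$position), ,
                             drop = FALSE]
    rownames(annotation) <- NULL

    truth <- list(genes = genes, sites = sites, config = config)
    class(truth) <- "apa_truth"
    list(genome = genome, gene_models = models,
         pas_annotation = annotation, truth = truth)
  })
}

#' Simulate per-sample poly(A)-site counts
#'
#' Per gene and sample, a negative-binomial total (mean
#' `depth_per_sample * gene_weight`, dispersion 0.05) is split across the
#' gene's sites by a Dirichlet-multinomial draw around the condition's true
#' proportions with the configured precision.
#'
#' @param truth truth object from [simulate_reference()].
#' @param config the matching [sim_config()].
#' @return list with `counts` (site-count table, see [sample_columns()]) and
#'   `design`.
#' @export
simulate_site_counts <- function(truth, config) {
  stopifnot(inherits(truth, "apa_truth"))
  if (config$precision <= 0) stop("precision must be > 0")
  design <- sim_design(config)
  with_seed(derive_seed(config$seed, 2L), {
    sites <- truth$sites
    genes <- truth$genes
    m <- matrix(0L, nrow(sites), nrow(design),
                dimnames = list(NULL, design$sample))
    for (gi in seq_len(nrow(genes))) {
      sel <- which(sites$gene_id == genes$gene_id[gi])
      mu <- config$depth_per_sample * genes$gene_weight[gi]
      for (j in seq_len(nrow(design))) {
        total <- rnbinom(1, size = 1 / SIM_NB_DISPERSION, mu = mu)
        if (length(sel) == 1L) { m[sel, j] <- total; next }
        pi0 <- if (design$condition[j] == "control")
          sites$prop_control[sel] else sites$prop_treated[sel]
        p <- rdirichlet1(config$precision * pi0)
        m[sel, j] <- rmultinom(1, total, p)[, 1]
      }
    }
    counts <- data.frame(
      gene_id = sites$gene_id, site_index = sites$site_index,
      contig = sites$contig, strand = sites$strand,
      start = sites$position, end = sites$position + 1L,
      site_pos = sites$position, stringsAsFactors = FALSE)
    counts <- cbind(counts, as.data.frame(m))
    list(counts = counts, design = design)
  })
}

# Discretised symmetric Laplace on -7..7; scale 0 collapses to exactly 0.
sample_jitter <- function(n, scale) {
  if (scale <= 0) return(integer(n))
  k <- seq(-SIM_JITTER_MAX, SIM_JITTER_MAX)
  sample(k, n, replace = TRUE, prob = exp(-abs(k) / scale))
}

#' Emit one cleavage-event record per simulated read
#'
#' @param counts site-count table from [simulate_site_counts()].
#' @param truth,config as elsewhere.
#' @return cleavage-event data.frame (`contig`, `position`, `strand`,
#'   `sample_id`), one row per read, with Laplace jitter truncated at
#'   +/- 7 nt around the true site.
#' @export
simulate_read_ends <- function(counts, truth, config) {
  samples <- sample_columns(counts)
  with_seed(derive_seed(config$seed, 3L), {
    out <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      n <- counts[[samples[j]]]
      tot <- sum(n)
      pos <- rep(counts$site_pos, n) +
        sample_jitter(tot, config$jitter_scale)
      out[[j]] <- data.frame(
        contig = rep(counts$contig, n),
        position = pos,
        strand = rep(counts$strand, n),
        sample_id = samples[j],
        stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, out)
    rownames(events) <- NULL
    events
  })
}

#' Simulate the matched proteome
#'
#' One protein per gene. log2 intensity = baseline + condition effect +
#' Gaussian noise; each cell goes missing with probability
#' `plogis(-steepness * (log2 - midpoint))`, concentrating missingness at
#' low abundance (MNAR).
#'
#' @param truth,config as elsewhere.
#' @return list with `intensity` (linear-scale matrix, NA = missing),
#'   `log2_complete` (pre-masking values), `design`, and `true_effect`.
#' @export
simulate_proteome <- function(truth, config) {
  design <- sim_design(config)
  genes <- truth$genes
  with_seed(derive_seed(config$seed, 4L), {
    np <- nrow(genes); nsamp <- nrow(design)
    baseline <- rnorm(np, SIM_BASELINE_LOG2_MEAN, SIM_BASELINE_LOG2_SD)
    effect <- genes$protein_log2_effect
    treated <- design$condition == "treated"
    log2m <- matrix(baseline, np, nsamp) +
      outer(effect, as.numeric(treated)) +
      matrix(rnorm(np * nsamp, 0, config$protein_noise_sd), np, nsamp)
    dimnames(log2m) <- list(genes$gene_id, design$sample)
    p_miss <- plogis(-config$missingness_steepness *
                       (log2m - config$missingness_midpoint))
    miss <- matrix(runif(np * nsamp) < p_miss, np, nsamp)
    intensity <- 2^log2m
    intensity[miss] <- NA_real_
    list(intensity = intensity, log2_complete = log2m,
         design = design, true_effect = effect)
  })
}

#' Run the whole generator and write every artifact to disk
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @return Invisibly, a list of the in-memory objects plus written paths:
#'   genome FASTA, gene-model BED12, PAS-annotation BED6, per-sample read-end
#'   BED6, counts/design/proteome/truth TSVs.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  sc <- simulate_site_counts(ref$truth, config)
  events <- simulate_read_ends(sc$counts, ref$truth, config)
  prot <- simulate_proteome(ref$truth, config)

  p <- list(
    genome = file.path(outdir, "genome.fa"),
    gene_models = file.path(outdir, "gene_models.bed"),
    annotation = file.path(outdir, "pas_annotation.bed"),
    counts = file.path(outdir, "site_counts.tsv"),
    design = file.path(outdir, "design.tsv"),
    proteome = file.path(outdir, "proteome.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_sites = file.path(outdir, "truth_sites.tsv"))
  Biostrings::writeXStringSet(ref$genome, p$genome)
  write_gene_models(ref$gene_models, p$gene_models)
  write_pas_annotation(ref$pas_annotation, p$annotation)
  p$reads <- write_cleavage_bed(events, outdir)
  write_site_counts(sc$counts, p$counts)
  data.table::fwrite(sc$design, p$design, sep = "\t")
  prot_df <- data.frame(gene_id = rownames(prot$intensity),
                        as.data.frame(prot$intensity),
                        stringsAsFactors = FALSE)
  data.table::fwrite(prot_df, p$proteome, sep = "\t")
  data.table::fwrite(ref$truth$genes, p$truth_genes, sep = "\t")
  data.table::fwrite(ref$truth$sites, p$truth_sites, sep = "\t")
  invisible(list(reference = ref, site_counts = sc, read_ends = events,
                 proteome = prot, paths = p))
}
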