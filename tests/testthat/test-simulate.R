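test_that("simulate_study is byte-deterministic for a fixed seed", {
  cfg <- sim_config(n_genes = 6L, n_target_genes = 2L, seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("single-site gene world is degenerate but valid", {
  cfg <- sim_config(n_genes = 1L, sites_per_gene_range = c(1L, 1L),
                    n_target_genes = 0L, seed = 3L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$truth$genes), 1L)
  expect_equal(nrow(ref$pas_annotation), 1L)
  expect_equal(ref$truth$sites$prop_control, 1)
  expect_equal(ref$truth$sites$site_index, 1L)
})

test_that("UGUA blocks are planted at the configured offset, background clean", {
  st <- small_study()   # motif_offset = 40
  truth <- st$ref$truth
  distal <- truth$sites[truth$sites$site_index == 1L, ]
  distal <- merge(distal, truth$genes[, c("gene_id", "is_target")],
                  by = "gene_id")
  fl <- extract_flanks(st$ref$genome, distal$contig, distal$position,
                       distal$strand, flank = 200L)
  # independent scan: match starts of TGTA in transcript orientation
  starts <- lapply(fl, function(s) {
    hits <- gregexpr("TGTA", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 201L  # offsets
  })
  for (i in seq_len(nrow(distal))) {
    hits <- starts[[i]]
    if (distal$is_target[i]) {
      expect_gte(sum(hits >= -60L & hits <= -40L), 4L)
    } else {
      # background is UGUA-depleted: at most 1 match per 400 nt flank
      expect_lte(length(hits), 1L)
    }
  }
})

test_that("3'UTR too short to hold the sites errors naming the gene", {
  cfg <- sim_config(n_genes = 4L, sites_per_gene_range = c(4L, 4L),
                    n_target_genes = 0L, utr3_length = 200L, seed = 1L)
  expect_error(simulate_reference(cfg), "gene000.*40 nt spacing")
})

test_that("site counts follow the stated proportions at huge precision", {
  cfg <- sim_config(n_genes = 5L, sites_per_gene_range = c(2L, 3L),
                    n_target_genes = 0L, shift_magnitude = 0,
                    precision = 1e9, n_per_condition = 100L, seed = 21L)
  ref <- simulate_reference(cfg)
  sc <- simulate_site_counts(ref$truth, cfg)
  samples <- sample_columns(sc$counts)
  for (g in unique(sc$counts$gene_id)) {
    sub <- sc$counts[sc$counts$gene_id == g, ]
    m <- as.matrix(sub[, samples])
    n_tot <- sum(m)
    p_hat <- rowSums(m) / n_tot
    p_true <- ref$truth$sites$prop_control[ref$truth$sites$gene_id == g]
    se <- sqrt(p_true * (1 - p_true) / n_tot)
    expect_true(all(abs(p_hat - p_true) <= 3 * se + 1e-12))
  }
})

test_that("zero shift leaves treated proportions identical to control", {
  cfg <- sim_config(n_genes = 20L, n_target_genes = 5L, shift_magnitude = 0,
                    seed = 5L)
  ref <- simulate_reference(cfg)
  expect_identical(ref$truth$sites$prop_control, ref$truth$sites$prop_treated)
})

test_that("truth invariants hold", {
  st <- small_study()
  truth <- st$ref$truth
  sums_c <- tapply(truth$sites$prop_control, truth$sites$gene_id, sum)
  sums_t <- tapply(truth$sites$prop_treated, truth$sites$gene_id, sum)
  expect_true(all(abs(sums_c - 1) < 1e-12))
  expect_true(all(abs(sums_t - 1) < 1e-12))
  # targets shift distal usage down under treatment
  distal <- truth$sites[truth$sites$site_index == 1L, ]
  tg <- truth$genes$gene_id[truth$genes$is_target]
  d <- distal[distal$gene_id %in% tg, ]
  expect_true(all(d$prop_treated < d$prop_control))
  # all gene spans and sites inside contig bounds
  w <- setNames(Biostrings::width(st$ref$genome), names(st$ref$genome))
  expect_true(all(truth$genes$end <= w[truth$genes$contig]))
  expect_true(all(truth$sites$position >= 0))
})

test_that("read ends conserve counts and respect jitter rules", {
  st <- small_study()
  ev <- st$ev
  samples <- sample_columns(st$sc$counts)
  col_sums <- colSums(as.matrix(st$sc$counts[, samples]))
  expect_equal(as.vector(table(ev$sample_id)[samples]), as.vector(col_sums))
  # jitter bounded at +/- 7 around a true site of the same gene strand
  true_pos <- st$ref$truth$sites$position
  d_min <- vapply(ev$position[1:500],
                  function(p) min(abs(p - true_pos)), numeric(1))
  expect_true(all(d_min <= 7))

  cfg0 <- sim_config(n_genes = 5L, n_target_genes = 0L, jitter_scale = 0,
                     seed = 9L)
  ref0 <- simulate_reference(cfg0)
  sc0 <- simulate_site_counts(ref0$truth, cfg0)
  ev0 <- simulate_read_ends(sc0$counts, ref0$truth, cfg0)
  expect_true(all(ev0$position %in% ref0$truth$sites$position))

  expect_identical(simulate_read_ends(sc0$counts, ref0$truth, cfg0), ev0)
})

test_that("proteome slope, MCAR limit and determinism behave as stated", {
  cfg <- sim_config(n_genes = 150L, n_target_genes = 40L, protein_slope = 0,
                    seed = 13L)
  ref <- simulate_reference(cfg)
  pr <- simulate_proteome(ref$truth, cfg)
  lfc <- rowMeans(pr$log2_complete[, 4:6]) - rowMeans(pr$log2_complete[, 1:3])
  tg <- ref$truth$genes$is_target
  tt <- t.test(lfc[tg], lfc[!tg])
  diff <- abs(diff(tt$estimate))
  se <- tt$stderr
  expect_lt(diff, 3 * se)

  cfg2 <- sim_config(n_genes = 400L, n_target_genes = 0L,
                     missingness_steepness = 0, seed = 17L)
  ref2 <- simulate_reference(cfg2)
  pr2 <- simulate_proteome(ref2$truth, cfg2)
  q <- cut(pr2$log2_complete, breaks = quantile(pr2$log2_complete),
           include.lowest = TRUE)
  miss_frac <- tapply(as.vector(is.na(pr2$intensity)), q, mean)
  n_q <- tapply(as.vector(is.na(pr2$intensity)), q, length)
  se_q <- sqrt(0.5 * 0.5 / n_q)
  expect_true(all(abs(miss_frac - mean(miss_frac)) <= 3 * se_q))

  expect_identical(simulate_proteome(ref$truth, cfg)$intensity, pr$intensity)
})

test_that("invalid configs error", {
  expect_error(sim_config(precision = 0))
  expect_error(sim_config(n_target_genes = 10, n_genes = 5))
  expect_error(sim_config(shift_magnitude = 1.5))
})
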