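design6 <- data.frame(sample = c(paste0("ctrl_", 1:3), paste0("trt_", 1:3)),
                      condition = rep(c("control", "treated"), each = 3),
                      stringsAsFactors = FALSE)

rand_intensity <- function(np, seed, miss = 0.2) {
  set.seed(seed)
  m <- 2^matrix(rnorm(np * 6, 25, 2), np, 6,
                dimnames = list(sprintf("p%04d", seq_len(np)),
                                design6$sample))
  m[matrix(runif(np * 6) < miss, np, 6)] <- NA
  m
}

test_that("median normalisation equalises sample medians", {
  m <- rand_intensity(200, seed = 1)
  m[, 2] <- m[, 2] * 4
  norm <- median_normalize(m)
  med <- apply(norm, 2, median, na.rm = TRUE)
  expect_equal(unname(med), rep(median(apply(m, 2, median, na.rm = TRUE)), 6))
  # already-equal medians: unchanged
  expect_equal(median_normalize(norm), norm, tolerance = 1e-12)
  # missing entries untouched
  expect_identical(is.na(norm), is.na(m))
  m[, 3] <- NA
  expect_error(median_normalize(m), "ctrl_3")
})

test_that("consistency filter keeps proteins complete in >= 1 condition", {
  m <- rand_intensity(4, seed = 2, miss = 0)
  m[1, ] <- c(1, 1, 1, NA, NA, 1)       # complete in control: keep
  m[2, ] <- c(1, 1, NA, 1, NA, 1)       # complete in neither: drop
  m[3, ] <- c(NA, NA, NA, 1, 1, 1)      # complete in treated: keep
  out <- filter_consistent(m, design6)
  expect_identical(rownames(out), rownames(m)[c(1, 3, 4)])
  # brute force on a random mask
  m2 <- rand_intensity(300, seed = 3, miss = 0.35)
  keep <- apply(m2, 1, function(x)
    all(!is.na(x[1:3])) || all(!is.na(x[4:6])))
  expect_identical(rownames(filter_consistent(m2, design6)),
                   rownames(m2)[keep])
})

test_that("imputation draws from the downshifted Gaussian and is reproducible", {
  m <- log2(rand_intensity(120, seed = 4, miss = 0.25))
  imp <- impute_missing(m, seed = 42)
  expect_identical(imp$log2[!imp$imputed], m[!imp$imputed])
  expect_identical(imp$imputed, is.na(m))
  expect_false(any(is.na(imp$log2)))
  expect_identical(impute_missing(m, seed = 42)$log2, imp$log2)
  expect_false(identical(impute_missing(m, seed = 43)$log2, imp$log2))
  # no missing: identity
  full <- m; full[is.na(full)] <- 0
  imp2 <- impute_missing(full, seed = 1)
  expect_identical(imp2$log2, full)
  expect_error(impute_missing(matrix(c(5, 5, NA), 1), seed = 1), "SD")
})

test_that("moderated t reproduces the pinned-prior hand example and limits", {
  # 3v3 with per-group variance exactly 1 => pooled s2 = 1
  x <- rbind(p1 = c(10, 11, 12, 14, 15, 16))  # each group sd = 1
  colnames(x) <- design6$sample
  res <- moderated_t(x, design6, prior = list(d0 = 4, s0_sq = 1))
  expect_equal(res$table$log2fc, 4)
  # s2_post = (4*1 + 4*1)/8 = 1; t = 4 / sqrt(2/3)
  expect_equal(res$table$t_mod, 4 / sqrt(2 / 3))
  expect_equal(res$table$df_total, 8)
  expect_equal(res$table$p_value,
               2 * pt(-4 / sqrt(2 / 3), df = 8))

  # d0 -> 0: ordinary two-sample t; d0 -> Inf: pooled-s0 z-like statistic
  m <- log2(rand_intensity(50, seed = 5, miss = 0))
  t_ord <- apply(m, 1, function(r) {
    s2 <- (var(r[1:3]) + var(r[4:6])) / 2
    (mean(r[4:6]) - mean(r[1:3])) / sqrt(s2 * (2 / 3))
  })
  res0 <- moderated_t(m, design6, prior = list(d0 = 1e-9, s0_sq = 1))
  expect_equal(res0$table$t_mod, unname(t_ord), tolerance = 1e-6)
  resI <- moderated_t(m, design6, prior = list(d0 = Inf, s0_sq = 2))
  expect_equal(res$prior$d0, 4)
  expect_equal(resI$table$t_mod,
               unname((rowMeans(m[, 4:6]) - rowMeans(m[, 1:3])) /
                        sqrt(2 * (2 / 3))), tolerance = 1e-12)
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(9)
  np <- 400
  s2_true <- 1 / rgamma(np, shape = 3, rate = 3)  # heterogeneous variances
  m <- matrix(rnorm(np * 6, 0, sqrt(rep(s2_true, 6))), np, 6,
              dimnames = list(sprintf("p%03d", 1:np), design6$sample))
  m[1:40, 4:6] <- m[1:40, 4:6] + 1
  got <- moderated_t(m, design6)
  dm <- cbind(intercept = 1, treated = rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, dm))
  expect_equal(got$prior$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(got$prior$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(got$table$t_mod, unname(fit$t[, "treated"]), tolerance = 1e-6)
  expect_equal(got$table$p_value, unname(fit$p.value[, "treated"]),
               tolerance = 1e-6)
})

test_that("quadrant battery reproduces its closed forms", {
  res <- data.frame(gene_id = sprintf("g%02d", 1:20), p_adjusted = 0.01,
                    length_change = c(rep(-1, 11), rep(1, 9)))
  prot <- data.frame(gene_id = res$gene_id,
                     log2fc = c(rep(1, 9), rep(-1, 2), rep(1, 9)))
  qt <- quadrant_tests(res, prot)
  # step 3 on shortened genes: (up = 9, down = 2) -> chi2 = 49/11
  expect_equal(qt$step3$statistic, 49 / 11, tolerance = 1e-12)
  expect_equal(qt$step3$statistic, 4.4545, tolerance = 1e-4)
  expect_equal(qt$step3$p_value, pchisq(49 / 11, 1, lower.tail = FALSE))
  expect_equal(qt$step3$p_value, 0.0348, tolerance = 1e-2)
  # balanced quadrants: step-2 chi-square 0, p = 1
  res2 <- data.frame(gene_id = sprintf("g%02d", 1:20), p_adjusted = 0.01,
                     length_change = rep(c(-1, 1), each = 10))
  prot2 <- data.frame(gene_id = res2$gene_id, log2fc = rep(c(1, -1), 10))
  qt2 <- quadrant_tests(res2, prot2)
  expect_equal(qt2$step2$statistic, 0)
  expect_equal(qt2$step2$p_value, 1)
  expect_equal(unname(qt2$step2$counts), rep(5L, 4))
  # nothing significant: NA steps with warnings
  res3 <- res
  res3$p_adjusted <- 0.9
  suppressWarnings(qt3 <- quadrant_tests(res3, prot))
  expect_true(is.na(qt3$step2$statistic))
})

test_that("proteome pipeline detects planted protein shifts via step 3", {
  set.seed(23)
  rejected <- replicate(20, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(n_genes = 60L, n_target_genes = 18L, seed = seed)
    ref <- simulate_reference(cfg)
    sc <- simulate_site_counts(ref$truth, cfg)
    filt <- suppressMessages(apa_filter(sc$counts, sc$design))
    apa <- lrt_apa(filt, sc$design)
    rlc <- relative_length_change(length_scores(cpm_normalize(filt)),
                                  sc$design, apa_results = apa)
    prot <- simulate_proteome(ref$truth, cfg)
    pp <- proteome_pipeline(prot$intensity, prot$design, seed = seed + 1L)
    qt <- quadrant_tests(rlc, pp$table)
    !is.na(qt$step3$p_value) && qt$step3$p_value < 0.05
  })
  expect_gte(mean(rejected), 0.9)
})
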