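# Shared fixtures, built once per test run.

# Small planted-motif study: 40 genes, 12 targets, default effect sizes.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 40L, n_target_genes = 12L, seed = 11L)
      ref <- simulate_reference(cfg)
      sc <- simulate_site_counts(ref$truth, cfg)
      ev <- simulate_read_ends(sc$counts, ref$truth, cfg)
      cache <<- list(cfg = cfg, ref = ref, sc = sc, ev = ev,
                     design = sc$design)
    }
    cache
  }
})

# Random site-count table (no genomic realism needed) for filter oracles.
random_pas_table <- function(n_genes, seed, max_sites = 4L,
                             lambda = 8, n_per_condition = 3L) {
  set.seed(seed)
  samples <- c(paste0("ctrl_", seq_len(n_per_condition)),
               paste0("trt_", seq_len(n_per_condition)))
  rows <- lapply(seq_len(n_genes), function(i) {
    ns <- sample(seq_len(max_sites), 1L)
    data.frame(gene_id = sprintf("g%04d", i), site_index = seq_len(ns),
               contig = "ctg", strand = "+",
               start = 1000L * i + 60L * seq_len(ns),
               end = 1000L * i + 60L * seq_len(ns) + 1L,
               site_pos = 1000L * i + 60L * seq_len(ns),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (s in samples)
    tab[[s]] <- rpois(nrow(tab), lambda)
  list(counts = tab,
       design = data.frame(sample = samples,
                           condition = rep(c("control", "treated"),
                                           each = n_per_condition),
                           stringsAsFactors = FALSE))
}
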