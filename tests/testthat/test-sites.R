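make_events <- function(pos, strand = "+", sample_id = "s1", contig = "ctg") {
  data.frame(contig = contig, position = as.integer(pos), strand = strand,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("BAM alignments yield 3'-end events at the correct base", {
  sam <- file.path(withr::local_tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ctg\tLN:1000",
    paste("r1", 0, "ctg", 101, 60, "150M", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t"),
    paste("r2", 16, "ctg", 101, 60, "150M", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t")), sam)
  ev <- extract_cleavage_events(sam, sample_id = "s1")
  ev <- ev[order(ev$strand), ]
  # + read aligned [100, 250): rightmost aligned base, 0-based = 249
  expect_equal(ev$position[ev$strand == "+"], 249L)
  # - read: leftmost aligned base = 100
  expect_equal(ev$position[ev$strand == "-"], 100L)
  # reverse orientation flips strand and the position rule follows it
  ev_r <- extract_cleavage_events(sam, orientation = "reverse",
                                  sample_id = "s1")
  expect_setequal(ev_r$strand, c("+", "-"))
})

test_that("simulated events round-trip through SAM extraction", {
  st <- small_study()
  ev <- st$ev[st$ev$sample_id == "ctrl_1", ][1:500, ]
  sam <- file.path(withr::local_tempdir(), "sim.sam")
  ctg_len <- setNames(Biostrings::width(st$ref$genome),
                      names(st$ref$genome))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ctg_len), ctg_len))
  body <- sprintf("r%d\t%d\t%s\t%d\t60\t1M\t*\t0\t0\tA\t*",
                  seq_len(nrow(ev)), ifelse(ev$strand == "+", 0L, 16L),
                  ev$contig, ev$position + 1L)
  writeLines(c(hdr, body), sam)
  got <- extract_cleavage_events(sam, sample_id = "ctrl_1")
  key <- function(d) sort(paste(d$contig, d$position, d$strand))
  expect_identical(key(got), key(ev))
})

test_that("merging matches brute-force single linkage on the 3-point case", {
  ev <- make_events(c(100, 110, 126))
  fs <- merge_cleavage_sites(ev, gap = 15L)
  f <- fs$features[order(fs$features$start), ]
  expect_equal(nrow(f), 2L)
  expect_equal(f$start, c(100L, 126L))
  expect_equal(f$end, c(111L, 127L))
  expect_equal(unname(unlist(brute_single_linkage(c(100, 110, 126), 15))),
               c(100, 110, 126))

  f1 <- merge_cleavage_sites(make_events(100), gap = 15L)$features
  expect_equal(f1$start, 100L)
  expect_equal(f1$end, 101L)
  expect_equal(f1$s1, 1L)

  expect_error(merge_cleavage_sites(ev, gap = -1), "gap")
})

test_that("merging is order-independent, strand-isolated and count-conserving", {
  set.seed(42)
  pos <- sample(1:2000, 400, replace = TRUE)
  ev <- rbind(make_events(pos, "+", "s1"), make_events(pos + 3L, "+", "s2"),
              make_events(pos, "-", "s1"))
  fs <- merge_cleavage_sites(ev, gap = 15L)
  shuffled <- ev[sample(nrow(ev)), ]
  fs2 <- merge_cleavage_sites(shuffled, gap = 15L)
  expect_identical(fs$features, fs2$features)
  # brute-force cluster count per strand
  for (str in c("+", "-")) {
    p <- ev$position[ev$strand == str]
    expect_equal(sum(fs$features$strand == str),
                 length(brute_single_linkage(p, 15)))
  }
  # conservation per sample
  for (s in c("s1", "s2"))
    expect_equal(sum(fs$features[[s]]), sum(ev$sample_id == s))
  # same coordinates, opposite strands never merge
  both <- merge_cleavage_sites(rbind(make_events(500), make_events(500, "-")),
                               gap = 15L)
  expect_equal(nrow(both$features), 2L)
  # widening the gap never increases the feature count
  n_feats <- vapply(c(0L, 5L, 15L, 50L), function(g)
    nrow(merge_cleavage_sites(ev, gap = g)$features), numeric(1))
  expect_true(all(diff(n_feats) <= 0))
})

test_that("annotation mapping keeps, drops and splits features correctly", {
  ann <- data.frame(contig = "ctg", position = c(105L, 125L, 300L),
                    strand = "+", gene_id = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  # feature [100,131) spans both G1 sites; events split by proximity
  ev <- make_events(c(100, 100, 114, 115, 116, 130))
  fs <- merge_cleavage_sites(ev, gap = 15L)
  expect_equal(nrow(fs$features), 1L)
  pas <- map_to_annotation(fs, ann)
  expect_equal(attr(pas, "n_dropped"), 0L)
  expect_equal(nrow(pas), 2L)
  # 100,100,114 -> 105; 115 tie -> 5'-most (105); 116,130 -> 125
  expect_equal(pas$s1[pas$site_pos == 105], 4L)
  expect_equal(pas$s1[pas$site_pos == 125], 2L)
  # distal-first on "+": larger coordinate = index 1
  expect_equal(pas$site_index[pas$site_pos == 125], 1L)
  expect_equal(pas$site_index[pas$site_pos == 105], 2L)

  # non-overlapping feature dropped with a message
  ev2 <- rbind(ev, make_events(600))
  fs2 <- merge_cleavage_sites(ev2, gap = 15L)
  expect_message(pas2 <- map_to_annotation(fs2, ann), "dropped")
  expect_equal(attr(pas2, "n_dropped"), 1L)
  expect_equal(sum(pas2$s1), 6L)

  bad <- ann
  bad$strand <- "."
  expect_error(map_to_annotation(fs, bad), "strand")
})

test_that("single-base annotation is enforced at read time", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.bed")
  writeLines("ctg\t10\t20\tG1\t0\t+", bad)
  expect_error(read_pas_annotation(bad), "collapse")
  ok <- file.path(d, "ok.bed")
  writeLines("ctg\t10\t11\tG1|1\t0\t+", ok)
  ann <- read_pas_annotation(ok)
  expect_equal(ann$position, 10L)
  expect_equal(ann$gene_id, "G1")
})

test_that("pipeline on simulated reads recovers the simulated count table", {
  st <- small_study()
  fs <- merge_cleavage_sites(st$ev, gap = 15L)
  pas <- map_to_annotation(fs, st$ref$pas_annotation)
  samples <- sample_columns(st$sc$counts)
  truth_tab <- st$sc$counts[order(st$sc$counts$gene_id,
                                  st$sc$counts$site_index), ]
  got <- pas[order(pas$gene_id, pas$site_index), ]
  expect_equal(nrow(got), nrow(truth_tab))
  expect_equal(got$site_pos, truth_tab$site_pos)
  for (s in samples)
    expect_identical(as.integer(got[[s]]), as.integer(truth_tab[[s]]))
})

test_that("region classification is strand-aware and summarised by reads", {
  models <- data.frame(
    contig = "ctg", start = 0L, end = 1000L, gene_id = "G1", strand = "+",
    thick_start = 100L, thick_end = 600L,
    block_starts = I(list(c(0L, 500L))), block_ends = I(list(c(300L, 1000L))),
    stringsAsFactors = FALSE)
  pas <- data.frame(
    gene_id = "G1", site_index = 1L, contig = "ctg", strand = "+",
    start = c(50L, 200L, 400L, 700L, 1200L),
    end = c(51L, 201L, 401L, 701L, 1201L),
    site_pos = c(50L, 200L, 400L, 700L, 1200L),
    s1 = c(1L, 1L, 1L, 7L, 1L), stringsAsFactors = FALSE)
  cls <- classify_site_regions(pas, models)
  expect_equal(cls$sites$region,
               c("5'UTR", "CDS", "intron", "3'UTR", "intergenic"))
  expect_equal(unname(cls$summary["3'UTR"]), 0.7)

  # mirrored gene: thick interval interpreted from the other side
  models$strand <- "-"
  pas$strand <- "-"
  cls2 <- classify_site_regions(pas, models)
  expect_equal(cls2$sites$region,
               c("3'UTR", "CDS", "intron", "5'UTR", "intergenic"))

  pas$gene_id <- "G2"
  expect_warning(classify_site_regions(pas[1, ], models), "absent")
})

test_that("simulated sites are all 3'UTR", {
  st <- small_study()
  fs <- merge_cleavage_sites(st$ev, gap = 15L)
  pas <- map_to_annotation(fs, st$ref$pas_annotation)
  cls <- classify_site_regions(pas, st$ref$gene_models)
  expect_equal(unname(cls$summary["3'UTR"]), 1.0)
})
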