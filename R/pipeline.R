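#' End-to-end APA analysis from cleavage events
#'
#' Runs merging (15 nt single linkage), annotation mapping, the three-stage
#' count filter, cpm normalisation, the Dirichlet-multinomial LRT, and the
#' weighted length score. The returned `results` table carries the cpm-scale
#' relative length change plus `length_change_prop`, the proportion-scale
#' variant used by the motif module's non-target rule.
#'
#' @param events cleavage-event data.frame (see
#'   [extract_cleavage_events()]).
#' @param annotation poly(A)-site annotation (see [read_pas_annotation()]).
#' @param design two-condition design.
#' @param gap merge distance in nt (default 15).
#' @param min_major,min_minor,min_fraction,min_mean filter thresholds, see
#'   [apa_filter()].
#' @param alpha significance threshold for calls.
#' @return list: `sites` (annotated site counts, pre-filter), `filtered`,
#'   `cpm`, `apa` (LRT results), `scores`, `results` (per-gene table with
#'   length changes and calls), `shortening` (chi-square enrichment).
#' @export
apa_pipeline <- function(events, annotation, design, gap = 15L,
                         min_major = 5L, min_minor = 1L,
                         min_fraction = 0.10, min_mean = 5,
                         alpha = 0.05) {
  design <- validate_design(design)
  feats <- merge_cleavage_sites(events, gap = gap)
  sites <- map_to_annotation(feats, annotation)
  filtered <- apa_filter(sites, design, min_major = min_major,
                         min_minor = min_minor, min_fraction = min_fraction,
                         min_mean = min_mean)
  if (!nrow(filtered)) stop("no sites survive filtering")
  cpm <- cpm_normalize(filtered)
  apa <- lrt_apa(filtered, design)
  scores <- length_scores(cpm)
  results <- relative_length_change(scores, design, apa_results = apa,
                                    alpha = alpha)
  prop <- relative_length_change(length_scores(filtered, proportion = TRUE),
                                 design)
  results$length_change_prop <-
    prop$length_change[match(results$gene_id, prop$gene_id)]
  shortening <- shortening_enrichment(results, alpha = alpha)
  list(sites = sites, filtered = filtered, cpm = cpm, apa = apa,
       scores = scores, results = results, shortening = shortening)
}
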