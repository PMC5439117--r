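#' Run the full classification pipeline on one cohort
#'
#' Copy-number calling, cluster assignment and subtype classification in one
#' call; the survival layer is run separately on the output.
#'
#' @param gistic GISTIC matrix, or `NULL` when using segments.
#' @param segments segment table, or `NULL`.
#' @param mutations mutation table.
#' @param source `"gistic"` or `"segments"` (which copy-number substrate to
#'   call from).
#' @param regions,genes,thresholds,rule_tables configuration; defaults as in
#'   the respective modules.
#' @return list: `callsets`, `clusters`, `subtypes` (data.frames keyed by
#'   sample_id).
#' @export
run_pipeline <- function(gistic = NULL, segments = NULL, mutations,
                         source = c("gistic", "segments"),
                         regions = default_regions(),
                         genes = default_gene_annotation(),
                         thresholds = default_thresholds(),
                         rule_tables = default_rule_tables()) {
  source <- match.arg(source)
  callsets <- make_callsets(gistic = gistic, segments = segments,
                            mutations = mutations, regions = regions,
                            genes = genes, thresholds = thresholds,
                            source = source)
  clusters <- assign_clusters_cohort(mutations, callsets)
  subtypes <- subtype_cohort(clusters, callsets, mutations, rule_tables)
  list(callsets = callsets, clusters = clusters, subtypes = subtypes)
}
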