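#' The three molecular cluster labels
#' @return character vector of the valid cluster labels.
#' @export
cluster_levels <- function() {
  c("OLIGO_IDHmut_CODEL", "ASTRO_IDHmut", "ASTRO_IDHwt")
}

#' Assign a sample to a molecular cluster
#'
#' 2016-WHO style rule on IDH1/IDH2 mutation and 1p/19q codeletion:
#' IDH-mutant (either gene) with codeletion -> oligodendroglial cluster;
#' IDH-mutant without codeletion -> IDH-mutant astrocytic cluster; IDH
#' wildtype -> IDH-wildtype astrocytic cluster. A codeletion call in an
#' IDH-wildtype sample is discordant with the cluster definitions: the sample
#' is still returned as `ASTRO_IDHwt` but flagged.
#'
#' All three arguments are vectorized; missing (`NA`) flags are an error, not
#' a guess.
#'
#' @param idh1_mut,idh2_mut,codel_1p19q logical flags.
#' @return data.frame: `cluster` (see [cluster_levels()]), `discordant`
#'   (logical: codel with IDH wildtype).
#' @export
assign_cluster <- function(idh1_mut, idh2_mut, codel_1p19q) {
  n <- length(idh1_mut)
  stopifnot(length(idh2_mut) == n, length(codel_1p19q) == n)
  if (anyNA(idh1_mut) || anyNA(idh2_mut) || anyNA(codel_1p19q)) {
    stop("assign_cluster: unresolved (NA) marker flags; refusing to guess")
  }
  idh <- idh1_mut | idh2_mut
  cluster <- ifelse(idh & codel_1p19q, "OLIGO_IDHmut_CODEL",
                    ifelse(idh, "ASTRO_IDHmut", "ASTRO_IDHwt"))
  discordant <- !idh & codel_1p19q
  if (any(discordant)) {
    warning("assign_cluster: ", sum(discordant),
            " sample(s) with 1p/19q codeletion but IDH wildtype;",
            " kept as ASTRO_IDHwt and flagged")
  }
  data.frame(cluster = cluster, discordant = discordant)
}

#' Assign clusters for a whole cohort
#'
#' Derives the IDH1/IDH2 flags from a mutation table and the codeletion flag
#' from a call set, then applies [assign_cluster()].
#'
#' @param mutations mutation table (`sample_id`, `gene`).
#' @param callsets `cna_callset` data.frame (provides `codel_1p19q`).
#' @return data.frame: sample_id, idh1_mut, idh2_mut, codel_1p19q, cluster,
#'   discordant.
#' @export
assign_clusters_cohort <- function(mutations, callsets) {
  s <- callsets$sample_id
  idh1 <- s %in% mutations$sample_id[mutations$gene == "IDH1"]
  idh2 <- s %in% mutations$sample_id[mutations$gene == "IDH2"]
  res <- assign_cluster(idh1, idh2, callsets$codel_1p19q)
  data.frame(sample_id = s, idh1_mut = idh1, idh2_mut = idh2,
             codel_1p19q = callsets$codel_1p19q,
             cluster = res$cluster, discordant = res$discordant)
}

#' Integrated 2016-WHO diagnostic label
#'
#' Combines cluster and grade into the canonical entity string. Oligoastro-
#' cytoma histology (OA/AOA) is resolved to the cluster-implied entity and
#' the resolution recorded. An oligodendroglial-cluster grade IV is kept but
#' flagged (there are no WHO grade IV oligodendrogliomas); unknown grade
#' yields an NOS-style suffix.
#'
#' @param cluster one of [cluster_levels()] (vectorized).
#' @param grade `"II"`, `"III"`, `"IV"` or `"unknown"`.
#' @param histology_2007 optional 2007 histology code (A, O, OA, AA, AO,
#'   AOA, GBM, unknown).
#' @return data.frame: `label`, `warning_grade_IV_oligo` (logical),
#'   `oa_resolved` (logical: OA/AOA histology resolved molecularly).
#' @export
integrated_label <- function(cluster, grade, histology_2007 = NULL) {
  n <- length(cluster)
  grade <- rep_len(as.character(grade), n)
  if (is.null(histology_2007)) histology_2007 <- rep("unknown", n)
  stopifnot(all(cluster %in% cluster_levels()))
  base <- function(cl, gr) {
    switch(cl,
      OLIGO_IDHmut_CODEL = switch(gr,
        II = "Oligodendroglioma, IDH-mutant and 1p/19q-codeleted, WHO grade II",
        III = "Anaplastic oligodendroglioma, IDH-mutant and 1p/19q-codeleted, WHO grade III",
        IV = "Anaplastic oligodendroglioma, IDH-mutant and 1p/19q-codeleted, WHO grade IV",
        "Oligodendroglial tumor, IDH-mutant and 1p/19q-codeleted, NOS-grade-unknown"),
      ASTRO_IDHmut = switch(gr,
        II = "Diffuse astrocytoma, IDH-mutant, WHO grade II",
        III = "Anaplastic astrocytoma, IDH-mutant, WHO grade III",
        IV = "Glioblastoma, IDH-mutant, WHO grade IV",
        "Astrocytic glioma, IDH-mutant, NOS-grade-unknown"),
      ASTRO_IDHwt = switch(gr,
        II = "Diffuse astrocytoma, IDH-wildtype, WHO grade II",
        III = "Anaplastic astrocytoma, IDH-wildtype, WHO grade III",
        IV = "Glioblastoma, IDH-wildtype, WHO grade IV",
        "Astrocytic glioma, IDH-wildtype, NOS-grade-unknown"))
  }
  label <- mapply(base, cluster, grade, USE.NAMES = FALSE)
  warn_iv <- cluster == "OLIGO_IDHmut_CODEL" & grade == "IV"
  if (any(warn_iv)) {
    warning("integrated_label: grade IV in the 1p/19q-codeleted cluster (",
            sum(warn_iv), " sample(s)); no WHO grade IV oligodendroglioma",
            " exists - check the input")
  }
  data.frame(label = label,
             warning_grade_IV_oligo = warn_iv,
             oa_resolved = histology_2007 %in% c("OA", "AOA"))
}

#' Cluster composition tables
#'
#' Contingency tables of cluster against 2007 histology and against WHO
#' grade.
#'
#' @param assignments data.frame with `sample_id`, `cluster`.
#' @param clinical clinical table with `sample_id`, `histology_2007`,
#'   `who_grade`.
#' @return list with `by_histology` and `by_grade` contingency tables.
#' @export
cluster_composition <- function(assignments, clinical) {
  m <- merge(assignments[, c("sample_id", "cluster")],
             clinical[, c("sample_id", "histology_2007", "who_grade")],
             by = "sample_id")
  list(by_histology = table(cluster = m$cluster, histology = m$histology_2007),
       by_grade = table(cluster = m$cluster, grade = m$who_grade))
}
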