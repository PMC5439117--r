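#' Default subtype rule tables
#'
#' Ordered decision tables mapping copy-number marker flags to the W1-W4
#' (IDH-wildtype) and M1-M3 (IDH-mutant) prognostic subtypes. Each rule is a
#' condition over named flags evaluated in order; the final catch-all is
#' mandatory so the table is total. The defaults implement: co-amplification
#' of CDK4/MDM2 overrides the chromosome rules (W4); chromosome 1 gain
#' -> W1; chromosome 19 gain -> W3; otherwise W2. For the IDH-mutant
#' cluster: CDK4 amplification or CDKN2A homozygous deletion -> M1;
#' chromosome 14 gain -> M2; otherwise M3. The branch order is a documented
#' package assumption consistent with the published marker lists and
#' survival ordering, not a verbatim published tree; override via a custom
#' rule table (or rules JSON on the CLI) if needed.
#'
#' @return list with elements `wildtype` and `mutant`, each an ordered list
#'   of `list(condition = <expression string>, label = <subtype>)`.
#' @export
default_rule_tables <- function() {
  list(
    wildtype = list(
      list(condition = "cdk4_mdm2_coamp", label = "W4"),
      list(condition = "chr1_gain", label = "W1"),
      list(condition = "chr19_gain", label = "W3"),
      list(condition = "TRUE", label = "W2")
    ),
    mutant = list(
      list(condition = "cdk4_amp || cdkn2a_homodel", label = "M1"),
      list(condition = "chr14_gain", label = "M2"),
      list(condition = "TRUE", label = "M3")
    )
  )
}

rule_flags <- function(rules) {
  fl <- unique(unlist(lapply(rules, function(r) {
    all.vars(parse(text = r$condition)[[1]])
  })))
  setdiff(fl, c("TRUE", "FALSE", "T", "F"))
}

apply_rule_table <- function(flags, rules) {
  needed <- rule_flags(rules)
  miss <- needed[!needed %in% names(flags) |
                   vapply(needed, function(f) is.null(flags[[f]]) ||
                            is.na(flags[[f]]), logical(1))]
  if (length(miss)) {
    stop("subtype rules: missing or unresolved marker flag(s): ",
         paste(miss, collapse = ", "))
  }
  for (r in rules) {
    if (isTRUE(eval(parse(text = r$condition), envir = as.list(flags)))) {
      return(r$label)
    }
  }
  stop("subtype rules: no rule matched (rule table lacks a catch-all)")
}

#' IDH-wildtype spatial subgroup (A/B/C)
#'
#' Subgroup A is separated from B and C by chromosome 1 gain or TP53
#' mutation; B and C are then separated by the presence (B) or absence (C)
#' of chromosome 19 gain. Vectorized.
#'
#' @param chr1_gain,tp53_mut,chr19_gain logical flags.
#' @return character vector in `{"A","B","C"}`.
#' @export
subgroup_wildtype <- function(chr1_gain, tp53_mut, chr19_gain) {
  if (anyNA(chr1_gain) || anyNA(tp53_mut) || anyNA(chr19_gain)) {
    stop("subgroup_wildtype: unresolved (NA) flags")
  }
  ifelse(chr1_gain | tp53_mut, "A", ifelse(chr19_gain, "B", "C"))
}

#' Classify an IDH-wildtype sample into W1-W4
#'
#' @param calls one-row `cna_callset` (or any list with the flags the rule
#'   table needs: `cdk4_mdm2_coamp`, `chr1_gain`, `chr19_gain`).
#' @param rules ordered rule table; default from [default_rule_tables()].
#' @return subtype label, one of W1-W4.
#' @export
classify_wildtype <- function(calls, rules = default_rule_tables()$wildtype) {
  apply_rule_table(as.list(calls), rules)
}

#' Classify an IDH-mutant sample into M1-M3
#'
#' @param calls one-row `cna_callset` (needs `cdk4_amp`, `cdkn2a_homodel`,
#'   `chr14_gain`).
#' @param rules ordered rule table; default from [default_rule_tables()].
#' @return subtype label, one of M1-M3.
#' @export
classify_mutant <- function(calls, rules = default_rule_tables()$mutant) {
  apply_rule_table(as.list(calls), rules)
}

#' Subtype a whole cohort
#'
#' Dispatches each sample on its cluster: the 1p/19q-codeleted cluster gets
#' `OLIGO_NA` (no W/M subtype is defined there), the IDH-wildtype cluster is
#' run through the wildtype rule table (and the A/B/C subgrouping), the
#' IDH-mutant cluster through the mutant table.
#'
#' @param clusters data.frame with `sample_id`, `cluster`.
#' @param callsets `cna_callset` data.frame.
#' @param mutations mutation table (for the TP53 flag in A/B/C subgrouping);
#'   optional.
#' @param rule_tables list(wildtype=, mutant=), see [default_rule_tables()].
#' @return data.frame: sample_id, cluster, subtype, subgroup (A/B/C for the
#'   IDH-wildtype cluster, NA otherwise).
#' @export
subtype_cohort <- function(clusters, callsets, mutations = NULL,
                           rule_tables = default_rule_tables()) {
  stopifnot(all(clusters$cluster %in% cluster_levels()))
  cs <- callsets[match(clusters$sample_id, callsets$sample_id), ,
                 drop = FALSE]
  if (anyNA(cs$sample_id)) {
    stop("subtype_cohort: sample(s) without call sets: ",
         paste(clusters$sample_id[is.na(cs$sample_id)], collapse = ", "))
  }
  tp53 <- clusters$sample_id %in%
    (if (is.null(mutations)) character(0)
     else mutations$sample_id[mutations$gene == "TP53"])
  n <- nrow(clusters)
  subtype <- character(n)
  subgroup <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cl <- clusters$cluster[i]
    if (cl == "OLIGO_IDHmut_CODEL") {
      subtype[i] <- "OLIGO_NA"
    } else if (cl == "ASTRO_IDHwt") {
      subtype[i] <- classify_wildtype(cs[i, ], rule_tables$wildtype)
      subgroup[i] <- subgroup_wildtype(cs$chr1_gain[i], tp53[i],
                                       cs$chr19_gain[i])
    } else {
      subtype[i] <- classify_mutant(cs[i, ], rule_tables$mutant)
    }
  }
  data.frame(sample_id = clusters$sample_id, cluster = clusters$cluster,
             subtype = subtype, subgroup = subgroup)
}
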