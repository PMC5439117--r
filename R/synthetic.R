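#' Marker names understood by the generator
#' @return character vector of marker flag names.
#' @export
marker_names <- function() {
  c("idh1", "idh2", "tp53", "atrx", "braf", "codel_1p19q", "chr1_gain",
    "chr7_gain", "chr14_gain", "chr19_gain", "chr20_gain", "chr4_loss",
    "chr10_loss", "loss_9p", "cdk4_amp", "mdm2_amp", "cdkn2a_homodel")
}

#' Default synthetic-cohort generator configuration
#'
#' Cluster sizes mirror the TCGA composition of the three molecular clusters
#' (176 codeleted / 251 IDH-mutant / 351 IDH-wildtype). Subtype median
#' survivals are the published W1-W3 and M1-M3 medians; W4 and the
#' oligodendroglial cluster are not printed anywhere and carry package
#' defaults (20 and 120 months). Age distributions place the wildtype peak
#' near 56-63 years, the IDH-mutant peak near 26-32 years, and give the
#' codeleted cluster a bimodal adult mixture peaking in the mid-30s and
#' mid-50s. Per-cluster marker prevalences are plausible defaults from the
#' glioma genomics literature, not published quantities; all values are
#' config-exposed.
#'
#' @param seed integer seed; all draws flow from it.
#' @return list (class `generator_config`); see fields in the source.
#' @export
default_generator_config <- function(seed = 7L) {
  prev <- list(
    OLIGO_IDHmut_CODEL = c(
      idh1 = 0.65, idh2 = 0.35, tp53 = 0.08, atrx = 0.03, braf = 0,
      codel_1p19q = 1.0, chr1_gain = 0, chr7_gain = 0.10, chr14_gain = 0,
      chr19_gain = 0, chr20_gain = 0.10, chr4_loss = 0.25,
      chr10_loss = 0.08, loss_9p = 0.10, cdk4_amp = 0, mdm2_amp = 0,
      cdkn2a_homodel = 0),
    ASTRO_IDHmut = c(
      idh1 = 0.90, idh2 = 0.10, tp53 = 0.80, atrx = 0.70, braf = 0,
      codel_1p19q = 0, chr1_gain = 0.05, chr7_gain = 0.35,
      chr14_gain = 0.20, chr19_gain = 0.05, chr20_gain = 0.05,
      chr4_loss = 0.10, chr10_loss = 0.15, loss_9p = 0.25,
      cdk4_amp = 0.10, mdm2_amp = 0.05, cdkn2a_homodel = 0.15),
    ASTRO_IDHwt = c(
      idh1 = 0, idh2 = 0, tp53 = 0.25, atrx = 0.05, braf = 0.03,
      codel_1p19q = 0, chr1_gain = 0.15, chr7_gain = 0.80,
      chr14_gain = 0.05, chr19_gain = 0.25, chr20_gain = 0.20,
      chr4_loss = 0.05, chr10_loss = 0.75, loss_9p = 0.45,
      cdk4_amp = 0.12, mdm2_amp = 0.08, cdkn2a_homodel = 0.45)
  )
  cfg <- list(
    n_per_cluster = c(OLIGO_IDHmut_CODEL = 176L, ASTRO_IDHmut = 251L,
                      ASTRO_IDHwt = 351L),
    marker_prevalence = prev,
    subtype_median_os = c(W1 = 6.6, W2 = 12.7, W3 = 15.2, W4 = 20.0,
                          M1 = 23.3, M2 = 63.0, M3 = 94.5,
                          OLIGO_NA = 120.0),
    censoring_rate = 0.3,
    age_params = list(
      OLIGO_IDHmut_CODEL = list(c(mean = 38, sd = 5, weight = 0.5),
                                c(mean = 56, sd = 5, weight = 0.5)),
      ASTRO_IDHmut = list(c(mean = 29, sd = 7, weight = 1)),
      ASTRO_IDHwt = list(c(mean = 59.5, sd = 8, weight = 1))),
    grade_distribution = list(
      OLIGO_IDHmut_CODEL = c(II = 0.60, III = 0.40, IV = 0),
      ASTRO_IDHmut = c(II = 0.35, III = 0.40, IV = 0.25),
      ASTRO_IDHwt = c(II = 0.10, III = 0.15, IV = 0.75)),
    noise_sd = 0.1,
    n_seg_pieces = 8L,
    seg_baseline_shift_sd = 0,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(all(cfg$n_per_cluster >= 0),
            all(names(cfg$n_per_cluster) %in% cluster_levels()))
  for (cl in names(cfg$marker_prevalence)) {
    p <- cfg$marker_prevalence[[cl]]
    unknown <- setdiff(names(p), marker_names())
    if (length(unknown)) {
      stop("generator config: unknown marker(s) in cluster ", cl, ": ",
           paste(unknown, collapse = ", "))
    }
    if (any(p < 0 | p > 1)) {
      stop("generator config: prevalence outside [0,1] in cluster ", cl)
    }
    if (sum(p[c("idh1", "idh2")]) > 1 + 1e-12) {
      stop("generator config: idh1 + idh2 prevalence > 1 in cluster ", cl)
    }
  }
  for (cl in names(cfg$age_params)) {
    w <- vapply(cfg$age_params[[cl]], function(x) x[["weight"]], numeric(1))
    if (abs(sum(w) - 1) > 1e-9) {
      stop("generator config: age mixture weights do not sum to 1 in ", cl)
    }
  }
  if (any(cfg$subtype_median_os <= 0)) {
    stop("generator config: subtype medians must be > 0")
  }
  stopifnot(cfg$censoring_rate >= 0, cfg$censoring_rate <= 1,
            cfg$noise_sd >= 0)
  invisible(cfg)
}

draw_ages <- function(n, comps) {
  if (n == 0L) return(numeric(0))
  w <- vapply(comps, function(x) x[["weight"]], numeric(1))
  pick <- sample.int(length(comps), n, replace = TRUE, prob = w)
  age <- vapply(seq_len(n), function(i) {
    stats::rnorm(1, comps[[pick[i]]][["mean"]], comps[[pick[i]]][["sd"]])
  }, numeric(1))
  round(pmax(age, 18), 1)
}

# signal implied by marker flags for one sample, keyed by gene-panel prefix;
# focal genes carry only their focal signal (see vignette)
gene_signal <- function(flags, prefix) {
  switch(prefix,
    C1P = if (flags[["codel_1p19q"]]) -1 else if (flags[["chr1_gain"]]) 1 else 0,
    C1Q = if (flags[["chr1_gain"]]) 1 else 0,
    C4 = if (flags[["chr4_loss"]]) -1 else 0,
    C7 = if (flags[["chr7_gain"]]) 1 else 0,
    C9P = ,
    C9P2 = if (flags[["loss_9p"]]) -1 else 0,
    C10 = if (flags[["chr10_loss"]]) -1 else 0,
    C14 = if (flags[["chr14_gain"]]) 1 else 0,
    C19P = if (flags[["chr19_gain"]]) 1 else 0,
    C19Q = if (flags[["codel_1p19q"]]) -1 else if (flags[["chr19_gain"]]) 1 else 0,
    C20 = if (flags[["chr20_gain"]]) 1 else 0,
    CDK4 = if (flags[["cdk4_amp"]]) 2 else 0,
    MDM2 = if (flags[["mdm2_amp"]]) 2 else 0,
    CDKN2A = if (flags[["cdkn2a_homodel"]]) -2 else 0,
    EGFR = 0,
    0)
}

segment_template <- function() {
  len <- grch37_chrom_lengths()
  rows <- list(
    list("1", 1, 121535434, "C1P"),
    list("1", 121535435, len[["1"]], "C1Q"),
    list("4", 1, len[["4"]], "C4"),
    list("7", 1, 55086713, "C7"),
    list("7", 55086714, 55324313, "EGFR"),
    list("7", 55324314, len[["7"]], "C7"),
    list("9", 1, 21967750, "C9P"),
    list("9", 21967751, 21995300, "CDKN2A"),
    list("9", 21995301, 47367679, "C9P2"),
    list("9", 47367680, len[["9"]], "NEUTRAL"),
    list("10", 1, len[["10"]], "C10"),
    list("12", 1, 58141509, "NEUTRAL"),
    list("12", 58141510, 58149796, "CDK4"),
    list("12", 58149797, 69201955, "NEUTRAL"),
    list("12", 69201956, 69239214, "MDM2"),
    list("12", 69239215, len[["12"]], "NEUTRAL"),
    list("14", 1, len[["14"]], "C14"),
    list("19", 1, 27681782, "C19P"),
    list("19", 27681783, len[["19"]], "C19Q"),
    list("20", 1, len[["20"]], "C20")
  )
  for (ch in c("2", "3", "5", "6", "8", "11", "13", "15", "16", "17",
               "18", "21", "22")) {
    rows[[length(rows) + 1L]] <- list(ch, 1, len[[ch]], "NEUTRAL")
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]],
               signal_key = r[[4]])
  }))
}

#' Simulate subtype-specific overall survival
#'
#' Event times are exponential with the subtype's configured median
#' (rate ln2 / median). Censoring is non-informative: each sample is subject
#' to an independent uniform censoring clock on [0, 2 x max configured
#' median] with probability `censoring_rate`; the realized censoring
#' fraction is therefore approximately (slightly below) the configured rate.
#' Uses the current RNG state; seed outside.
#'
#' @param subtype character vector of subtype labels.
#' @param medians named vector of median OS (months) per subtype.
#' @param censoring_rate probability of exposure to the censoring clock.
#' @return data.frame: os_months, event (1 = death observed).
#' @export
simulate_subtype_survival <- function(subtype, medians, censoring_rate) {
  if (!all(subtype %in% names(medians))) {
    stop("simulate_subtype_survival: subtype without configured median: ",
         paste(setdiff(subtype, names(medians)), collapse = ", "))
  }
  n <- length(subtype)
  med <- medians[subtype]
  t_true <- stats::rexp(n, rate = log(2) / med)
  cen_flag <- stats::runif(n) < censoring_rate
  c_time <- stats::runif(n, 0, 2 * max(medians))
  censored <- cen_flag & c_time < t_true
  data.frame(os_months = ifelse(censored, c_time, t_true),
             event = as.integer(!censored))
}

#' Generate a synthetic glioma cohort
#'
#' Draws, per sample: a cluster (per configured sizes), marker flags
#' (Bernoulli at configured prevalences, with structural constraints: IDH1
#' and IDH2 mutually exclusive; IDH mutation present in the two IDH-mutant
#' clusters only; 1p/19q codeletion only in the oligodendroglial cluster),
#' the subtype implied by the default decision tables, overall survival
#' (exponential at the subtype's configured median, with uniform censoring
#' applied at the configured rate), age (cluster-specific normal mixture),
#' grade and Karnofsky score. Emits a GISTIC-style gene score matrix, a
#' GRCh37 segment table carrying the same events, a mutation table and a
#' clinical table, plus the per-sample ground truth.
#'
#' @param config a [default_generator_config()]-style list; `config$seed`
#'   seeds all randomness.
#' @return list of class `glioma_cohort`: `gistic` (gene x sample matrix),
#'   `segments`, `mutations`, `clinical`, `truth`, `config`.
#' @export
generate_cohort <- function(config = default_generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  genes <- default_gene_annotation()
  rules <- default_rule_tables()
  clusters <- names(config$n_per_cluster)
  n_tot <- sum(config$n_per_cluster)

  samples <- character(0)
  truth_rows <- list()
  clin_rows <- list()
  mut_rows <- list()
  idx <- 0L
  for (cl in clusters) {
    n <- config$n_per_cluster[[cl]]
    if (n == 0L) next
    p <- config$marker_prevalence[[cl]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("SYN%04d", idx)
      flags <- stats::setNames(as.list(rep(FALSE, length(marker_names()))),
                               marker_names())
      # IDH: mutually exclusive draw; structurally absent in the wildtype
      # cluster, structurally defining for the other two
      u <- stats::runif(1)
      if (cl != "ASTRO_IDHwt") {
        flags$idh1 <- u < p[["idh1"]]
        flags$idh2 <- !flags$idh1 && u < p[["idh1"]] + p[["idh2"]]
        if (!flags$idh1 && !flags$idh2) flags$idh1 <- TRUE  # clusters are IDH-defined
      }
      flags$codel_1p19q <- cl == "OLIGO_IDHmut_CODEL" &&
        stats::runif(1) < p[["codel_1p19q"]]
      for (m in setdiff(marker_names(),
                        c("idh1", "idh2", "codel_1p19q"))) {
        flags[[m]] <- stats::runif(1) < p[[m]]
      }
      flags$cdk4_mdm2_coamp <- flags$cdk4_amp && flags$mdm2_amp
      subtype <- if (cl == "OLIGO_IDHmut_CODEL") "OLIGO_NA"
        else if (cl == "ASTRO_IDHwt") apply_rule_table(flags, rules$wildtype)
        else apply_rule_table(flags, rules$mutant)
      truth_rows[[idx]] <- data.frame(sample_id = sid, cluster = cl,
                                      subtype = subtype,
                                      as.data.frame(flags[marker_names()]))
      samples <- c(samples, sid)
    }
  }
  if (length(truth_rows) == 0L) {
    empty_truth <- data.frame(sample_id = character(0),
                              cluster = character(0),
                              subtype = character(0))
    for (m in marker_names()) empty_truth[[m]] <- logical(0)
    return(structure(list(
      gistic = matrix(numeric(0), nrow = nrow(genes), ncol = 0,
                      dimnames = list(genes$gene, NULL)),
      segments = data.frame(sample_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            log2 = numeric(0)),
      mutations = data.frame(sample_id = character(0), gene = character(0),
                             variant_class = character(0)),
      clinical = data.frame(sample_id = character(0), age_years = numeric(0),
                            histology_2007 = character(0),
                            who_grade = character(0), kps = numeric(0),
                            os_months = numeric(0), event = integer(0)),
      truth = empty_truth, config = config), class = "glioma_cohort"))
  }
  truth <- do.call(rbind, truth_rows)

  # survival, age, grade, KPS
  sv <- simulate_subtype_survival(truth$subtype, config$subtype_median_os,
                                  config$censoring_rate)
  os <- sv$os_months
  event <- sv$event

  age <- numeric(nrow(truth))
  grade <- character(nrow(truth))
  for (cl in clusters) {
    sel <- truth$cluster == cl
    if (!any(sel)) next
    age[sel] <- draw_ages(sum(sel), config$age_params[[cl]])
    gd <- config$grade_distribution[[cl]]
    grade[sel] <- sample(names(gd), sum(sel), replace = TRUE, prob = gd)
  }
  kps <- pmin(100, pmax(40, round(stats::rnorm(
    nrow(truth), 90 - 5 * (grade == "IV"), 8) / 10) * 10))
  histology <- vapply(seq_len(nrow(truth)), function(i) {
    cl <- truth$cluster[i]; g <- grade[i]
    if (g == "IV") return("GBM")
    if (cl == "OLIGO_IDHmut_CODEL") {
      if (g == "II") sample(c("O", "OA"), 1, prob = c(0.8, 0.2))
      else sample(c("AO", "AOA"), 1, prob = c(0.8, 0.2))
    } else if (cl == "ASTRO_IDHmut") {
      if (g == "II") sample(c("A", "OA"), 1, prob = c(0.85, 0.15))
      else sample(c("AA", "AOA"), 1, prob = c(0.85, 0.15))
    } else {
      if (g == "II") "A" else "AA"
    }
  }, character(1))
  clinical <- data.frame(sample_id = truth$sample_id,
                         age_years = age, histology_2007 = histology,
                         who_grade = grade, kps = kps,
                         os_months = round(os, 3), event = event)

  # mutation table
  mut_map <- c(idh1 = "IDH1", idh2 = "IDH2", tp53 = "TP53", atrx = "ATRX",
               braf = "BRAF")
  vc <- c(IDH1 = "Missense_Mutation", IDH2 = "Missense_Mutation",
          TP53 = "Missense_Mutation", ATRX = "Nonsense_Mutation",
          BRAF = "Missense_Mutation")
  for (m in names(mut_map)) {
    hit <- truth$sample_id[truth[[m]]]
    if (length(hit)) {
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sample_id = hit, gene = mut_map[[m]],
        variant_class = vc[[mut_map[[m]]]])
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample_id = character(0), gene = character(0),
               variant_class = character(0))
  mutations <- mutations[order(mutations$sample_id, mutations$gene), ,
                         drop = FALSE]
  rownames(mutations) <- NULL

  # GISTIC matrix: signal implied by flags + gaussian noise
  prefix <- sub("_G[0-9]+$", "", genes$gene)
  gistic <- matrix(0, nrow = nrow(genes), ncol = nrow(truth),
                   dimnames = list(genes$gene, truth$sample_id))
  for (j in seq_len(nrow(truth))) {
    fl <- as.list(truth[j, marker_names()])
    gistic[, j] <- vapply(prefix, gene_signal, numeric(1), flags = fl)
  }
  if (config$noise_sd > 0) {
    gistic <- gistic + matrix(stats::rnorm(length(gistic), 0,
                                           config$noise_sd),
                              nrow = nrow(gistic))
  }

  # segment table: same events as genomic intervals, non-focal regions split
  # into pieces with independent noise
  tmpl <- segment_template()
  seg_rows <- vector("list", nrow(truth))
  for (j in seq_len(nrow(truth))) {
    fl <- as.list(truth[j, marker_names()])
    shift <- if (config$seg_baseline_shift_sd > 0) {
      stats::rnorm(1, 0, config$seg_baseline_shift_sd)
    } else 0
    parts <- list()
    for (r in seq_len(nrow(tmpl))) {
      key <- tmpl$signal_key[r]
      sig <- if (key == "NEUTRAL") 0 else gene_signal(fl, key)
      npc <- if (key %in% c("CDK4", "MDM2", "CDKN2A", "EGFR")) 1L
             else config$n_seg_pieces
      bnd <- round(seq(tmpl$start[r] - 1, tmpl$end[r], length.out = npc + 1L))
      st <- bnd[-length(bnd)] + 1
      en <- bnd[-1L]
      parts[[r]] <- data.frame(
        sample_id = truth$sample_id[j], chrom = tmpl$chrom[r],
        start = st, end = en,
        log2 = sig + shift +
          if (config$noise_sd > 0) stats::rnorm(npc, 0, config$noise_sd)
          else 0)
    }
    seg_rows[[j]] <- do.call(rbind, parts)
  }
  segments <- if (nrow(truth)) do.call(rbind, seg_rows) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), log2 = numeric(0))
  rownames(segments) <- NULL
  rownames(truth) <- NULL

  structure(list(gistic = gistic, segments = segments,
                 mutations = mutations, clinical = clinical, truth = truth,
                 config = config),
            class = "glioma_cohort")
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat("Synthetic glioma cohort:", nrow(x$truth), "samples\n")
  print(table(x$truth$cluster))
  invisible(x)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param cohort a `glioma_cohort`.
#' @return data.frame: sample_id, cluster, subtype, one logical column per
#'   marker flag. This is the oracle joined against classifier output in
#'   recovery tests.
#' @export
ground_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  cohort$truth
}
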