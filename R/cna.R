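#' Length-weighted median
#'
#' Weighted median with a documented tie rule: values are sorted; the median
#' is the first value whose cumulative weight reaches half the total weight.
#' If a prefix's cumulative weight equals exactly half, the median is the
#' midpoint between that value and the next one (so two equal-weight values
#' at 0.1 and 0.3 give 0.2).
#'
#' @param x numeric values.
#' @param w positive weights (same length).
#' @return The weighted median, or `NA_real_` for empty input.
#' @export
weighted_median <- function(x, w) {
  if (length(x) == 0L) return(NA_real_)
  stopifnot(length(x) == length(w), all(w > 0), all(is.finite(x)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- cw[length(cw)] / 2
  i <- which(cw >= half - 1e-9 * cw[length(cw)])[1L]
  at_half <- abs(cw[i] - half) <= 1e-9 * cw[length(cw)]
  if (at_half && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' Baseline-correct a segment table
#'
#' Per-sample centering: every log2 value is shifted by minus the
#' length-weighted median of that sample's autosomal segments, so the shifted
#' per-sample weighted median is exactly 0. This stands in for the adapted
#' baseline-correction applied to methylation-array copy-number profiles.
#' The operation is idempotent.
#'
#' @param seg segment table (data.frame: sample_id, chrom, start, end, log2).
#' @param strategy `"median"` (default) or `"mode"`: mode centers on the
#'   midpoint of the most populated 0.1-wide log2 histogram bin instead.
#' @return Segment table with corrected `log2`.
#' @export
baseline_correct <- function(seg, strategy = c("median", "mode")) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(seg))
  for (s in unique(seg$sample_id)) {
    idx <- seg$sample_id == s & is_autosome(seg$chrom)
    if (!any(idx)) {
      stop("baseline_correct: sample '", s, "' has no autosomal segments")
    }
    w <- seg$end[idx] - seg$start[idx] + 1
    shift <- if (strategy == "median") {
      weighted_median(seg$log2[idx], w)
    } else {
      br <- seq(floor(min(seg$log2[idx]) * 10) / 10 - 0.05,
                ceiling(max(seg$log2[idx]) * 10) / 10 + 0.15, by = 0.1)
      h <- vapply(seq_len(length(br) - 1L), function(i) {
        sum(w[seg$log2[idx] >= br[i] & seg$log2[idx] < br[i + 1L]])
      }, numeric(1))
      k <- which.max(h)
      (br[k] + br[k + 1L]) / 2
    }
    sel <- seg$sample_id == s
    seg$log2[sel] <- seg$log2[sel] - shift
  }
  seg
}

#' Per-sample region median from segments
#'
#' Length-weighted median of log2 over the portions of segments intersecting
#' the region interval(s). Samples without overlap get `NA`.
#'
#' @param seg segment table.
#' @param region data.frame of intervals (`chrom`, `start`, `end`) or one row
#'   of a regions table.
#' @param samples optional sample ordering; defaults to unique IDs in `seg`.
#' @return Named numeric vector, one value per sample.
#' @export
region_median <- function(seg, region, samples = unique(seg$sample_id)) {
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  segc <- normalize_chrom(seg$chrom)
  vals <- vapply(samples, function(s) {
    vv <- numeric(0); ww <- numeric(0)
    for (i in seq_len(nrow(region))) {
      hit <- seg$sample_id == s & segc == normalize_chrom(region$chrom[i]) &
        seg$end >= region$start[i] & seg$start <= region$end[i]
      if (!any(hit)) next
      ov <- pmin(seg$end[hit], region$end[i]) -
        pmax(seg$start[hit], region$start[i]) + 1
      vv <- c(vv, seg$log2[hit]); ww <- c(ww, ov)
    }
    if (length(vv) == 0L) NA_real_ else weighted_median(vv, ww)
  }, numeric(1))
  names(vals) <- samples
  vals
}

#' Call a broad copy-number state
#'
#' Inclusive thresholding: gain if `value >= gain_thr`, loss if
#' `value <= loss_thr`, else neutral. Boundary values call as events.
#'
#' @param value finite log2 score (vectorized).
#' @param gain_thr,loss_thr thresholds, gain_thr > 0 > loss_thr.
#' @return character vector in `{"gain","loss","neutral"}`; `NA` in, `NA` out.
#' @export
call_state <- function(value, gain_thr, loss_thr) {
  stopifnot(gain_thr > 0, loss_thr < 0)
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- ifelse(value[ok] >= gain_thr, "gain",
                    ifelse(value[ok] <= loss_thr, "loss", "neutral"))
  out
}

#' Call a focal gene state (amplification / homozygous deletion)
#'
#' @param value finite log2 score (vectorized).
#' @param amp_thr,del_thr focal thresholds (defaults +0.6 / -0.6), inclusive.
#' @return character vector in
#'   `{"amplified","homozygously_deleted","neutral"}`.
#' @export
call_gene_focal <- function(value, amp_thr = 0.6, del_thr = -0.6) {
  st <- call_state(value, amp_thr, del_thr)
  unname(c(gain = "amplified", loss = "homozygously_deleted",
           neutral = "neutral")[st])
}

state_to_int <- function(st) {
  unname(c(gain = 1L, loss = -1L, neutral = 0L,
           amplified = 1L, homozygously_deleted = -1L)[st])
}

#' Build per-sample copy-number call sets
#'
#' Turns either a GISTIC gene-by-sample score matrix or a (baseline-corrected)
#' segment table into discrete per-region and per-gene calls plus the derived
#' marker flags the downstream classifiers consume. The GISTIC route uses the
#' +/-0.5 broad thresholds with region values = plain median of member-gene
#' scores; the segment route applies [baseline_correct()] then the +/-0.1
#' broad thresholds on length-weighted region medians. Focal gene calls use
#' +/-0.6 on both routes.
#'
#' @param gistic numeric gene x sample matrix (GISTIC scores), or `NULL`.
#' @param segments segment table, or `NULL`. Exactly one of `gistic`/
#'   `segments` is used, selected by `source`.
#' @param mutations optional mutation table (`sample_id`, `gene`); mutated
#'   gene counts enter the alteration burden.
#' @param regions region table, see [default_regions()].
#' @param genes gene annotation for GISTIC-route region membership.
#' @param thresholds see [default_thresholds()].
#' @param source `"gistic"` or `"segments"`.
#' @param baseline baseline-correction strategy for the segment route.
#' @return data.frame (class `cna_callset`), one row per sample: `sample_id`,
#'   integer region states `state_<region>` (-1/0/+1), gene states
#'   `gene_<gene>`, logical flags `codel_1p19q`, `chr1_gain`, `chr7_gain`,
#'   `chr14_gain`, `chr19_gain`, `chr20_gain`, `chr4_loss`, `chr10_loss`,
#'   `loss_9p`, `cdk4_amp`, `mdm2_amp`, `cdk4_mdm2_coamp`, `cdkn2a_homodel`,
#'   and integer `alteration_burden`.
#' @export
make_callsets <- function(gistic = NULL, segments = NULL, mutations = NULL,
                          regions = default_regions(),
                          genes = default_gene_annotation(),
                          thresholds = default_thresholds(),
                          source = c("gistic", "segments"),
                          baseline = c("median", "mode")) {
  source <- match.arg(source)
  validate_thresholds(thresholds)
  need <- c("1p", "19q", "9p", "chr1", "chr4", "chr7", "chr10", "chr14",
            "chr19", "chr20", "CDK4", "MDM2", "CDKN2A")
  missing_r <- setdiff(need, regions$region)
  if (length(missing_r)) {
    stop("make_callsets: region map lacks entries: ",
         paste(missing_r, collapse = ", "))
  }
  broad <- regions[regions$type != "gene", , drop = FALSE]
  focal <- regions[regions$type == "gene", , drop = FALSE]

  if (source == "gistic") {
    if (is.null(gistic)) stop("make_callsets: source='gistic' needs a matrix")
    samples <- colnames(gistic)
    gmap <- region_gene_map(broad, genes)
    rv <- sapply(broad$region, function(r) {
      memb <- intersect(gmap[[r]], rownames(gistic))
      if (length(memb) == 0L) return(rep(NA_real_, length(samples)))
      apply(gistic[memb, , drop = FALSE], 2, stats::median)
    })
    gv <- sapply(focal$region, function(g) {
      if (g %in% rownames(gistic)) gistic[g, ] else rep(NA_real_, length(samples))
    })
    gthr <- c(thresholds$gistic_gain, thresholds$gistic_loss)
  } else {
    if (is.null(segments)) stop("make_callsets: source='segments' needs a table")
    segments <- baseline_correct(segments, match.arg(baseline))
    samples <- unique(segments$sample_id)
    rv <- sapply(broad$region, function(r) {
      region_median(segments, broad[broad$region == r, ], samples)
    })
    gv <- sapply(focal$region, function(g) {
      region_median(segments, focal[focal$region == g, ], samples)
    })
    gthr <- c(thresholds$seg_gain, thresholds$seg_loss)
  }
  rv <- matrix(rv, nrow = length(samples),
               dimnames = list(samples, broad$region))
  gv <- matrix(gv, nrow = length(samples),
               dimnames = list(samples, focal$region))

  rstate <- apply(rv, 2, call_state, gain_thr = gthr[1], loss_thr = gthr[2])
  gstate <- apply(gv, 2, call_gene_focal,
                  amp_thr = thresholds$amp, del_thr = thresholds$homodel)
  rstate <- matrix(rstate, nrow = length(samples),
                   dimnames = list(samples, broad$region))
  gstate <- matrix(gstate, nrow = length(samples),
                   dimnames = list(samples, focal$region))

  ri <- apply(rstate, 2, state_to_int)
  gi <- apply(gstate, 2, state_to_int)
  ri <- matrix(ri, nrow = length(samples), dimnames = dimnames(rstate))
  gi <- matrix(gi, nrow = length(samples), dimnames = dimnames(gstate))

  flag <- function(reg, what) !is.na(rstate[, reg]) & rstate[, reg] == what
  out <- data.frame(
    sample_id = samples,
    codel_1p19q = flag("1p", "loss") & flag("19q", "loss"),
    chr1_gain = flag("chr1", "gain"),
    chr7_gain = flag("chr7", "gain"),
    chr14_gain = flag("chr14", "gain"),
    chr19_gain = flag("chr19", "gain"),
    chr20_gain = flag("chr20", "gain"),
    chr4_loss = flag("chr4", "loss"),
    chr10_loss = flag("chr10", "loss"),
    loss_9p = flag("9p", "loss"),
    cdk4_amp = !is.na(gstate[, "CDK4"]) & gstate[, "CDK4"] == "amplified",
    mdm2_amp = !is.na(gstate[, "MDM2"]) & gstate[, "MDM2"] == "amplified",
    cdkn2a_homodel = !is.na(gstate[, "CDKN2A"]) &
      gstate[, "CDKN2A"] == "homozygously_deleted",
    stringsAsFactors = FALSE
  )
  out$cdk4_mdm2_coamp <- out$cdk4_amp & out$mdm2_amp

  n_mut <- integer(length(samples))
  if (!is.null(mutations) && nrow(mutations)) {
    tb <- table(mutations$sample_id[!duplicated(
      paste(mutations$sample_id, mutations$gene))])
    n_mut <- as.integer(tb[samples])
    n_mut[is.na(n_mut)] <- 0L
  }
  out$alteration_burden <- rowSums(abs(ri), na.rm = TRUE) +
    rowSums(abs(gi), na.rm = TRUE) + n_mut

  states <- as.data.frame(ri)
  names(states) <- paste0("state_", colnames(ri))
  gstates <- as.data.frame(gi)
  names(gstates) <- paste0("gene_", colnames(gi))
  out <- cbind(out, states, gstates)
  rownames(out) <- NULL
  class(out) <- c("cna_callset", "data.frame")
  out
}

#' Call set for a single sample
#'
#' Convenience wrapper around [make_callsets()] for one sample.
#'
#' @param sample sample ID, must be present in the input.
#' @inheritParams make_callsets
#' @param ... passed to [make_callsets()].
#' @return One-row `cna_callset`.
#' @export
make_callset <- function(sample, gistic = NULL, segments = NULL, ...) {
  present <- if (!is.null(gistic)) sample %in% colnames(gistic)
             else sample %in% segments$sample_id
  if (!present) stop("make_callset: sample '", sample, "' not in input")
  cs <- make_callsets(gistic = gistic, segments = segments, ...)
  cs[cs$sample_id == sample, , drop = FALSE]
}

#' Per-cluster copy-number alteration frequencies
#'
#' @param callsets a `cna_callset` data.frame.
#' @param clusters named character vector or data.frame (`sample_id`,
#'   `cluster`) giving each sample's cluster.
#' @param regions region table; frequencies are reported for its non-gene
#'   regions, ordered by chromosome 1..22.
#' @return data.frame: cluster, region, chrom, gain_freq, loss_freq,
#'   neutral_freq, n.
#' @export
cna_frequency <- function(callsets, clusters,
                          regions = default_regions()) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(clusters$cluster, clusters$sample_id)
  }
  cl <- clusters[callsets$sample_id]
  if (anyNA(cl)) stop("cna_frequency: samples without cluster label")
  broad <- regions[regions$type != "gene", , drop = FALSE]
  ord <- order(match(normalize_chrom(broad$chrom),
                     c(as.character(1:22), "X", "Y")), broad$start)
  broad <- broad[ord, ]
  out <- list()
  for (cname in unique(cl)) {
    idx <- which(cl == cname)
    if (length(idx) == 0L) stop("cna_frequency: empty cluster '", cname, "'")
    for (i in seq_len(nrow(broad))) {
      st <- callsets[[paste0("state_", broad$region[i])]][idx]
      st <- st[!is.na(st)]
      n <- length(st)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cname, region = broad$region[i], chrom = broad$chrom[i],
        gain_freq = if (n) sum(st == 1L) / n else NA_real_,
        loss_freq = if (n) sum(st == -1L) / n else NA_real_,
        neutral_freq = if (n) sum(st == 0L) / n else NA_real_,
        n = n)
    }
  }
  do.call(rbind, out)
}
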