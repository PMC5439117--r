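seg_df <- function(sample, chrom, start, end, log2) {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             log2 = log2)
}

test_that("baseline correction centers per sample and is idempotent", {
  seg <- seg_df("S1", "1", c(1, 101), c(100, 200), c(0.2, 0.2))
  out <- baseline_correct(seg)
  expect_equal(out$log2, c(0, 0))

  # already centered input unchanged
  seg2 <- seg_df("S1", c("1", "2"), 1, 100, c(-0.3, 0.3))
  expect_equal(baseline_correct(seg2)$log2, seg2$log2)

  # per-sample independence
  seg3 <- rbind(seg_df("A", "1", 1, 100, 0.5),
                seg_df("B", "1", c(1, 101), c(100, 200), c(-0.1, 0.1)))
  out3 <- baseline_correct(seg3)
  expect_equal(out3$log2[out3$sample_id == "B"], c(-0.1, 0.1))
  expect_equal(out3$log2[out3$sample_id == "A"], 0)

  # idempotence on a messy profile
  set.seed(4)
  seg4 <- seg_df("S1", "1", seq(1, 901, 100), seq(100, 1000, 100),
                 rnorm(10, 0.2, 0.5))
  once <- baseline_correct(seg4)
  expect_equal(baseline_correct(once), once)

  # sample with only sex-chromosome segments errors by name
  seg5 <- seg_df("WEIRD", "X", 1, 100, 0.1)
  expect_error(baseline_correct(seg5), "WEIRD")
})

test_that("region median is the length-weighted median of overlaps", {
  reg <- data.frame(chrom = "1", start = 1, end = 1000000)
  seg <- seg_df("S1", "1", 1, 1000000, -0.35)
  expect_equal(region_median(seg, reg)[["S1"]], -0.35)

  # two equal-length overlapping segments -> midpoint by documented rule;
  # cross-checked with a brute-force per-bp oracle on a tiny region
  seg2 <- seg_df("S1", c("1", "1"), c(1, 1), c(10, 10), c(0.1, 0.3))
  reg2 <- data.frame(chrom = "1", start = 1, end = 10)
  expect_equal(region_median(seg2, reg2)[["S1"]], 0.2)
  expect_equal(region_median(seg2, reg2)[["S1"]],
               bp_region_median(seg2, "1", 1, 10))

  # partial overlap weighting, brute-force cross-check
  seg3 <- seg_df("S1", c("1", "1"), c(1, 7), c(8, 20), c(-0.4, 0.6))
  reg3 <- data.frame(chrom = "1", start = 5, end = 16)
  expect_equal(region_median(seg3, reg3)[["S1"]],
               bp_region_median(seg_df("S1", "1", c(5, 7), c(8, 16),
                                       c(-0.4, 0.6)), "1", 5, 16))

  # region with no coverage -> missing
  regx <- data.frame(chrom = "X", start = 1, end = 100)
  expect_true(is.na(region_median(seg, regx)[["S1"]]))
})

test_that("threshold calling is inclusive at every documented boundary", {
  expect_equal(call_state(0.6, 0.5, -0.5), "gain")
  expect_equal(call_state(0.5, 0.5, -0.5), "gain")
  expect_equal(call_state(-0.5, 0.5, -0.5), "loss")
  expect_equal(call_state(0.0, 0.5, -0.5), "neutral")
  expect_equal(call_state(-0.1, 0.1, -0.1), "loss")
  expect_equal(call_state(0.1, 0.1, -0.1), "gain")
  expect_equal(call_gene_focal(0.9), "amplified")
  expect_equal(call_gene_focal(0.6), "amplified")
  expect_equal(call_gene_focal(-1.4), "homozygously_deleted")
  expect_equal(call_gene_focal(-0.6), "homozygously_deleted")
  expect_equal(call_gene_focal(0.5), "neutral")  # broad-gain level, not focal
})

test_that("raising the gain threshold never creates gains (monotonicity)", {
  set.seed(8)
  v <- runif(200, -1, 1)
  lo <- call_state(v, 0.3, -0.3)
  hi <- call_state(v, 0.6, -0.3)
  expect_false(any(lo == "neutral" & hi == "gain"))
  expect_true(all(hi[lo == "neutral"] != "gain"))
})

test_that("make_callsets derives flags per contract", {
  co <- small_cohort()
  cs <- make_callsets(gistic = co$gistic, mutations = co$mutations)
  tr <- ground_truth_table(co)
  expect_equal(cs$sample_id, tr$sample_id)
  # invariants tie derived flags to their components
  expect_equal(cs$cdk4_mdm2_coamp, cs$cdk4_amp & cs$mdm2_amp)
  expect_equal(cs$codel_1p19q,
               cs$state_1p == -1L & cs$state_19q == -1L)
  # noise-free recovery of every generator flag
  for (f in c("codel_1p19q", "chr1_gain", "chr7_gain", "chr14_gain",
              "chr19_gain", "chr20_gain", "chr4_loss", "chr10_loss",
              "loss_9p", "cdk4_amp", "mdm2_amp", "cdkn2a_homodel")) {
    expect_equal(cs[[f]], tr[[f]], label = f)
  }
  # all-neutral sample: burden counts only mutations
  g0 <- co$gistic
  g0[, 1] <- 0
  cs0 <- make_callsets(gistic = g0, mutations = co$mutations)
  nmut <- length(unique(co$mutations$gene[co$mutations$sample_id ==
                                            cs0$sample_id[1]]))
  expect_equal(cs0$alteration_burden[1], nmut)
})

test_that("segment route matches gistic route on a noise-free cohort", {
  co <- small_cohort()
  cs_g <- make_callsets(gistic = co$gistic)
  cs_s <- make_callsets(segments = co$segments, source = "segments")
  for (f in c("codel_1p19q", "chr1_gain", "chr7_gain", "chr14_gain",
              "chr19_gain", "chr20_gain", "chr10_loss", "loss_9p",
              "cdk4_amp", "mdm2_amp", "cdkn2a_homodel")) {
    expect_equal(cs_s[[f]][match(cs_g$sample_id, cs_s$sample_id)],
                 cs_g[[f]], label = f)
  }
})

test_that("chrN dialect produces identical downstream calls", {
  co <- small_cohort()
  seg <- co$segments
  seg2 <- seg
  seg2$chrom <- paste0("chr", seg2$chrom)
  d <- withr::local_tempdir()
  p <- file.path(d, "seg.tsv")
  write.table(seg2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  cs_a <- make_callsets(segments = seg, source = "segments")
  cs_b <- make_callsets(segments = read_segments(p), source = "segments")
  expect_equal(cs_a, cs_b)
})

test_that("make_callset extracts one sample and validates presence", {
  co <- small_cohort()
  one <- make_callset(co$truth$sample_id[3], gistic = co$gistic)
  expect_equal(nrow(one), 1L)
  expect_equal(one$sample_id, co$truth$sample_id[3])
  expect_error(make_callset("NOPE", gistic = co$gistic), "NOPE")
})

test_that("cna_frequency counts events and conserves mass", {
  co <- small_cohort()
  cs <- make_callsets(gistic = co$gistic)
  tr <- ground_truth_table(co)
  fr <- cna_frequency(cs, data.frame(sample_id = tr$sample_id,
                                     cluster = tr$cluster))
  expect_true(all(fr$gain_freq >= 0 & fr$gain_freq <= 1))
  expect_equal(fr$gain_freq + fr$loss_freq + fr$neutral_freq,
               rep(1, nrow(fr)))
  # codeleted cluster with prevalence 1 -> loss frequency 1 on 1p and 19q
  ol <- fr[fr$cluster == "OLIGO_IDHmut_CODEL", ]
  expect_equal(ol$loss_freq[ol$region == "1p"], 1)
  expect_equal(ol$loss_freq[ol$region == "19q"], 1)
  # direct-count spot check
  wt <- fr[fr$cluster == "ASTRO_IDHwt" & fr$region == "chr7", ]
  expect_equal(wt$gain_freq,
               mean(tr$chr7_gain[tr$cluster == "ASTRO_IDHwt"]))
  # chromosome ordering 1 -> 22
  chroms <- as.integer(unique(fr$chrom))
  expect_true(!is.unsorted(chroms))
  expect_error(cna_frequency(cs, setNames(rep("A", 0), character(0))),
               "cluster")
})
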