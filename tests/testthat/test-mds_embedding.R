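test_that("alteration matrix encodes mutations and CNA states", {
  co <- small_cohort()
  cs <- make_callsets(gistic = co$gistic, mutations = co$mutations)
  M <- suppressWarnings(build_alteration_matrix(co$mutations, cs))
  tr <- ground_truth_table(co)
  s_oligo <- tr$sample_id[tr$cluster == "OLIGO_IDHmut_CODEL"][1]
  expect_equal(unname(M[s_oligo, c("1p", "19q")]), c(-1, -1))
  idh1_s <- unique(co$mutations$sample_id[co$mutations$gene == "IDH1"])
  expect_true(all(M[idh1_s, "IDH1"] == 1))
  expect_true(all(M[setdiff(rownames(M), idh1_s), "IDH1"] == 0))
  expect_true(all(M %in% c(-1, 0, 1)))
  expect_error(build_alteration_matrix(co$mutations, cs,
                                       mutation_genes = character(0),
                                       cna_regions = character(0)),
               "empty feature")
})

test_that("pairwise distances follow the chosen metric", {
  M <- rbind(a = c(0, 0), b = c(1, 0))
  D <- pairwise_distance(M)
  expect_equal(D["a", "b"], 1)
  expect_equal(diag(D), c(a = 0, b = 0))

  M2 <- rbind(a = c(1, -1, 0), b = c(-1, 1, 0), c = c(1, -1, 0))
  D2 <- pairwise_distance(M2)
  expect_equal(D2["a", "b"], 2 * sqrt(2))
  expect_equal(D2["a", "c"], 0)     # identical rows
  expect_true(isSymmetric(D2))

  Dj <- pairwise_distance(rbind(a = c(1, 1, 0), b = c(1, 0, 0)), "jaccard")
  expect_equal(Dj["a", "b"], 0.5)
  expect_error(pairwise_distance(M[1, , drop = FALSE]), ">= 2")
})

test_that("classical MDS recovers collinear and exact configurations", {
  # 3 collinear points, d = (1, 1, 2): 1D coords are {-1, 0, +1} up to sign
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  e <- classical_mds(D, 1)
  expect_equal(sort(e$points[, 1]), c(-1, 0, 1), tolerance = 1e-8)
  expect_lt(abs(e$eigenvalues[2]), 1e-8)

  # unit square corners reproduce their distances exactly in 2D
  P <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  e2 <- classical_mds(as.matrix(dist(P)), 2)
  expect_equal(as.matrix(dist(e2$points)), as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # identical points embed at the origin
  D0 <- matrix(0, 4, 4)
  e0 <- classical_mds(D0, 2)
  expect_true(all(e0$points == 0))

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
  expect_error(classical_mds(D, 3), "k out of range")
})

test_that("MDS matches cmdscale and stays sign-deterministic", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    P <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(dist(P))
    e <- classical_mds(D, 3)
    ref <- cmdscale(D, k = 3, eig = TRUE)
    expect_equal(abs(e$points), abs(ref$points), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(e$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
    # columns centered, eigenvalues non-increasing
    expect_lt(max(abs(colSums(e$points))), 1e-9 * n)
    expect_true(!is.unsorted(rev(e$eigenvalues)))
    # repeated call identical (sign convention deterministic)
    expect_identical(e$points, classical_mds(D, 3)$points)
  }
})

test_that("non-Euclidean input zeroes negative axes with a warning", {
  # strongly non-Euclidean dissimilarities: the double-centered matrix has
  # two negative eigenvalues, so the 4th axis of a k = 4 embedding is invalid
  D <- matrix(0, 5, 5)
  D[upper.tri(D)] <- c(1, 2, 1, 1, 5, 1, 9, 1, 1, 1)
  D <- D + t(D)
  expect_warning(e <- classical_mds(D, 4), "negative eigenvalue")
  expect_true(all(e$points[, 4] == 0))
  expect_true(any(e$points[, 1] != 0))
})

test_that("cohort embedding separates true clusters and is order-invariant", {
  co <- small_cohort()
  cs <- make_callsets(gistic = co$gistic, mutations = co$mutations)
  tr <- ground_truth_table(co)
  emb <- suppressWarnings(
    embed_cohort(co$mutations, cs, k = 2,
                 clusters = data.frame(sample_id = tr$sample_id,
                                       cluster = tr$cluster)))
  expect_equal(ncol(emb$embedding$points), 2L)
  expect_gt(mean_silhouette(emb$embedding$points, emb$table$cluster), 0.5)
  expect_equal(emb$table$burden,
               unname(cs$alteration_burden[match(emb$table$sample_id,
                                                 cs$sample_id)]))
  # permuting sample order leaves the geometry unchanged
  perm <- sample(nrow(cs))
  cs_p <- cs[perm, ]
  emb_p <- suppressWarnings(embed_cohort(co$mutations, cs_p, k = 2))
  d1 <- as.matrix(dist(emb$embedding$points))
  d2 <- as.matrix(dist(emb_p$embedding$points))
  ord <- match(emb$table$sample_id, emb_p$table$sample_id)
  expect_equal(d2[ord, ord], d1, tolerance = 1e-10, ignore_attr = TRUE)
  # k = 3 has three coordinate columns
  emb3 <- suppressWarnings(embed_cohort(co$mutations, cs, k = 3))
  expect_equal(colnames(emb3$embedding$points), c("mds1", "mds2", "mds3"))
})
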