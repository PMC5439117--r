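#' Build the molecular alteration matrix
#'
#' One binary column per configured mutation gene (1 = mutated) and one
#' ternary column per configured copy-number region (+1 gain, -1 loss,
#' 0 neutral), over the union of samples seen in either source. Samples
#' absent from one source get zeros there, with a warning.
#'
#' @param mutations mutation table (`sample_id`, `gene`), or `NULL`.
#' @param callsets `cna_callset` data.frame, or `NULL`.
#' @param mutation_genes character vector of mutation indicator columns.
#' @param cna_regions character vector of region names to take from the
#'   callset `state_*` columns.
#' @return numeric sample x feature matrix (class kept plain; rownames are
#'   sample IDs).
#' @export
build_alteration_matrix <- function(mutations = NULL, callsets = NULL,
                                    mutation_genes = c("IDH1", "IDH2", "TP53",
                                                       "ATRX", "BRAF"),
                                    cna_regions = c("1p", "19q", "9p", "chr1",
                                                    "chr4", "chr7", "chr10",
                                                    "chr14", "chr19",
                                                    "chr20")) {
  mutation_genes <- unique(mutation_genes)
  cna_regions <- unique(cna_regions)
  if (length(mutation_genes) + length(cna_regions) == 0L) {
    stop("build_alteration_matrix: empty feature set")
  }
  s_mut <- if (!is.null(mutations)) unique(mutations$sample_id) else character(0)
  s_cna <- if (!is.null(callsets)) callsets$sample_id else character(0)
  samples <- union(s_cna, s_mut)
  if (length(samples) == 0L) stop("build_alteration_matrix: no samples")
  only_one <- c(setdiff(s_cna, s_mut), setdiff(s_mut, s_cna))
  if (length(only_one) && length(s_mut) && length(s_cna)) {
    warning("build_alteration_matrix: ", length(only_one),
            " sample(s) missing from one source; zero-filled")
  }
  M <- matrix(0, nrow = length(samples),
              ncol = length(mutation_genes) + length(cna_regions),
              dimnames = list(samples, c(mutation_genes, cna_regions)))
  if (!is.null(mutations) && length(mutation_genes)) {
    for (g in mutation_genes) {
      hit <- unique(mutations$sample_id[mutations$gene == g])
      M[intersect(hit, samples), g] <- 1
    }
  }
  if (!is.null(callsets) && length(cna_regions)) {
    for (r in cna_regions) {
      col <- paste0("state_", r)
      if (!col %in% names(callsets)) {
        stop("build_alteration_matrix: callsets lack region state '", r, "'")
      }
      v <- callsets[[col]]
      v[is.na(v)] <- 0L
      M[callsets$sample_id, r] <- v
    }
  }
  M
}

#' Pairwise distances between alteration profiles
#'
#' @param M sample x feature numeric matrix.
#' @param metric `"euclidean"` (default) or `"jaccard"`; jaccard binarizes to
#'   altered/not-altered first and returns 1 - Jaccard similarity.
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(M, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  if (nrow(M) < 2L) stop("pairwise_distance: need >= 2 samples")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(M, method = "euclidean"))
  } else {
    B <- (M != 0) * 1L
    inter <- B %*% t(B)
    tot <- rowSums(B)
    uni <- outer(tot, tot, "+") - inter
    D <- 1 - inter / uni
    D[uni == 0] <- 0    # two all-zero profiles are identical
    diag(D) <- 0
  }
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, B = -1/2 J D^2 J with
#' J = I - 11'/n, eigendecomposes B and returns the top-k eigenvectors scaled
#' by the square root of their eigenvalues. Axes with non-positive
#' eigenvalues among the top k are zeroed with a warning. Each axis' sign is
#' fixed so its largest-magnitude loading is positive, making the output
#' deterministic.
#'
#' @param D symmetric nonnegative distance matrix, zero diagonal.
#' @param k number of output dimensions, 1 <= k <= n-1.
#' @return list of class `mds_embedding`: `points` (n x k), `eigenvalues`
#'   (all n, non-increasing), `k`.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("classical_mds: distance matrix must be symmetric")
  }
  if (k < 1L || k > n - 1L) stop("classical_mds: k out of range [1, n-1]")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  lam <- eg$values
  pts <- matrix(0, n, k)
  for (j in seq_len(k)) {
    if (lam[j] > 1e-12) {
      v <- eg$vectors[, j] * sqrt(lam[j])
      if (v[which.max(abs(v))] < 0) v <- -v
      pts[, j] <- v
    } else if (lam[j] < -1e-12) {
      warning("classical_mds: axis ", j,
              " has negative eigenvalue; coordinates zeroed")
    }
  }
  dimnames(pts) <- list(rownames(D), paste0("mds", seq_len(k)))
  structure(list(points = pts, eigenvalues = lam, k = k),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$points), "samples,",
      x$k, "dimensions\n")
  pos <- sum(pmax(x$eigenvalues, 0))
  kmass <- sum(pmax(x$eigenvalues[seq_len(x$k)], 0))
  cat(sprintf("  variance captured by %d axes: %.1f%%\n", x$k,
              if (pos > 0) 100 * kmass / pos else 0))
  invisible(x)
}

#' Embed a cohort in MDS space
#'
#' Composition of [build_alteration_matrix()], [pairwise_distance()] and
#' [classical_mds()]; attaches per-sample alteration burden (dot-size weight
#' in the cluster maps) and, if given, cluster labels.
#'
#' @param mutations,callsets inputs to [build_alteration_matrix()].
#' @param k embedding dimension (2 or 3 in practice).
#' @param clusters optional data.frame (`sample_id`, `cluster`).
#' @param metric distance metric, see [pairwise_distance()].
#' @param ... feature configuration passed to [build_alteration_matrix()].
#' @return list of class `cohort_embedding`: `embedding` (`mds_embedding`),
#'   `table` (sample_id, mds1..mdsk, burden, cluster).
#' @export
embed_cohort <- function(mutations, callsets, k = 2L, clusters = NULL,
                         metric = "euclidean", ...) {
  M <- build_alteration_matrix(mutations, callsets, ...)
  D <- pairwise_distance(M, metric)
  emb <- classical_mds(D, k)
  tab <- data.frame(sample_id = rownames(M), emb$points, row.names = NULL)
  burden <- stats::setNames(callsets$alteration_burden, callsets$sample_id)
  tab$burden <- as.integer(burden[tab$sample_id])
  if (!is.null(clusters)) {
    cl <- stats::setNames(clusters$cluster, clusters$sample_id)
    tab$cluster <- as.character(cl[tab$sample_id])
  }
  structure(list(embedding = emb, table = tab), class = "cohort_embedding")
}
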