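# Independent oracles and shared fixtures for the test suite.

# Naive Cox partial log-likelihood (single covariate), computed from the
# definition with explicit risk sets -- independent of cox_derivs().
naive_cox_loglik <- function(beta, time, event, x,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    wr <- sum(exp(beta * x[R]))
    wd <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_along(D) - 1) {
      frac <- if (ties == "efron") l / length(D) else 0
      ll <- ll - log(wr - frac * wd)
    }
  }
  ll
}

# Brute-force maximum of the naive partial likelihood over a 1-D grid.
naive_cox_mle <- function(time, event, x, ties = "efron",
                          lower = -10, upper = 10) {
  stats::optimize(function(b) naive_cox_loglik(b, time, event, x, ties),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# Naive product-limit estimator via explicit counts.
naive_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    n <- sum(time >= ut[i])
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Brute-force per-bp weighted median of segment coverage over a region,
# for small coordinate ranges only.
bp_region_median <- function(seg, chrom, lo, hi) {
  vals <- c()
  for (pos in lo:hi) {
    hit <- seg$chrom == chrom & seg$start <= pos & seg$end >= pos
    vals <- c(vals, seg$log2[hit])
  }
  # documented rule: midpoint when the half-weight boundary is exact
  v <- sort(vals)
  n <- length(v)
  if (n %% 2 == 0) (v[n / 2] + v[n / 2 + 1]) / 2 else v[(n + 1) / 2]
}

# Mean silhouette width of a labelling over embedded coordinates.
mean_silhouette <- function(pts, lab) {
  D <- as.matrix(stats::dist(pts))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(lab == lab[i]), i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(D[i, lab == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small noise-free cohort shared across tests (built once per test run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_generator_config(seed = 11)
      cfg$n_per_cluster <- c(OLIGO_IDHmut_CODEL = 20L, ASTRO_IDHmut = 30L,
                             ASTRO_IDHwt = 40L)
      cfg$noise_sd <- 0
      cfg$censoring_rate <- 0
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

all_flags <- function(...) {
  g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
  g
}
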