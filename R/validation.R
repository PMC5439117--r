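#' Merge statistically indistinguishable subtype groups
#'
#' Computes the pairwise Cox p-value between two candidate groups; if it
#' exceeds `alpha` the groups are merged under a combined label (e.g.
#' `"W1/W2"`) and the merge is recorded. With `alpha = 0` nothing ever
#' merges.
#'
#' @param time,event survival data.
#' @param group group labels.
#' @param pair character vector of length 2: the candidate groups.
#' @param alpha significance threshold (default 0.05).
#' @return list: `group` (possibly-merged labels), `merged` (logical),
#'   `p` (the pairwise Cox p-value), `label` (merged label or `NA`).
#' @export
merge_indistinguishable <- function(time, event, group, pair,
                                    alpha = 0.05) {
  stopifnot(length(pair) == 2L)
  group <- as.character(group)
  for (g in pair) {
    if (!any(group == g, na.rm = TRUE)) {
      stop("merge_indistinguishable: empty group '", g, "'")
    }
  }
  sel <- group %in% pair
  fit <- cox_ph(time[sel], event[sel],
                matrix(as.numeric(group[sel] == pair[2L]), ncol = 1,
                       dimnames = list(NULL, pair[2L])))
  p <- fit$coefficients$p[1L]
  merged <- alpha > 0 && p > alpha   # alpha = 0 disables merging
  lab <- NA_character_
  if (merged) {
    lab <- paste(pair, collapse = "/")
    group[group %in% pair] <- lab
  }
  list(group = group, merged = merged, p = p, label = lab)
}

#' Normalize median overall survival to a baseline
#'
#' Kaplan-Meier median per group, divided by the KM median of the pooled
#' baseline records. Baseline group(s) pooled then normalized value is 1 by
#' construction (exactly 1 for a single baseline group).
#'
#' @param time,event survival data.
#' @param group group labels.
#' @param baseline character vector of baseline group label(s).
#' @return list of class `normalized_os`: `table` (group, median_os,
#'   normalized), `baseline` (labels), `baseline_median`.
#' @export
normalize_os <- function(time, event, group, baseline) {
  group <- as.character(group)
  lev <- sort(unique(group[!is.na(group)]))
  if (!all(baseline %in% lev)) {
    stop("normalize_os: baseline group(s) absent: ",
         paste(setdiff(baseline, lev), collapse = ", "))
  }
  med <- vapply(lev, function(g) {
    km_estimate(time[group == g], event[group == g])$median
  }, numeric(1))
  if (anyNA(med)) {
    stop("normalize_os: undefined median in group '",
         lev[which(is.na(med))[1L]], "' (survival never reaches 0.5)")
  }
  bsel <- group %in% baseline
  bmed <- km_estimate(time[bsel], event[bsel])$median
  if (is.na(bmed) || bmed <= 0) {
    stop("normalize_os: baseline median undefined or non-positive")
  }
  structure(list(table = data.frame(group = lev, median_os = med,
                                    normalized = med / bmed,
                                    row.names = NULL),
                 baseline = baseline, baseline_median = bmed),
            class = "normalized_os")
}

#' Cross-cohort regression of normalized survival
#'
#' Ordinary least squares of cohort B's normalized median OS on cohort A's,
#' over the subtype labels shared by both. Free intercept by default;
#' `through_origin = TRUE` forces the line through zero.
#'
#' @param norm_a,norm_b `normalized_os` objects (or their `$table`s).
#' @param through_origin logical.
#' @return list of class `cohort_regression`: `slope`, `intercept`, `R`
#'   (Pearson correlation of the shared points), `n`, `labels`.
#' @export
cross_cohort_regression <- function(norm_a, norm_b,
                                    through_origin = FALSE) {
  ta <- if (inherits(norm_a, "normalized_os")) norm_a$table else norm_a
  tb <- if (inherits(norm_b, "normalized_os")) norm_b$table else norm_b
  shared <- intersect(ta$group, tb$group)
  if (length(shared) < 2L) {
    stop("cross_cohort_regression: < 2 shared subtype labels")
  }
  a <- ta$normalized[match(shared, ta$group)]
  b <- tb$normalized[match(shared, tb$group)]
  fit <- if (through_origin) stats::lm(b ~ a + 0) else stats::lm(b ~ a)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[["a"]]),
                 intercept = if (through_origin) 0
                             else unname(co[["(Intercept)"]]),
                 R = stats::cor(a, b), n = length(shared),
                 labels = shared),
            class = "cohort_regression")
}

#' @export
print.cohort_regression <- function(x, ...) {
  cat(sprintf("Cross-cohort regression over %d subtypes: slope = %.3f, ",
              x$n, x$slope))
  cat(sprintf("intercept = %.3f, R = %.3f\n", x$intercept, x$R))
  invisible(x)
}
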