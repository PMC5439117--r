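#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times (months), non-negative.
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @return list of class `km_curve`: `table` (data.frame time, n_risk,
#'   n_event, n_censor, surv over distinct event times), `median` (smallest
#'   event time with S(t) <= 0.5, `NA` if S never reaches 0.5), `n`,
#'   `n_event`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L || all(is.na(time))) {
    stop("km_estimate: no usable survival times")
  }
  ok <- !is.na(time) & !is.na(event)
  time <- time[ok]; event <- as.integer(event[ok])
  stopifnot(all(time >= 0), all(event %in% c(0L, 1L)))
  ut <- sort(unique(time[event == 1L]))
  n <- length(time)
  surv <- numeric(length(ut))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event == 1L)
    n_censor[i] <- sum(time == t & event == 0L)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5 + 1e-12)) ut[which(surv <= 0.5 + 1e-12)[1L]]
         else NA_real_
  structure(list(table = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 median = med, n = n, n_event = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$n_event,
      ", median =", if (is.na(x$median)) "not reached" else
        sprintf("%.2f", x$median), "\n")
  invisible(x)
}

# Partial log-likelihood, score and information for the Cox model.
# Data must be sorted by increasing time; tied event times handled by Efron
# or Breslow. Returns list(loglik, score, info). The linear predictor is
# shifted by its maximum for numerical stability; the partial likelihood is
# invariant to that shift.
cox_derivs <- function(beta, time, event, X, ties) {
  n <- length(time)
  d <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)
  w <- exp(eta)
  # reverse cumulative aggregates: risk set at t = indices with time >= t,
  # which is a suffix of the sorted vector
  rev_cum <- function(v) rev(cumsum(rev(v)))
  S0 <- rev_cum(w)
  S1 <- matrix(apply(X * w, 2, rev_cum), nrow = n)
  pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  S2 <- matrix(sapply(seq_len(nrow(pairs)), function(p) {
    rev_cum(X[, pairs[p, 1]] * X[, pairs[p, 2]] * w)
  }), nrow = n)
  unpack2 <- function(row) {
    m <- matrix(0, d, d)
    m[cbind(pairs[, 1], pairs[, 2])] <- row
    m[cbind(pairs[, 2], pairs[, 1])] <- row
    m
  }
  ll <- 0
  U <- numeric(d)
  I <- matrix(0, d, d)
  ut <- unique(time[event == 1L])
  first_at <- match(ut, time)
  for (j in seq_along(ut)) {
    t <- ut[j]
    k <- first_at[j]
    tied <- which(time == t & event == 1L)
    Dj <- length(tied)
    s0r <- S0[k]
    s1r <- S1[k, ]
    s2r <- unpack2(S2[k, ])
    wt <- w[tied]
    s0t <- sum(wt)
    s1t <- colSums(X[tied, , drop = FALSE] * wt)
    s2t <- t(X[tied, , drop = FALSE] * wt) %*% X[tied, , drop = FALSE]
    ll <- ll + sum(eta[tied])
    U <- U + colSums(X[tied, , drop = FALSE])
    for (l in seq_len(Dj) - 1L) {
      frac <- if (ties == "efron") l / Dj else 0
      z0 <- s0r - frac * s0t
      z1 <- s1r - frac * s1t
      z2 <- s2r - frac * s2t
      ll <- ll - log(z0)
      U <- U - z1 / z0
      I <- I + z2 / z0 - tcrossprod(z1 / z0)
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson (convergence when
#' the largest absolute score component drops below `tol`, or `max_iter`
#' iterations). Efron tie handling by default (Breslow available). Wald 95%
#' confidence intervals and p-values.
#'
#' @param time,event survival times and event indicators.
#' @param X covariate matrix (n x d) or vector; must be non-constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return list of class `cox_result`: `coefficients` data.frame (term, coef,
#'   HR, se, ci_low, ci_high, p), `loglik`, `n`, `n_event`, `ties`,
#'   `converged`, `separation` (monotone-likelihood flag).
#' @export
cox_ph <- function(time, event, X, ties = c("efron", "breslow"),
                   max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- !is.na(time) & !is.na(event) & stats::complete.cases(X)
  time <- time[ok]; event <- as.integer(event[ok])
  X <- X[ok, , drop = FALSE]
  if (sum(event) == 0L) stop("cox_ph: zero events")
  if (any(apply(X, 2, function(v) length(unique(v)) < 2L))) {
    stop("cox_ph: constant covariate")
  }
  o <- order(time)
  time <- time[o]; event <- event[o]; X <- X[o, , drop = FALSE]
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)                  # centering for stability
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dv <- cox_derivs(beta, time, event, Xc, ties)
    if (max(abs(dv$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(dv$info, dv$score),
                     error = function(e) stop("cox_ph: singular information",
                                              " matrix"))
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))  # damp
    beta <- beta + step
  }
  dv <- cox_derivs(beta, time, event, Xc, ties)
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("cox_ph: monotone likelihood (complete separation); hazard",
            " ratio effectively infinite")
  }
  se <- sqrt(diag(solve(dv$info)))
  z <- beta / se
  coefs <- data.frame(term = colnames(X), coef = beta, HR = exp(beta),
                      se = se,
                      ci_low = exp(beta - 1.959964 * se),
                      ci_high = exp(beta + 1.959964 * se),
                      p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  structure(list(coefficients = coefs, loglik = dv$loglik,
                 n = length(time), n_event = sum(event), ties = ties,
                 converged = converged, separation = separation),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  df <- x$coefficients
  df$HR <- sprintf("%.3f", df$HR)
  df$ci <- sprintf("%.3f-%.3f", x$coefficients$ci_low,
                   x$coefficients$ci_high)
  df$p <- format.pval(x$coefficients$p, digits = 3)
  print(df[, c("term", "HR", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Group-wise survival comparison
#'
#' Per-group n, events and Kaplan-Meier median, plus pairwise Cox hazard
#' ratios and a global Cox model with the grouping entered as a factor
#' (reference = first level).
#'
#' @param time,event survival data.
#' @param group categorical grouping (same length).
#' @param ref optional reference level (default: first sorted level).
#' @return list of class `group_comparison`: `summary` data.frame (group, n,
#'   events, median_os), `pairwise` data.frame (group1, group2, HR, ci_low,
#'   ci_high, p), `global` (`cox_result` over factor dummies, `NULL` if only
#'   one group has data).
#' @export
compare_groups <- function(time, event, group, ref = NULL) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- as.character(group[ok])
  lev <- sort(unique(group))
  if (!is.null(ref)) lev <- c(ref, setdiff(lev, ref))
  if (length(lev) < 2L) stop("compare_groups: need >= 2 groups")
  empty <- lev[!lev %in% group]
  if (length(empty)) stop("compare_groups: empty group '", empty[1L], "'")
  summ <- do.call(rbind, lapply(lev, function(g) {
    km <- km_estimate(time[group == g], event[group == g])
    data.frame(group = g, n = km$n, events = km$n_event,
               median_os = km$median)
  }))
  pw <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    sel <- group %in% c(lev[i], lev[j])
    fit <- tryCatch(
      cox_ph(time[sel], event[sel],
             matrix(as.numeric(group[sel] == lev[j]), ncol = 1,
                    dimnames = list(NULL, lev[j]))),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- fit$coefficients
    pw[[length(pw) + 1L]] <- data.frame(group1 = lev[i], group2 = lev[j],
                                        HR = co$HR, ci_low = co$ci_low,
                                        ci_high = co$ci_high, p = co$p)
  }
  Xg <- sapply(lev[-1L], function(g) as.numeric(group == g))
  Xg <- matrix(Xg, ncol = length(lev) - 1L,
               dimnames = list(NULL, lev[-1L]))
  glob <- tryCatch(cox_ph(time, event, Xg), error = function(e) NULL)
  structure(list(summary = summ,
                 pairwise = if (length(pw)) do.call(rbind, pw) else NULL,
                 global = glob),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise Cox:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Age-dichotomized survival analysis
#'
#' Splits at `cutoff` years (boundary age assigned to the older group,
#' i.e. `< cutoff` versus `>= cutoff`), compares survival, and optionally
#' fits a multivariate Cox model with age group, WHO grade (II vs III/IV)
#' and Karnofsky performance (>= 90 vs < 90).
#'
#' @param time,event survival data.
#' @param age ages in years.
#' @param cutoff split point in years (default 45).
#' @param grade optional WHO grades ("II"/"III"/"IV") for adjustment.
#' @param kps optional Karnofsky scores for adjustment.
#' @return list: `comparison` ([compare_groups()] output for young vs old),
#'   `multivariate` (`cox_result` or `NULL`).
#' @export
age_stratified_analysis <- function(time, event, age, cutoff = 45,
                                    grade = NULL, kps = NULL) {
  ok <- !is.na(age) & !is.na(time) & !is.na(event)
  grp <- ifelse(age >= cutoff, sprintf("age_ge_%g", cutoff),
                sprintf("age_lt_%g", cutoff))
  if (length(unique(grp[ok])) < 2L) {
    stop("age_stratified_analysis: all ages on one side of the cutoff")
  }
  cmp <- compare_groups(time[ok], event[ok],
                        grp[ok], ref = sprintf("age_lt_%g", cutoff))
  mv <- NULL
  if (!is.null(grade) || !is.null(kps)) {
    X <- matrix(as.numeric(age[ok] >= cutoff), ncol = 1,
                dimnames = list(NULL, "age_ge_cutoff"))
    if (!is.null(grade)) {
      X <- cbind(X, grade_III_IV = as.numeric(grade[ok] %in% c("III", "IV")))
    }
    if (!is.null(kps)) {
      X <- cbind(X, kps_ge_90 = as.numeric(kps[ok] >= 90))
    }
    keep <- stats::complete.cases(X)
    mv <- cox_ph(time[ok][keep], event[ok][keep], X[keep, , drop = FALSE])
  }
  list(comparison = cmp, multivariate = mv)
}

#' Merged-subtype Cox model
#'
#' Merges subtype classes (e.g. M1 and M2 into "M1/2") and fits a Cox model
#' of merged-class versus the remaining class, optionally adjusted for WHO
#' grade (II versus III/IV).
#'
#' @param time,event survival data.
#' @param subtype subtype labels.
#' @param merge character vector of labels to merge (default c("M1","M2")).
#' @param merged_name label for the merged class.
#' @param other the comparison class (default "M3").
#' @param grade optional WHO grades for adjustment.
#' @return `cox_result`; the merged-class indicator is the first term.
#' @export
merged_subtype_model <- function(time, event, subtype,
                                 merge = c("M1", "M2"),
                                 merged_name = "M1/2", other = "M3",
                                 grade = NULL) {
  sel <- subtype %in% c(merge, other)
  if (!any(subtype[sel] %in% merge)) {
    stop("merged_subtype_model: merged class empty")
  }
  if (!any(subtype[sel] == other)) {
    stop("merged_subtype_model: comparison class '", other, "' empty")
  }
  X <- matrix(as.numeric(subtype[sel] %in% merge), ncol = 1,
              dimnames = list(NULL, merged_name))
  if (!is.null(grade)) {
    X <- cbind(X, grade_III_IV = as.numeric(grade[sel] %in% c("III", "IV")))
  }
  cox_ph(time[sel], event[sel], X)
}
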