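# Contiguous suprathreshold runs of a t timecourse. NAs (skipped
# timepoints) count as subthreshold. Returns one row per cluster with the
# mass = sum of t inside the run.
find_clusters <- function(tvec, threshold, time_ms) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- !is.na(tvec) & sgn * tvec > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1L]] <- data.frame(
        start_idx = starts[i], end_idx = ends[i],
        start_ms = time_ms[starts[i]], end_ms = time_ms[ends[i]],
        mass = sum(tvec[idx]), sign = sgn)
    }
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_ms = numeric(), end_ms = numeric(),
                      mass = numeric(), sign = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start_idx), , drop = FALSE]
}

max_cluster_mass <- function(tvec, threshold) {
  cl <- find_clusters(tvec, threshold, seq_along(tvec))
  c(pos = if (any(cl$sign > 0)) max(cl$mass[cl$sign > 0]) else 0,
    neg = if (any(cl$sign < 0)) max(-cl$mass[cl$sign < 0]) else 0)
}

# One-sample t statistics per column; constant columns give NA with a
# warning (skipped timepoints).
colwise_t <- function(Y) {
  n <- nrow(Y)
  m <- colMeans(Y)
  s <- sqrt((colSums(Y^2) - n * m^2) / (n - 1))
  bad <- s <= 0
  if (any(bad)) {
    warning(sum(bad), " constant timepoint(s) skipped (t undefined)")
    s[bad] <- NA_real_
  }
  m / (s / sqrt(n))
}

cluster_result <- function(clusters, t_obs, time_ms, threshold_t, n_perm,
                           seed, sidedness) {
  structure(list(clusters = clusters, t_obs = t_obs, time_ms = time_ms,
                 threshold_t = threshold_t, n_perm = n_perm, seed = seed,
                 sidedness = sidedness),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> threshold_t=%.2f n_perm=%d\n",
              x$threshold_t, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, digits = 4) else cat("  no clusters\n")
  invisible(x)
}

#' One-sample cluster-based permutation test on timecourses
#'
#' Tests a subjects-by-timepoints matrix against zero while controlling for
#' multiple comparisons over time. Per timepoint a one-sample t statistic is
#' computed; contiguous runs with `|t| > threshold_t` form candidate
#' clusters (positive and negative separately) whose statistic is the mass
#' (sum of t). The null distribution of the maximum cluster mass per sign is
#' built by randomly sign-flipping whole subject timecourses `n_perm` times;
#' each observed cluster's p-value is `(1 + #(null >= observed)) / (1 +
#' n_perm)` against the same-sign null. Testing each sign at `alpha / 2`
#' gives two-sided control (the reported p-values are per-sign; compare to
#' 0.025 for a two-sided 5% test).
#'
#' @param Y numeric matrix, subjects x timepoints (>= 8 subjects).
#' @param time_ms timepoint positions in ms (defaults to indices).
#' @param threshold_t cluster-forming threshold (default 3.1).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param seed RNG seed.
#' @return object of class `cluster_result` with `clusters` (start/end,
#'   mass, sign, p), the observed t timecourse and settings.
#' @export
cbpt_one_sample <- function(Y, time_ms = NULL, threshold_t = 3.1,
                            n_perm = 1000L, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 8L) stop("need at least 8 subjects", call. = FALSE)
  if (anyNA(Y)) stop("missing timepoints are not supported", call. = FALSE)
  time_ms <- time_ms %||% seq_len(ncol(Y))
  t_obs <- colwise_t(Y)
  clusters <- find_clusters(t_obs, threshold_t, time_ms)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- S %*% Y / n
    ss <- colSums(Y^2) # invariant under sign flips
    V <- sweep(-M^2, 2L, ss / n, `+`) * n / (n - 1)
    Tp <- M / sqrt(V / n)
    t(vapply(seq_len(n_perm), function(i) max_cluster_mass(Tp[i, ], threshold_t),
             numeric(2L)))
  })
  clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
    nulls <- if (clusters$sign[i] > 0) null_max[, "pos"] else null_max[, "neg"]
    (1 + sum(nulls >= abs(clusters$mass[i]))) / (1 + n_perm)
  }, numeric(1L))
  cluster_result(clusters, t_obs, time_ms, threshold_t, n_perm, seed, "two")
}

# Per-timepoint OLS of Y (subjects x time) on scores (subjects x k) with
# intercept; returns slope betas and t statistics as k x T matrices.
ols_t_timecourse <- function(Y, Z0) {
  Z <- cbind(1, as.matrix(Z0))
  n <- nrow(Z); p <- ncol(Z)
  XtXi <- solve(crossprod(Z))
  B <- XtXi %*% crossprod(Z, Y)
  RSS <- colSums((Y - Z %*% B)^2)
  sigma2 <- RSS / (n - p)
  se <- sqrt(outer(diag(XtXi), sigma2))
  list(beta = B[-1L, , drop = FALSE], t = (B / se)[-1L, , drop = FALSE])
}

#' Per-timepoint individual-difference GLMs of decodability
#'
#' Regresses each timepoint's decodability across subjects on the supplied
#' factor scores (ordinary least squares with intercept), returning the
#' slope coefficient and t-statistic timecourses for every factor.
#'
#' @param Y numeric matrix, subjects x timepoints.
#' @param scores numeric matrix/data.frame, subjects x factors (e.g. three
#'   questionnaire factor scores).
#' @param time_ms timepoint positions in ms.
#' @return object of class `id_timecourse`: list with `beta` and `t`
#'   (factors x timepoints matrices), `factors`, `time_ms`.
#' @export
id_glm_timecourse <- function(Y, scores, time_ms = NULL) {
  Y <- as.matrix(Y)
  Z0 <- as.matrix(scores)
  if (nrow(Y) != nrow(Z0)) stop("row mismatch", call. = FALSE)
  fit <- ols_t_timecourse(Y, Z0)
  nm <- colnames(Z0) %||% paste0("factor", seq_len(ncol(Z0)))
  rownames(fit$beta) <- rownames(fit$t) <- nm
  structure(list(beta = fit$beta, t = fit$t, factors = nm,
                 time_ms = time_ms %||% seq_len(ncol(Y))),
            class = "id_timecourse")
}

#' Cluster-based permutation test for individual-difference GLMs
#'
#' As [cbpt_one_sample()], but on the per-timepoint t timecourse of one
#' factor from the cross-subject GLM of decodability on factor scores. The
#' null permutes the factor-score rows jointly across subjects (preserving
#' the scores' intercorrelations) and refits every timepoint.
#'
#' @param Y numeric matrix, subjects x timepoints (decodability).
#' @param scores subjects x factors matrix/data.frame.
#' @param factor name or index of the factor under test.
#' @param time_ms timepoint positions in ms.
#' @param threshold_t cluster-forming threshold (default 2.1).
#' @param n_perm number of row permutations.
#' @param seed RNG seed.
#' @return `cluster_result` for the chosen factor's t timecourse.
#' @export
cbpt_glm <- function(Y, scores, factor = 1L, time_ms = NULL,
                     threshold_t = 2.1, n_perm = 1000L, seed = NULL) {
  Y <- as.matrix(Y)
  Z0 <- as.matrix(scores)
  if (any(apply(Z0, 2L, sd) == 0)) {
    stop("zero-variance factor score", call. = FALSE)
  }
  nm <- colnames(Z0) %||% paste0("factor", seq_len(ncol(Z0)))
  fi <- if (is.character(factor)) match(factor, nm) else as.integer(factor)
  if (is.na(fi)) stop("unknown factor", call. = FALSE)
  time_ms <- time_ms %||% seq_len(ncol(Y))
  t_obs <- ols_t_timecourse(Y, Z0)$t[fi, ]
  clusters <- find_clusters(t_obs, threshold_t, time_ms)
  n <- nrow(Y)
  null_max <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      Zp <- Z0[sample.int(n), , drop = FALSE]
      max_cluster_mass(ols_t_timecourse(Y, Zp)$t[fi, ], threshold_t)
    }, numeric(2L)))
  })
  clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
    nulls <- if (clusters$sign[i] > 0) null_max[, "pos"] else null_max[, "neg"]
    (1 + sum(nulls >= abs(clusters$mass[i]))) / (1 + n_perm)
  }, numeric(1L))
  cluster_result(clusters, t_obs, time_ms, threshold_t, n_perm, seed, "two")
}

#' Paired comparison of per-subject peak latencies
#'
#' Paired t-test on per-subject peak-latency differences between two
#' decodable variables, with Cohen's d computed on the differences
#' (`mean(diff) / sd(diff)`). Zero-variance differences are flagged
#' degenerate rather than tested.
#'
#' @param peaks_a,peaks_b per-subject peak latencies in ms.
#' @param alternative passed to [t.test()].
#' @return list with `t`, `df`, `p`, `cohens_d`, `ci`, `mean_diff`,
#'   `degenerate`.
#' @export
compare_peak_latencies <- function(peaks_a, peaks_b,
                                   alternative = "two.sided") {
  d <- peaks_a - peaks_b
  if (sd(d) == 0) {
    warning("zero-variance latency differences; test degenerate")
    return(list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1L,
                p = NA_real_, cohens_d = if (all(d == 0)) 0 else NA_real_,
                ci = c(NA_real_, NA_real_), mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- t.test(d, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohens_d = mean(d) / sd(d), ci = unname(tt$conf.int),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Normalize a decodability timecourse for display
#'
#' Divides by the maximum value so the peak maps to 1. Display-only: all
#' statistics in this package are computed on unnormalized timecourses.
#'
#' @param r_t numeric vector.
#' @return `r_t / max(r_t)`.
#' @export
normalize_for_display <- function(r_t) {
  m <- max(r_t, na.rm = TRUE)
  if (m <= 0) warning("non-positive maximum; normalization flips/undefines signs")
  r_t / m
}
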