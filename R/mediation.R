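# Closed-form OLS path decomposition for the single-mediator model.
# With intercepts fitted throughout, the identity c = c' + a*b is exact.
mediation_point <- function(X, M, Y) {
  xc <- X - mean(X); mc <- M - mean(M); yc <- Y - mean(Y)
  sxx <- sum(xc^2); smm <- sum(mc^2); sxm <- sum(xc * mc)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  if (sxx == 0 || smm == 0) stop("zero-variance X or M", call. = FALSE)
  a <- sxm / sxx
  c_tot <- sxy / sxx
  det <- sxx * smm - sxm^2
  if (det <= 0) stop("X and M are collinear", call. = FALSE)
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c(a = a, b = b, c = c_tot, c_prime = c_prime, ab = a * b)
}

#' Mediation path decomposition (point estimates)
#'
#' Standard three-regression single-mediator decomposition with X the OC
#' score, M the per-subject dES sensitivity (stopping-model beta) and Y mean
#' confidence: `a` from `M ~ X`; `b` and the direct effect `c'` from
#' `Y ~ X + M`; the total effect `c` from `Y ~ X`; and the indirect effect
#' `ab = a * b`. With intercepts fitted throughout, `c = c' + ab` holds
#' exactly. Variables are standardized by default (flagged in the result);
#' the decomposition identity holds either way.
#'
#' @param X,M,Y numeric vectors (independent, mediator, outcome) of equal
#'   length with at least 10 complete triples.
#' @param standardize z-score X, M, Y before fitting.
#' @return object of class `mediation_result`: `paths` data.frame (path,
#'   estimate, se, z, p) for a, b, c, c', ab (ab's se/z/p via Sobel), plus
#'   `n` and `standardized`.
#' @export
mediation_paths <- function(X, M, Y, standardize = TRUE) {
  ok <- complete.cases(X, M, Y)
  X <- X[ok]; M <- M[ok]; Y <- Y[ok]
  if (length(X) < 10L) stop("need >= 10 complete triples", call. = FALSE)
  if (sd(X) == 0 || sd(M) == 0) stop("zero-variance X or M", call. = FALSE)
  if (standardize) {
    X <- drop(scale(X)); M <- drop(scale(M)); Y <- drop(scale(Y))
  }
  est <- mediation_point(X, M, Y)
  m_a <- lm(M ~ X)
  m_y <- lm(Y ~ X + M)
  m_c <- lm(Y ~ X)
  se <- c(a = summary(m_a)$coefficients["X", "Std. Error"],
          b = summary(m_y)$coefficients["M", "Std. Error"],
          c = summary(m_c)$coefficients["X", "Std. Error"],
          c_prime = summary(m_y)$coefficients["X", "Std. Error"])
  se["ab"] <- sqrt(est[["b"]]^2 * se[["a"]]^2 + est[["a"]]^2 * se[["b"]]^2)
  z <- est / se[names(est)]
  out <- list(paths = data.frame(path = names(est), estimate = unname(est),
                                 se = unname(se[names(est)]), z = unname(z),
                                 p = unname(2 * pnorm(-abs(z))),
                                 stringsAsFactors = FALSE),
              n = length(X), standardized = standardize)
  class(out) <- "mediation_result"
  out
}

#' Bootstrap mediation inference
#'
#' Case-resampling bootstrap of all mediation paths (default 10,000
#' resamples): subjects are resampled with replacement, the closed-form
#' decomposition is recomputed per resample, and percentile confidence
#' intervals plus two-sided p-values from the bootstrap distribution's
#' symmetric tail are reported. Identical seeds give identical intervals.
#'
#' @inheritParams mediation_paths
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf_level CI level.
#' @return `mediation_result` whose `paths` table carries `ci_lo`, `ci_hi`
#'   and bootstrap `p`, plus `n_boot` and `seed`.
#' @export
mediation_bootstrap <- function(X, M, Y, n_boot = 10000L, seed = NULL,
                                standardize = TRUE, conf_level = 0.95) {
  ok <- complete.cases(X, M, Y)
  X <- X[ok]; M <- M[ok]; Y <- Y[ok]
  res <- mediation_paths(X, M, Y, standardize = standardize)
  if (standardize) {
    X <- drop(scale(X)); M <- drop(scale(M)); Y <- drop(scale(Y))
  }
  n <- length(X)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 5L,
                  dimnames = list(NULL, c("a", "b", "c", "c_prime", "ab")))
    for (bi in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(mediation_point(X[i], M[i], Y[i]),
                      error = function(e) rep(NA_real_, 5L))
      out[bi, ] <- est
    }
    out
  })
  alpha <- 1 - conf_level
  p <- res$paths
  p$ci_lo <- NA_real_; p$ci_hi <- NA_real_; p$p_boot <- NA_real_
  for (j in seq_len(nrow(p))) {
    bj <- boot[, p$path[j]]
    bj <- bj[is.finite(bj)]
    p$ci_lo[j] <- quantile(bj, alpha / 2, names = FALSE)
    p$ci_hi[j] <- quantile(bj, 1 - alpha / 2, names = FALSE)
    lo <- (1 + sum(bj <= 0)) / (1 + length(bj))
    hi <- (1 + sum(bj >= 0)) / (1 + length(bj))
    p$p_boot[j] <- min(1, 2 * min(lo, hi))
  }
  res$paths <- p
  res$n_boot <- n_boot
  res$seed <- seed
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n=%d%s%s\n", x$n,
              if (isTRUE(x$standardized)) " (standardized)" else "",
              if (!is.null(x$n_boot)) sprintf(" n_boot=%d", x$n_boot) else ""))
  print(x$paths, digits = 3)
  invisible(x)
}
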