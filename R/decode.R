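#' Z-score epochs by block and channel
#'
#' Univariate normalization: for every (block, channel) pair, the pooled
#' distribution of samples over that block's trials and all timepoints is
#' scaled to mean 0 and SD 1. Idempotent to numerical precision. Channels
#' that are constant within a block raise an error by default, or are
#' zero-filled with `constant = "zero"`.
#'
#' @param epochs an [epoch_set()].
#' @param constant `"error"` or `"zero"` handling of constant channels.
#' @return the standardized `epoch_set`.
#' @export
standardize_epochs <- function(epochs, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  stopifnot(inherits(epochs, "epoch_set"))
  X <- epochs$data
  for (b in levels(epochs$blocks)) {
    idx <- which(epochs$blocks == b)
    if (length(idx) < 1L) next
    sub <- X[idx, , , drop = FALSE]
    if (length(idx) * dim(X)[3L] < 2L) {
      stop("block ", b, " has fewer than two samples", call. = FALSE)
    }
    flat <- matrix(aperm(sub, c(1L, 3L, 2L)), ncol = dim(X)[2L])
    m <- colMeans(flat)
    s <- sqrt(colSums(sweep(flat, 2L, m)^2) / (nrow(flat) - 1L))
    if (any(s == 0)) {
      if (constant == "error") {
        stop("constant channel within block ", b, call. = FALSE)
      }
      s[s == 0] <- Inf # zero-fill
    }
    flat <- sweep(sweep(flat, 2L, m), 2L, s, `/`)
    X[idx, , ] <- aperm(array(flat, dim = dim(sub)[c(1L, 3L, 2L)]),
                        c(1L, 3L, 2L))
  }
  epochs$data <- X
  epochs
}

resolve_target <- function(epochs, target) {
  if (is.character(target) && length(target) == 1L) {
    y <- epochs$targets[[target]]
    if (is.null(y)) stop("unknown target: ", target, call. = FALSE)
    list(name = target, y = y)
  } else {
    list(name = "custom", y = as.numeric(target))
  }
}

# n_iter x n matrix of fold labels 0..k-1, stratified by game when game ids
# are available (all draws of a game land in one fold, avoiding leakage
# between folds through within-game autocorrelation).
make_folds <- function(n, k, n_iter, game_id = NULL) {
  out <- matrix(0L, n_iter, n)
  if (!is.null(game_id)) {
    games <- unique(game_id)
    for (i in seq_len(n_iter)) {
      gl <- sample(rep_len(0:(k - 1L), length(games)))
      out[i, ] <- gl[match(game_id, games)]
    }
  } else {
    for (i in seq_len(n_iter)) {
      out[i, ] <- sample(rep_len(0:(k - 1L), n))
    }
  }
  out
}

#' Iterative random-subset lasso decoding of a target timecourse
#'
#' For each timepoint, an L1-penalized linear decoder is estimated `n_iter`
#' times on random subsets of `subset_size` channels under k-fold
#' cross-validation; held-out predictions are pooled over folds and
#' correlated with the true per-trial target, and the resulting r is
#' averaged over iterations. The per-timepoint average is the decodability
#' timecourse; its argmax (first occurrence on ties) is the peak latency.
#' Folds stratify by game when the epoch set carries game ids. Identical
#' (epochs, target, seed, settings) give identical timecourses.
#'
#' Reference analyses use 2,000 iterations of 50-sensor subsets at
#' `lambda = 0.01`; the default iteration budget here is reduced for
#' interactive use and can be raised for reproduction runs.
#'
#' @param epochs an [epoch_set()] (standardize first; see
#'   [standardize_epochs()]).
#' @param target name of a column of `epochs$targets`, or a numeric
#'   per-trial vector.
#' @param lambda lasso penalty (default 0.01).
#' @param n_iter number of random-subset iterations.
#' @param subset_size channels per subset.
#' @param k cross-validation folds.
#' @param seed RNG seed.
#' @param fold_by_game stratify folds by game when game ids are present.
#' @param tol,maxit coordinate-descent control.
#' @return object of class `decodability_timecourse`: `variable`, `r_t`,
#'   `time_ms`, `peak_time_ms` and the settings.
#' @export
iterative_subset_decode <- function(epochs, target, lambda = 0.01,
                                    n_iter = 200L, subset_size = 50L,
                                    k = 5L, seed = NULL,
                                    fold_by_game = TRUE,
                                    tol = 1e-4, maxit = 10000L) {
  stopifnot(inherits(epochs, "epoch_set"))
  tg <- resolve_target(epochs, target)
  y <- tg$y
  n <- dim(epochs$data)[1L]
  p <- dim(epochs$data)[2L]
  if (n < 2L * k) stop("need at least 2k trials", call. = FALSE)
  if (!all(is.finite(y)) || sd(y) == 0) {
    stop("target must be finite with nonzero variance", call. = FALSE)
  }
  if (subset_size > p) stop("subset_size exceeds channel count", call. = FALSE)
  gid <- if (fold_by_game) epochs$game_id else NULL
  r_t <- with_seed(seed, {
    subsets <- t(vapply(seq_len(n_iter),
                        function(i) sort(sample.int(p, subset_size)) - 1L,
                        integer(subset_size)))
    folds <- make_folds(n, k, n_iter, gid)
    decode_course_cpp(epochs$data, dim(epochs$data), y, subsets, folds,
                      lambda, tol, maxit)
  })
  nzv <- attr(r_t, "n_zero_var") %||% 0L
  if (nzv > 0L) {
    warning(nzv, " iteration(s) had zero-variance pooled predictions (r = 0)")
  }
  structure(list(variable = tg$name, r_t = as.numeric(r_t),
                 time_ms = epochs$time_ms,
                 peak_time_ms = epochs$time_ms[which.max(r_t)],
                 n_iter = n_iter, subset_size = subset_size, lambda = lambda,
                 k_folds = k, seed = seed),
            class = "decodability_timecourse")
}

#' @export
print.decodability_timecourse <- function(x, ...) {
  cat(sprintf("<decodability %s> peak r=%.3f @ %g ms (lambda=%g, %d x %d subsets)\n",
              x$variable, max(x$r_t), x$peak_time_ms, x$lambda, x$n_iter,
              x$subset_size))
  invisible(x)
}

#' Tune the lasso penalty on an orthogonal variable
#'
#' Chooses the penalty from `grid` that maximizes the mean cross-validated
#' decodability (over all timepoints) of an orthogonal target -- a variable
#' uncorrelated with the analysis targets, so that tuning does not peek at
#' the effects of interest. The orthogonality is checked against every
#' analysis target (configurable threshold). The tuning run uses all
#' channels in a single iteration per the non-iterative tuning procedure;
#' exact score ties are broken toward the largest penalty. The chosen
#' lambda is then frozen for all analysis targets.
#'
#' @param epochs an [epoch_set()].
#' @param orthogonal_target name or per-trial numeric vector.
#' @param grid candidate lambda values.
#' @param k folds.
#' @param seed RNG seed (folds are shared across grid points).
#' @param max_abs_corr orthogonality bound versus analysis targets.
#' @param n_iter iterations per grid point (default 1, all channels).
#' @return list with `lambda` (selected), and `scores` (data.frame lambda,
#'   score).
#' @export
tune_lambda <- function(epochs, orthogonal_target, grid, k = 5L, seed = NULL,
                        max_abs_corr = 0.1, n_iter = 1L) {
  tg <- resolve_target(epochs, orthogonal_target)
  for (v in names(epochs$targets)) {
    if (is.character(orthogonal_target) && identical(v, orthogonal_target)) next
    cc <- abs(cor(tg$y, epochs$targets[[v]]))
    if (is.finite(cc) && cc > max_abs_corr) {
      stop(sprintf("tuning variable correlates with analysis target '%s' (|r| = %.3f)",
                   v, cc), call. = FALSE)
    }
  }
  p <- dim(epochs$data)[2L]
  grid <- sort(as.numeric(grid))
  scores <- vapply(grid, function(lam) {
    d <- iterative_subset_decode(epochs, orthogonal_target, lambda = lam,
                                 n_iter = n_iter, subset_size = p, k = k,
                                 seed = seed)
    mean(d$r_t)
  }, numeric(1L))
  best <- max(scores)
  sel <- max(which(scores >= best - 1e-12)) # ties toward the largest lambda
  list(lambda = grid[sel],
       scores = data.frame(lambda = grid, score = scores))
}

#' Searchlight decoding map over sensors
#'
#' Decodes the target from each sensor plus its direct neighbors (one lasso
#' per sensor at each timepoint in the window, k-fold cross-validated) and
#' maps the mean decodability within the time window of interest onto the
#' sensor array. A smaller penalty than the whole-array analysis is
#' appropriate given the much smaller channel sets (default 0.001).
#'
#' @param epochs an [epoch_set()].
#' @param target name or per-trial vector.
#' @param layout the `sensor_layout` matching the epoch channels.
#' @param lambda lasso penalty.
#' @param window_ms length-2 window (ms) over which decodability is
#'   averaged; must lie inside the epoch.
#' @param k folds.
#' @param seed RNG seed (folds shared across sensors).
#' @return object of class `searchlight_map`: `values` (per sensor),
#'   `window_ms`, `lambda`, `layout`.
#' @export
searchlight_decode <- function(epochs, target, layout, lambda = 0.001,
                               window_ms, k = 5L, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(layout, "sensor_layout"))
  if (layout$n_sensors != dim(epochs$data)[2L]) {
    stop("layout channel count does not match epochs", call. = FALSE)
  }
  tm <- epochs$time_ms
  if (window_ms[1L] < min(tm) || window_ms[2L] > max(tm)) {
    stop("window outside the epoch", call. = FALSE)
  }
  widx <- which(tm >= window_ms[1L] & tm <= window_ms[2L])
  tg <- resolve_target(epochs, target)
  n <- dim(epochs$data)[1L]
  folds <- with_seed(seed, make_folds(n, k, 1L, epochs$game_id))
  values <- vapply(seq_len(layout$n_sensors), function(s) {
    chans <- sort(unique(c(s, layout$neighbors[[s]])))
    sub <- epochs$data[, chans, widx, drop = FALSE]
    r <- decode_course_cpp(sub, dim(sub), tg$y,
                           matrix(seq_along(chans) - 1L, nrow = 1L),
                           folds, lambda)
    mean(r)
  }, numeric(1L))
  structure(list(values = values, window_ms = window_ms, lambda = lambda,
                 variable = tg$name, layout = layout),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("<searchlight_map %s> %d sensors, window %g..%g ms, max @ sensor %d\n",
              x$variable, length(x$values), x$window_ms[1L], x$window_ms[2L],
              which.max(x$values)))
  invisible(x)
}

#' Per-subject peak latencies and their group mean
#'
#' The per-subject peak is the argmax of the decodability timecourse (first
#' occurrence on tie plateaus); the group statistic is the mean of the
#' individual peaks.
#'
#' @param timecourses a subjects x timepoints matrix, or a list of
#'   `decodability_timecourse` objects.
#' @param time_ms time axis (required for a bare matrix).
#' @return list with `peaks_ms` (per subject) and `group_mean_ms`.
#' @export
peak_latency <- function(timecourses, time_ms = NULL) {
  if (is.list(timecourses) && !is.data.frame(timecourses) &&
      !is.matrix(timecourses)) {
    peaks <- vapply(timecourses, function(d) d$peak_time_ms, numeric(1L))
  } else {
    M <- as.matrix(timecourses)
    time_ms <- time_ms %||% seq_len(ncol(M))
    peaks <- time_ms[apply(M, 1L, which.max)]
  }
  list(peaks_ms = peaks, group_mean_ms = mean(peaks))
}
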