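#' Generate a quasi-uniform sensor layout on a disc
#'
#' Places `n_sensors` points on a unit disc using a sunflower (golden-angle)
#' arrangement, optionally jittered, and derives a direct-neighbor adjacency
#' by distance threshold: two sensors are neighbors when their distance is
#' at most `factor` times the median nearest-neighbor distance. The
#' threshold is escalated until every sensor reaches `min_degree` neighbors,
#' so the adjacency is symmetric and non-degenerate. The default 273
#' sensors matches a 275-channel axial gradiometer system with two channels
#' unusable.
#'
#' @param n_sensors number of sensors (default 273).
#' @param seed RNG seed for the jitter.
#' @param jitter_sd positional jitter SD (0 = deterministic layout).
#' @param factor neighbor-distance multiplier.
#' @param min_degree minimum neighbors per sensor.
#' @return object of class `sensor_layout`: `n_sensors`, `positions`
#'   (n x 2), `neighbors` (list of integer vectors).
#' @export
generate_sensor_layout <- function(n_sensors = 273L, seed = NULL,
                                   jitter_sd = 0, factor = 1.4,
                                   min_degree = 2L) {
  i <- seq_len(n_sensors)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_sensors)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  if (jitter_sd > 0) {
    pos <- pos + with_seed(seed, matrix(rnorm(2L * n_sensors, 0, jitter_sd),
                                        ncol = 2L))
  }
  sensor_layout_from_positions(pos, factor = factor,
                               min_degree = min(min_degree, n_sensors - 1L))
}

#' Build a sensor layout from explicit positions
#'
#' @param positions numeric matrix (n x 2) of sensor coordinates.
#' @param factor neighbor-distance multiplier on the median
#'   nearest-neighbor distance.
#' @param min_degree minimum neighbors per sensor; the distance threshold is
#'   escalated until reached.
#' @return a `sensor_layout`.
#' @export
sensor_layout_from_positions <- function(positions, factor = 1.4,
                                         min_degree = 1L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  D <- as.matrix(dist(positions))
  diag(D) <- Inf
  thr <- factor * median(apply(D, 1L, min))
  repeat {
    A <- D <= thr
    if (all(rowSums(A) >= min_degree) || !is.finite(thr)) break
    thr <- thr * 1.1
  }
  neighbors <- lapply(seq_len(n), function(i) as.integer(which(unname(A[i, ]))))
  structure(list(n_sensors = n, positions = positions, neighbors = neighbors),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sensors, mean degree %.1f\n", x$n_sensors,
              mean(lengths(x$neighbors))))
  invisible(x)
}

#' Spatiotemporal embedding specification for synthetic epochs
#'
#' Describes how per-trial decision variables are written into multichannel
#' epochs. Each variable `v` contributes
#' `a_v * w_v[ch] * g_v[t] * z_v[trial]`, where `w_v` is a unit-norm spatial
#' pattern over channels, `g_v` a Gaussian temporal kernel (peak and width
#' in ms, supported inside the epoch window) and `z_v` the within-subject
#' z-scored trial values; i.i.d. Gaussian sensor noise of SD `noise_sd` is
#' added on top. The amplitude of the variable named by `attenuated`
#' (default `"delta_es"`) declines linearly with the subject's OC score:
#' `a = amplitude * max(0, 1 + oc_attenuation * oc)`.
#'
#' @param variables named list; each element a list with `weights`
#'   (per-channel spatial pattern, normalized internally), `peak_ms`,
#'   `width_ms` (Gaussian SD) and optional `amplitude` (default 1).
#' @param noise_sd Gaussian noise SD per sample.
#' @param oc_attenuation slope of the attenuated variable's amplitude on OC.
#' @param attenuated name of the attenuated variable.
#' @return object of class `embedding_spec`.
#' @export
embedding_spec <- function(variables, noise_sd = 1, oc_attenuation = 0,
                           attenuated = "delta_es") {
  stopifnot(is.list(variables), length(names(variables)) == length(variables))
  variables <- lapply(variables, function(v) {
    nrm <- sqrt(sum(v$weights^2))
    if (nrm == 0) stop("zero spatial pattern", call. = FALSE)
    v$weights <- v$weights / nrm
    v$amplitude <- v$amplitude %||% 1
    v
  })
  structure(list(variables = variables, noise_sd = noise_sd,
                 oc_attenuation = oc_attenuation, attenuated = attenuated),
            class = "embedding_spec")
}

#' Spatial patterns for embeddings
#'
#' `spatial_pattern_random` draws a dense random unit-norm pattern over all
#' channels; `spatial_pattern_local` concentrates the pattern on one sensor
#' and its direct neighbors (used to validate searchlight localization).
#'
#' @param layout a `sensor_layout`.
#' @param seed RNG seed.
#' @param center sensor index for the local pattern.
#' @return numeric per-channel weight vector.
#' @export
spatial_pattern_random <- function(layout, seed = NULL) {
  w <- with_seed(seed, rnorm(layout$n_sensors))
  w / sqrt(sum(w^2))
}

#' @rdname spatial_pattern_random
#' @export
spatial_pattern_local <- function(layout, center) {
  w <- numeric(layout$n_sensors)
  w[center] <- 1
  w[layout$neighbors[[center]]] <- 0.6
  w / sqrt(sum(w^2))
}

#' Construct an epoch set
#'
#' Container for trial x channel x time data with its time axis, per-trial
#' block labels, per-trial target variables and optional game ids (used for
#' game-stratified cross-validation folds).
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param time_ms numeric vector of sample times (ms).
#' @param blocks per-trial block labels.
#' @param targets data.frame of per-trial target variables.
#' @param subject_id identifier.
#' @param game_id optional per-trial game identifiers.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, blocks, targets, subject_id = "s1",
                      game_id = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3L] != length(time_ms)) stop("time axis mismatch", call. = FALSE)
  if (dim(data)[1L] != length(blocks)) stop("block labels mismatch", call. = FALSE)
  if (dim(data)[1L] != nrow(targets)) stop("targets mismatch", call. = FALSE)
  if (anyNA(data)) stop("missing samples are not supported", call. = FALSE)
  structure(list(data = data, time_ms = time_ms, blocks = as.factor(blocks),
                 targets = as.data.frame(targets), subject_id = subject_id,
                 game_id = game_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set %s> %d trials x %d channels x %d timepoints (%g..%g ms)\n",
              as.character(x$subject_id), d[1L], d[2L], d[3L],
              min(x$time_ms), max(x$time_ms)))
  cat(sprintf("  targets: %s; blocks: %d\n",
              paste(names(x$targets), collapse = ", "), nlevels(x$blocks)))
  invisible(x)
}

#' Default epoch time axis
#'
#' 135 samples from -100 to 1240 ms at 100 Hz, matching epochs cut from
#' -100 to 1250 ms relative to stimulus onset and downsampled to 100 Hz.
#'
#' @param from,to,hz window bounds (ms) and sampling rate.
#' @return numeric vector of sample times.
#' @export
epoch_time_axis <- function(from = -100, to = 1250, hz = 100) {
  seq(from, to - 1000 / hz + 1e-9, by = 1000 / hz)
}

#' Generate synthetic multichannel epochs with embedded decision variables
#'
#' Builds one subject's epoch set: for each trial (one per design row) the
#' selected target variables are z-scored within subject and written into
#' the data as rank-one spatiotemporal patterns per [embedding_spec()],
#' on top of i.i.d. Gaussian noise. The amplitude of the spec's attenuated
#' variable scales with the subject's OC score (floored at zero). Trials
#' are partitioned into `n_blocks` contiguous blocks.
#'
#' @param design per-trial data.frame holding the embedded variable columns
#'   (e.g. design rows from [simulate_agent()]).
#' @param layout a `sensor_layout`; channel count must match the spec's
#'   spatial patterns.
#' @param spec an [embedding_spec()].
#' @param oc subject's standardized OC score.
#' @param n_blocks number of contiguous blocks (default 4).
#' @param seed RNG seed.
#' @param time_ms epoch time axis (default [epoch_time_axis()]).
#' @param subject_id identifier.
#' @return an [epoch_set()]; `targets` holds the z-scored embedded values.
#' @export
generate_epochs <- function(design, layout, spec, oc = 0, n_blocks = 4L,
                            seed = NULL, time_ms = epoch_time_axis(),
                            subject_id = "s1") {
  stopifnot(inherits(spec, "embedding_spec"), inherits(layout, "sensor_layout"))
  vars <- names(spec$variables)
  if (!all(vars %in% names(design))) {
    stop("design lacks embedded variable(s): ",
         paste(setdiff(vars, names(design)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(design[, vars])) {
    stop("embedded variables must be complete", call. = FALSE)
  }
  p <- layout$n_sensors
  for (v in vars) {
    if (length(spec$variables[[v]]$weights) != p) {
      stop("spatial pattern length does not match layout channels", call. = FALSE)
    }
  }
  n <- nrow(design)
  Tn <- length(time_ms)
  targets <- as.data.frame(lapply(design[, vars, drop = FALSE], function(x) {
    s <- sd(x)
    if (s == 0) stop("constant embedded variable", call. = FALSE)
    (x - mean(x)) / s
  }))
  with_seed(seed, {
    X <- array(rnorm(n * p * Tn, 0, spec$noise_sd), dim = c(n, p, Tn))
    for (v in vars) {
      vv <- spec$variables[[v]]
      amp <- vv$amplitude
      if (identical(v, spec$attenuated)) {
        amp <- amp * max(0, 1 + spec$oc_attenuation * oc)
      }
      g <- exp(-(time_ms - vv$peak_ms)^2 / (2 * vv$width_ms^2))
      M <- amp * tcrossprod(targets[[v]], vv$weights) # n x p
      for (ti in seq_len(Tn)) {
        if (g[ti] > 1e-8) X[, , ti] <- X[, , ti] + M * g[ti]
      }
    }
    blocks <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
    epoch_set(X, time_ms, blocks, targets, subject_id = subject_id,
              game_id = design$game_id %||% NULL)
  })
}
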