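#' Stopping-agent parameters
#'
#' Parameters of a logistic stopping agent. At every draw the agent declares
#' with probability
#' `plogis(beta0 + beta_nd * N_d + beta_des * dES_d + beta_esprev * ES_{d-1}
#'  [+ beta_hor * horizon])`,
#' where `N_d` is the draw number, `dES_d` the evidence-strength update,
#' `ES_{d-1}` the previous total evidence and `horizon` the coded condition
#' (short = -0.5, long = +0.5; the horizon term only applies to the horizon
#' variant). After a decision the agent reports a confidence rating
#' `conf_intercept + conf_slope * beta_des + noise`, clipped to \[0, 100\]:
#' agents more sensitive to recent evidence are, by construction, more
#' confident, which is the hook the mediation analysis exercises.
#'
#' @param beta0 intercept (negative values delay decisions).
#' @param beta_nd weight on the draw number (urgency).
#' @param beta_des weight on the evidence-strength update (recency).
#' @param beta_esprev weight on the previous cumulative evidence.
#' @param beta_hor weight on the coded horizon condition.
#' @param oc standardized obsessive-compulsive (OC) score attached to the
#'   agent; carried along for individual-difference analyses.
#' @param conf_intercept,conf_slope,conf_noise_sd confidence-model
#'   parameters.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(beta0 = -4, beta_nd = 0.15, beta_des = 0.6,
                         beta_esprev = 0.25, beta_hor = -0.8, oc = 0,
                         conf_intercept = 60, conf_slope = 25,
                         conf_noise_sd = 10) {
  p <- list(beta0 = beta0, beta_nd = beta_nd, beta_des = beta_des,
            beta_esprev = beta_esprev, beta_hor = beta_hor, oc = oc,
            conf_intercept = conf_intercept, conf_slope = conf_slope,
            conf_noise_sd = conf_noise_sd)
  if (!all(vapply(p, is.finite, logical(1L)))) {
    stop("agent parameters must be finite", call. = FALSE)
  }
  structure(p, class = "agent_params")
}

#' Generate undecided task games
#'
#' Generates stimulus sequences for either task variant. Grid games reveal
#' one stimulus per draw over a 25-location grid; horizon games reveal five
#' stimuli per draw, with the maximum number of draws uniform on 4--8
#' (short) or 10--14 (long) and the two horizon conditions split evenly
#' across `n_games` (80 + 80 at the task's standard 160). Each game's
#' majority stimulus is randomized, and each revealed stimulus is the
#' majority type with probability `p_majority`.
#'
#' Optionally the whole sequence set is rejection-sampled until the pairwise
#' correlations among the per-draw regressors `N_d`, `dES` and `ES_{d-1}`
#' (pooled over all draws) fall below `max_abs_corr`, mirroring sequence
#' construction that reduces regressor collinearity.
#'
#' @param variant `"grid"` or `"horizon"`.
#' @param n_games number of games (grid default 15; horizon default 160).
#' @param p_majority per-stimulus probability of the majority type, in
#'   (0.5, 1).
#' @param seed RNG seed; same seed, same sequences.
#' @param max_abs_corr optional bound for regressor decorrelation
#'   (rejection sampling; `NULL` disables).
#' @param max_tries rejection-sampling budget.
#' @return a list of undecided [game_record()] objects.
#' @export
generate_games <- function(variant = c("horizon", "grid"),
                           n_games = if (match.arg(variant) == "grid") 15L else 160L,
                           p_majority = 0.65, seed = NULL,
                           max_abs_corr = NULL, max_tries = 200L) {
  variant <- match.arg(variant)
  if (p_majority <= 0.5 || p_majority >= 1) {
    stop("p_majority must lie in (0.5, 1)", call. = FALSE)
  }
  with_seed(seed, {
    best <- NULL
    best_r <- Inf
    for (try in seq_len(max(1L, max_tries))) {
      games <- replicate(n_games, NULL, simplify = FALSE)
      horizons <- if (variant == "horizon") {
        sample(rep(c("short", "long"), length.out = n_games))
      } else rep("none", n_games)
      for (i in seq_len(n_games)) {
        maj <- sample(c("A", "B"), 1L)
        if (variant == "grid") {
          n_draws <- 25L
          maj_counts <- rbinom(n_draws, 1L, p_majority)
          per_draw <- 1L
        } else {
          n_draws <- if (horizons[i] == "short") sample(4:8, 1L) else sample(10:14, 1L)
          maj_counts <- rbinom(n_draws, 5L, p_majority)
          per_draw <- 5L
        }
        n_A <- if (maj == "A") maj_counts else per_draw - maj_counts
        games[[i]] <- game_record(
          game_id = sprintf("g%03d", i), variant = variant,
          n_A = n_A, n_B = per_draw - n_A, horizon = horizons[i],
          max_draws = if (variant == "grid") 25L else n_draws,
          true_majority = maj)
      }
      if (is.null(max_abs_corr)) return(games)
      feats <- do.call(rbind, lapply(games, evidence_features))
      cc <- cor(feats[, c("n_d", "delta_es", "es_prev")])
      r <- max(abs(cc[upper.tri(cc)]))
      if (r < best_r) {
        best <- games
        best_r <- r
      }
      if (r < max_abs_corr) return(games)
    }
    warning(sprintf(paste0("decorrelation bound %.2f not reached within ",
                           "max_tries; returning the best set (max |r| = %.2f)"),
                    max_abs_corr, best_r))
    best
  })
}

# Long feature table for a set of games, with horizon coding and game-level
# metadata; shared across subjects when simulating cohorts.
cohort_features <- function(games) {
  feats <- do.call(rbind, lapply(games, evidence_features))
  meta <- data.frame(
    game_id = vapply(games, function(g) as.character(g$game_id), character(1L)),
    horizon = vapply(games, function(g) horizon_code(g$horizon), numeric(1L)),
    true_majority = vapply(games, function(g) g$true_majority, character(1L)),
    stringsAsFactors = FALSE)
  feats$horizon <- meta$horizon[match(feats$game_id, meta$game_id)]
  feats$true_majority <- meta$true_majority[match(feats$game_id, meta$game_id)]
  feats
}

# Vectorized single-subject pass over a precomputed feature table.
# Returns the subject's design rows (through the decision draw) plus a
# one-row summary. `feats` must be ordered by game and draw.
simulate_subject_rows <- function(feats, params, lapse = 0) {
  eta <- params$beta0 + params$beta_nd * feats$n_d +
    params$beta_des * feats$delta_es + params$beta_esprev * feats$es_prev +
    params$beta_hor * feats$horizon
  p <- plogis(eta)
  hit <- runif(nrow(feats)) < p
  gid <- feats$game_id
  # first hit per game, NA when the horizon runs out undeclared
  hit_idx <- which(hit)
  first_hit <- hit_idx[!duplicated(gid[hit_idx])]
  dec_draw <- rep(NA_integer_, length(unique(gid)))
  names(dec_draw) <- unique(gid)
  dec_draw[gid[first_hit]] <- feats$n_d[first_hit]

  dd_row <- dec_draw[gid]
  keep <- is.na(dd_row) | feats$n_d <= dd_row
  rows <- feats[keep, , drop = FALSE]
  dd_kept <- dd_row[keep]
  rows$decide <- as.integer(!is.na(dd_kept) & rows$n_d == dd_kept)
  rows$non_decision <- is.na(dd_kept)

  # choice = cumulative majority at the decision draw (ties at random),
  # with an optional lapse toward the minority
  dec_rows <- rows[rows$decide == 1L, , drop = FALSE]
  sgn <- sign(dec_rows$es_diff)
  sgn[sgn == 0] <- sample(c(-1, 1), sum(sgn == 0), replace = TRUE)
  if (lapse > 0) {
    flip <- runif(nrow(dec_rows)) < lapse
    sgn[flip] <- -sgn[flip]
  }
  choice <- ifelse(sgn > 0, "A", "B")
  correct <- choice == dec_rows$true_majority
  confidence <- pmin(100, pmax(0, params$conf_intercept +
    params$conf_slope * params$beta_des +
    rnorm(nrow(dec_rows), 0, params$conf_noise_sd)))

  # chosen-relative lags for the recency model
  ch_sgn <- rep(NA_real_, nrow(rows))
  ch_sgn[rows$game_id %in% dec_rows$game_id] <-
    (sgn[match(rows$game_id[rows$game_id %in% dec_rows$game_id],
               dec_rows$game_id)])
  rows$es_chosen_lag0 <- ch_sgn * rows$es_diff
  new_game <- !duplicated(rows$game_id)
  rows$es_chosen_lag1 <- c(NA, rows$es_chosen_lag0[-nrow(rows)])
  rows$es_chosen_lag1[new_game] <- NA
  rows$es_chosen_lag2 <- c(NA, rows$es_chosen_lag1[-nrow(rows)])
  rows$es_chosen_lag2[new_game] <- NA

  n_games <- length(dec_draw)
  summary <- data.frame(
    n_games = n_games,
    n_decided = nrow(dec_rows),
    mean_draws = mean(dd_kept[rows$decide == 1L]),
    accuracy = if (nrow(dec_rows)) mean(correct) else NA_real_,
    mean_confidence = if (nrow(dec_rows)) mean(confidence) else NA_real_,
    n_unique_draws = length(unique(dd_kept[rows$decide == 1L])),
    n_unique_confidence = length(unique(round(confidence))),
    stringsAsFactors = FALSE)
  list(rows = rows, summary = summary,
       decisions = data.frame(game_id = dec_rows$game_id,
                              decision_draw = dec_rows$n_d,
                              choice = choice, correct = correct,
                              confidence = confidence,
                              stringsAsFactors = FALSE))
}

#' Simulate a stopping agent over a set of games
#'
#' Plays each undecided game with the logistic stopping rule described in
#' [agent_params()]: at every draw the agent declares with the model's
#' probability; if the horizon is exhausted without a declaration the game
#' is a non-decision. On declaring, the agent chooses the current cumulative
#' majority (ties at random, with an optional lapse rate) and reports a
#' confidence rating.
#'
#' @param games list of undecided [game_record()] objects.
#' @param params an [agent_params()].
#' @param seed RNG seed.
#' @param lapse probability of choosing against the current majority.
#' @param subject_id identifier attached to the output rows.
#' @return a list with `games` (decided game records), `design` (per-draw
#'   design rows through the decision draw, as [build_design_table()]),
#'   and `summary` (one-row data.frame: mean draws, accuracy, confidence).
#' @export
simulate_agent <- function(games, params, seed = NULL, lapse = 0,
                           subject_id = "s1") {
  stopifnot(inherits(params, "agent_params"))
  if (any(vapply(games, function(g) !is.na(g$decision_draw), logical(1L)))) {
    stop("games must be undecided", call. = FALSE)
  }
  with_seed(seed, {
    feats <- cohort_features(games)
    res <- simulate_subject_rows(feats, params, lapse = lapse)
    decided <- lapply(games, function(g) {
      i <- match(as.character(g$game_id), res$decisions$game_id)
      if (!is.na(i)) {
        g$decision_draw <- as.integer(res$decisions$decision_draw[i])
        g$choice <- res$decisions$choice[i]
        g$confidence <- res$decisions$confidence[i]
      }
      g
    })
    design <- res$rows
    design$subject_id <- subject_id
    design <- design[, c("subject_id", "game_id", "n_d", "es_prev",
                         "delta_es", "horizon", "es_chosen_lag0",
                         "es_chosen_lag1", "es_chosen_lag2", "decide",
                         "non_decision")]
    summary <- cbind(subject_id = subject_id, res$summary)
    list(games = decided, design = design, summary = summary)
  })
}

#' Generate a subject population with an OC-linked recency weight
#'
#' Draws `n_subjects` agents whose stopping-model coefficients vary around
#' population means. The standardized OC score is `oc ~ N(0, 1)` and the
#' recency weight is tied to it,
#' `beta_des = mean + oc_effect_on_des * oc + N(0, sd)`, while the other
#' coefficients are drawn independently. Confidence parameters share the
#' slope `conf_effect` on `beta_des`, so the mediation structure
#' OC -> beta_des -> confidence holds by construction (with zero direct
#' OC -> confidence path unless `oc_direct_on_conf` is set).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param beta_means,beta_sds named numeric vectors over `beta0`, `beta_nd`,
#'   `beta_des`, `beta_esprev`, `beta_hor`.
#' @param oc_effect_on_des slope of `beta_des` on the OC score.
#' @param conf_effect confidence slope on `beta_des`.
#' @param oc_direct_on_conf direct OC effect on the confidence intercept.
#' @param conf_intercept,conf_noise_sd confidence-model constants.
#' @param seed RNG seed.
#' @return a data.frame, one row per subject, with `subject_id`, `oc`, the
#'   five betas and the confidence parameters.
#' @export
generate_population <- function(n_subjects,
                                beta_means = c(beta0 = -4, beta_nd = 0.15,
                                               beta_des = 0.6,
                                               beta_esprev = 0.25,
                                               beta_hor = -0.8),
                                beta_sds = c(beta0 = 0.3, beta_nd = 0.05,
                                             beta_des = 0.1,
                                             beta_esprev = 0.05,
                                             beta_hor = 0.1),
                                oc_effect_on_des = -0.3, conf_effect = 25,
                                oc_direct_on_conf = 0,
                                conf_intercept = 60, conf_noise_sd = 10,
                                seed = NULL) {
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  with_seed(seed, {
    oc <- rnorm(n_subjects)
    pop <- data.frame(
      subject_id = sprintf("s%04d", seq_len(n_subjects)), oc = oc,
      beta0 = rnorm(n_subjects, beta_means[["beta0"]], beta_sds[["beta0"]]),
      beta_nd = rnorm(n_subjects, beta_means[["beta_nd"]], beta_sds[["beta_nd"]]),
      beta_des = beta_means[["beta_des"]] + oc_effect_on_des * oc +
        rnorm(n_subjects, 0, beta_sds[["beta_des"]]),
      beta_esprev = rnorm(n_subjects, beta_means[["beta_esprev"]],
                          beta_sds[["beta_esprev"]]),
      beta_hor = rnorm(n_subjects, beta_means[["beta_hor"]], beta_sds[["beta_hor"]]),
      conf_intercept = conf_intercept + oc_direct_on_conf * oc,
      conf_slope = conf_effect, conf_noise_sd = conf_noise_sd,
      stringsAsFactors = FALSE)
    pop
  })
}

#' Simulate a whole cohort over a shared game set
#'
#' Plays every subject of a [generate_population()] table over the same game
#' sequences (features are computed once), returning stacked design rows and
#' per-subject summaries. This is the fast path used by the recovery and
#' replication simulations.
#'
#' @param games list of undecided games.
#' @param population data.frame from [generate_population()].
#' @param seed RNG seed.
#' @param lapse choice lapse rate.
#' @return list with `design` (stacked per-draw rows for all subjects) and
#'   `summaries` (one row per subject, including `oc`).
#' @export
simulate_cohort <- function(games, population, seed = NULL, lapse = 0) {
  feats <- cohort_features(games)
  with_seed(seed, {
    out_rows <- vector("list", nrow(population))
    out_sum <- vector("list", nrow(population))
    for (i in seq_len(nrow(population))) {
      pr <- population[i, ]
      params <- agent_params(beta0 = pr$beta0, beta_nd = pr$beta_nd,
                             beta_des = pr$beta_des,
                             beta_esprev = pr$beta_esprev,
                             beta_hor = pr$beta_hor, oc = pr$oc,
                             conf_intercept = pr$conf_intercept,
                             conf_slope = pr$conf_slope,
                             conf_noise_sd = pr$conf_noise_sd)
      res <- simulate_subject_rows(feats, params, lapse = lapse)
      res$rows$subject_id <- pr$subject_id
      out_rows[[i]] <- res$rows
      out_sum[[i]] <- cbind(subject_id = pr$subject_id, oc = pr$oc,
                            res$summary)
    }
    design <- do.call(rbind, out_rows)
    rownames(design) <- NULL
    list(design = design, summaries = do.call(rbind, out_sum))
  })
}
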