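# Shared fixture builders and independent oracles used across test files.

# Independent brute-force evidence features: plain loops, no shared code
# with the package implementation.
brute_force_evidence <- function(n_A, n_B) {
  n <- length(n_A)
  es_A <- es_B <- es_total <- delta <- numeric(n)
  a <- b <- 0
  prev_total <- 0
  for (d in seq_len(n)) {
    a <- a + n_A[d]
    b <- b + n_B[d]
    es_A[d] <- a
    es_B[d] <- b
    es_total[d] <- max(a, b) - min(a, b)
    delta[d] <- es_total[d] - prev_total
    prev_total <- es_total[d]
  }
  list(es_A = es_A, es_B = es_B, es_total = es_total, delta_es = delta)
}

random_short_game <- function(id = "g1") {
  L <- sample(4:8, 1)
  n_A <- rbinom(L, 5, runif(1, 0.2, 0.8))
  game_record(id, "horizon", n_A = n_A, n_B = 5L - n_A, horizon = "short",
              max_draws = L, true_majority = sample(c("A", "B"), 1))
}

# The two figure-caption example games: a grid sequence whose cumulative
# counts at draw 5 are (3, 2), and a horizon sequence with first draw
# (4 blue, 1 yellow) and cumulative (7 blue, 8 yellow) by draw 3.
fig_grid_game <- function() {
  game_record("fig_grid", "grid", n_A = c(1, 1, 0, 1, 0), n_B = c(0, 0, 1, 0, 1))
}

fig_horizon_game <- function() {
  game_record("fig_horizon", "horizon", n_A = c(4, 2, 1), n_B = c(1, 3, 4),
              horizon = "short", max_draws = 4)
}

# Small standardized epoch set with one embedded variable; returns the
# epoch set plus ground truth.
small_embedded_epochs <- function(n_trials = 100, n_ch = 16, peak_ms = 500,
                                  width_ms = 80, amplitude = 4,
                                  noise_sd = 0.5, seed = 1,
                                  time_ms = seq(-100, 1240, by = 40)) {
  lay <- generate_sensor_layout(n_ch, seed = seed)
  w <- spatial_pattern_random(lay, seed = seed + 1)
  tg <- data.frame(delta_es = withr::with_seed(seed + 2, rnorm(n_trials)),
                   game_id = rep(seq_len(n_trials / 5), each = 5))
  spec <- embedding_spec(list(delta_es = list(weights = w, peak_ms = peak_ms,
                                              width_ms = width_ms,
                                              amplitude = amplitude)),
                         noise_sd = noise_sd)
  ep <- generate_epochs(tg, lay, spec, seed = seed + 3, time_ms = time_ms)
  list(epochs = standardize_epochs(ep), layout = lay, weights = w,
       targets = tg, peak_ms = peak_ms)
}
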