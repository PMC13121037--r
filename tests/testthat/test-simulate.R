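test_that("generators are pure functions of their seed", {
  g1 <- generate_games("horizon", 20, seed = 5)
  g2 <- generate_games("horizon", 20, seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_games("horizon", 20, seed = 6)))

  p1 <- generate_population(30, seed = 7)
  expect_identical(p1, generate_population(30, seed = 7))

  lay <- generate_sensor_layout(40, seed = 3, jitter_sd = 0.01)
  expect_identical(lay, generate_sensor_layout(40, seed = 3, jitter_sd = 0.01))

  # the generator restores the ambient RNG stream
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_games("horizon", 4, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("horizon games split 80/80 with the stated draw ranges", {
  games <- generate_games("horizon", 160, seed = 8)
  hz <- vapply(games, function(g) g$horizon, character(1))
  expect_identical(sum(hz == "short"), 80L)
  expect_identical(sum(hz == "long"), 80L)
  md <- vapply(games, function(g) g$max_draws, integer(1))
  expect_true(all(md[hz == "short"] %in% 4:8))
  expect_true(all(md[hz == "long"] %in% 10:14))
  expect_true(all(vapply(games, function(g) all(g$n_A + g$n_B == 5L), logical(1))))
})

test_that("grid games reveal one stimulus over 25 locations", {
  games <- generate_games("grid", 15, seed = 9)
  expect_length(games, 15L)
  for (g in games[1:3]) {
    expect_identical(length(g$n_A), 25L)
    expect_true(all(g$n_A + g$n_B == 1L))
  }
})

test_that("a near-degenerate majority rate makes evidence strictly increase", {
  games <- generate_games("horizon", 10, p_majority = 0.999, seed = 10)
  for (g in games) {
    es <- evidence_strength(g)$es_total
    expect_true(all(diff(es) > 0))
  }
  expect_error(generate_games("horizon", 10, p_majority = 0.4), "p_majority")
  expect_error(generate_games("horizon", 10, p_majority = 1), "p_majority")
})

test_that("regressor decorrelation honors the requested bound", {
  games <- generate_games("horizon", 60, p_majority = 0.55, seed = 11,
                          max_abs_corr = 0.6, max_tries = 50)
  feats <- do.call(rbind, lapply(games, deltaES:::evidence_features))
  cc <- cor(feats[, c("n_d", "delta_es", "es_prev")])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.6)
})

test_that("a saturated negative intercept yields only non-decisions", {
  games <- generate_games("horizon", 20, seed = 12)
  ag <- simulate_agent(games, agent_params(beta0 = -50), seed = 13)
  expect_identical(ag$summary$n_decided, 0L)
  expect_true(all(ag$design$decide == 0L))
  expect_true(all(vapply(ag$games, function(g) is.na(g$decision_draw), logical(1))))
})

test_that("an indifferent agent stops like a truncated geometric", {
  # with all slopes 0 and beta0 = 0, p(decide) = 0.5 at every draw;
  # the closed-form expectation of the decision draw in a game with L
  # draws is sum(d * 0.5^d) / (1 - 0.5^L), conditional on deciding
  games <- generate_games("horizon", 2000, seed = 14)
  params <- agent_params(beta0 = 0, beta_nd = 0, beta_des = 0,
                        beta_esprev = 0, beta_hor = 0)
  ag <- simulate_agent(games, params, seed = 15)
  L <- vapply(ag$games, function(g) length(g$n_A), numeric(1))
  expected_mean <- mean(vapply(L, function(l) {
    d <- seq_len(l)
    sum(d * 0.5^d) / (1 - 0.5^l)
  }, numeric(1)))
  got <- ag$summary$mean_draws
  expect_lt(abs(got - expected_mean), 3 * sqrt(2 / ag$summary$n_decided))
})

test_that("weaker dES weighting strictly lengthens information gathering", {
  games <- generate_games("horizon", 4000, seed = 16)
  hi <- simulate_agent(games, agent_params(beta_des = 0.8), seed = 17)
  lo <- simulate_agent(games, agent_params(beta_des = 0.2), seed = 17)
  expect_gt(lo$summary$mean_draws, hi$summary$mean_draws)
})

test_that("population OC effect on the dES weight is recovered by regression", {
  pop <- generate_population(500, oc_effect_on_des = -0.5,
                             beta_sds = c(beta0 = 0.3, beta_nd = 0.05,
                                          beta_des = 0.1, beta_esprev = 0.05,
                                          beta_hor = 0.1), seed = 18)
  slope <- coef(lm(beta_des ~ oc, pop))[["oc"]]
  expect_lt(abs(slope - (-0.5)), 0.05)

  null_pop <- generate_population(500, oc_effect_on_des = 0, seed = 19)
  expect_lt(abs(cor(null_pop$oc, null_pop$beta_des)), 3 / sqrt(500))
})

test_that("sensor layouts have symmetric, well-sized neighborhoods", {
  lay <- generate_sensor_layout(273)
  expect_identical(lay$n_sensors, 273L)
  deg <- lengths(lay$neighbors)
  expect_true(all(deg >= 2))
  expect_gt(mean(deg), 4)
  expect_lt(mean(deg), 8)
  for (i in sample(273, 25)) {
    for (j in lay$neighbors[[i]]) {
      expect_true(i %in% lay$neighbors[[j]])
    }
  }
})

test_that("three collinear sensors fall back to a chain adjacency", {
  lay <- sensor_layout_from_positions(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_identical(lay$neighbors, list(2L, c(1L, 3L), 2L))
})

test_that("a noiseless embedding is rank one and perfectly decodable at peak", {
  lay <- sensor_layout_from_positions(cbind(0:3, c(0, 1, 0, 1)))
  tg <- data.frame(delta_es = deltaES:::with_seed(20, rnorm(60)))
  spec <- embedding_spec(list(delta_es = list(weights = c(1, 0.5, 0, 0),
                                              peak_ms = 500, width_ms = 100)),
                         noise_sd = 0)
  ep <- generate_epochs(tg, lay, spec, seed = 21,
                        time_ms = seq(0, 1000, by = 100))
  peak_idx <- which.min(abs(ep$time_ms - 500))
  slab <- ep$data[, , peak_idx]
  sv <- svd(slab)$d
  expect_gt(sv[1], 1e-8)
  expect_lt(sv[2] / sv[1], 1e-10)
  expect_equal(abs(cor(slab[, 1], tg$delta_es)), 1, tolerance = 1e-12)
})

test_that("OC attenuation scales only the targeted variable's amplitude", {
  lay <- sensor_layout_from_positions(cbind(0:3, c(0, 1, 0, 1)))
  tg <- data.frame(delta_es = deltaES:::with_seed(22, rnorm(40)))
  mk <- function(att, oc) {
    spec <- embedding_spec(list(delta_es = list(weights = c(1, 1, 0, 0),
                                                peak_ms = 400, width_ms = 100)),
                           noise_sd = 0, oc_attenuation = att)
    generate_epochs(tg, lay, spec, oc = oc, seed = 23,
                    time_ms = seq(0, 800, by = 100))$data
  }
  # no attenuation: identical epochs whatever the OC score
  expect_identical(mk(0, -2), mk(0, 2))
  # attenuation scales amplitude linearly and floors at zero
  expect_equal(mk(-0.35, 1), mk(0, 0) * (1 - 0.35), tolerance = 1e-12)
  expect_true(all(mk(-0.5, 3) == 0)) # 1 + (-0.5)(3) < 0 -> floored
})

test_that("epoch containers validate their dimensions", {
  lay <- sensor_layout_from_positions(cbind(0:2, c(0, 1, 0)))
  tg <- data.frame(delta_es = rnorm(20))
  spec <- embedding_spec(list(delta_es = list(weights = rep(1, 5),
                                              peak_ms = 400, width_ms = 100)))
  expect_error(generate_epochs(tg, lay, spec), "match")
  expect_error(epoch_set(array(0, c(4, 3, 5)), time_ms = 1:4,
                         blocks = rep(1, 4), targets = tg[1:4, , drop = FALSE]),
               "time axis")
})
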