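test_that("block/channel standardization zeroes pooled moments and is idempotent", {
  set.seed(51)
  X <- array(rnorm(60 * 6 * 10, mean = 3, sd = 2), c(60, 6, 10))
  ep <- epoch_set(X, time_ms = seq(0, 900, by = 100), blocks = rep(1:3, each = 20),
                  targets = data.frame(delta_es = rnorm(60)))
  std <- standardize_epochs(ep)
  # oracle: recompute each block x channel's pooled moments directly
  for (b in 1:3) {
    idx <- which(ep$blocks == b)
    for (ch in 1:6) {
      v <- as.vector(std$data[idx, ch, ])
      expect_lt(abs(mean(v)), 1e-12)
      expect_lt(abs(sd(v) - 1), 1e-12)
    }
  }
  again <- standardize_epochs(std)
  expect_lt(max(abs(again$data - std$data)), 1e-8)
})

test_that("constant channels within a block error or zero-fill per flag", {
  X <- array(rnorm(40 * 3 * 5), c(40, 3, 5))
  X[1:20, 2, ] <- 7
  ep <- epoch_set(X, time_ms = seq(0, 400, by = 100), blocks = rep(1:2, each = 20),
                  targets = data.frame(delta_es = rnorm(40)))
  expect_error(standardize_epochs(ep), "constant channel")
  z <- standardize_epochs(ep, constant = "zero")
  expect_true(all(z$data[1:20, 2, ] == 0))
})

test_that("the coordinate-descent lasso agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(52)
  for (i in 1:5) {
    n <- sample(c(60, 150), 1)
    p <- sample(c(8, 25), 1)
    X <- matrix(rnorm(n * p), n)
    beta <- c(rnorm(3), rep(0, p - 3))
    y <- drop(X %*% beta) + rnorm(n)
    lam <- sample(c(0.02, 0.1, 0.3), 1)
    ours <- deltaES:::cd_lasso_fit(X, y, lam, tol = 1e-8)
    ref <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, standardize = FALSE,
                          thresh = 1e-12)
    expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-4)
    expect_equal(ours$intercept, as.numeric(ref$a0), tolerance = 1e-4)
  }
})

test_that("decoding recovers an embedded variable at its kernel peak only", {
  fx <- small_embedded_epochs(n_trials = 100, n_ch = 16, peak_ms = 500,
                              amplitude = 5, noise_sd = 0.3, seed = 61)
  d <- iterative_subset_decode(fx$epochs, "delta_es", n_iter = 20,
                               subset_size = 8, seed = 62)
  peak_idx <- which.min(abs(d$time_ms - 500))
  expect_gt(d$r_t[peak_idx], 0.9)
  expect_gt(d$r_t[peak_idx], d$r_t[1]) # far above the pre-stimulus baseline
  expect_equal(d$peak_time_ms, d$time_ms[which.max(d$r_t)])
})

test_that("decodability of fresh noise targets is nil and permutation kills signal", {
  fx <- small_embedded_epochs(n_trials = 100, n_ch = 16, seed = 63)
  noise_target <- deltaES:::with_seed(64, rnorm(100))
  d0 <- iterative_subset_decode(fx$epochs, noise_target, n_iter = 10,
                                subset_size = 8, seed = 65)
  # cross-validated correlations are slightly negatively biased under the
  # null (held-out predictions lean on fold means), so the band is centered
  # just below zero rather than at zero
  expect_gt(mean(d0$r_t), -0.15)
  expect_lt(mean(d0$r_t), 0.05)
  expect_lt(max(d0$r_t), 0.3)

  d1 <- iterative_subset_decode(fx$epochs, "delta_es", n_iter = 10,
                                subset_size = 8, seed = 66)
  hits <- 0
  for (k in 1:20) {
    perm <- deltaES:::with_seed(100 + k, sample(fx$epochs$targets$delta_es))
    dp <- iterative_subset_decode(fx$epochs, perm, n_iter = 3,
                                  subset_size = 8, seed = 67)
    hits <- hits + (max(dp$r_t) < max(d1$r_t))
  }
  expect_gte(hits, 19)
})

test_that("decoding is deterministic given the seed", {
  fx <- small_embedded_epochs(n_trials = 60, n_ch = 10, seed = 68,
                              time_ms = seq(0, 600, by = 100))
  d1 <- iterative_subset_decode(fx$epochs, "delta_es", n_iter = 5,
                                subset_size = 6, seed = 70)
  d2 <- iterative_subset_decode(fx$epochs, "delta_es", n_iter = 5,
                                subset_size = 6, seed = 70)
  expect_identical(d1$r_t, d2$r_t)
  d3 <- iterative_subset_decode(fx$epochs, "delta_es", n_iter = 5,
                                subset_size = 6, seed = 71)
  expect_false(identical(d1$r_t, d3$r_t))
})

test_that("lambda tuning returns singletons, enforces orthogonality, and ties up", {
  fx <- small_embedded_epochs(n_trials = 80, n_ch = 10, seed = 72,
                              time_ms = seq(0, 600, by = 100))
  ortho <- deltaES:::with_seed(73, rnorm(80))
  tl <- tune_lambda(fx$epochs, ortho, grid = 0.05, n_iter = 1, seed = 74,
                    max_abs_corr = 0.35)
  expect_identical(tl$lambda, 0.05)
  # a tuning variable correlated with an analysis target is rejected
  corr_target <- fx$epochs$targets$delta_es + deltaES:::with_seed(75, rnorm(80, 0, 0.1))
  expect_error(tune_lambda(fx$epochs, corr_target, grid = c(0.01, 0.1)),
               "correlates")
  # with a pure-noise tuning target and penalties large enough to zero
  # every coefficient, scores tie exactly and the largest lambda wins
  tl2 <- tune_lambda(fx$epochs, ortho, grid = c(5, 10, 20), n_iter = 1,
                     seed = 76, max_abs_corr = 0.35)
  expect_identical(tl2$lambda, 20)
  expect_identical(tl2$scores$score[1], tl2$scores$score[3])
})

test_that("searchlight maps localize a neighborhood-confined embedding", {
  lay <- generate_sensor_layout(30, seed = 81)
  center <- 7L
  w <- spatial_pattern_local(lay, center)
  tg <- data.frame(delta_es = deltaES:::with_seed(82, rnorm(100)),
                   game_id = rep(1:20, each = 5))
  spec <- embedding_spec(list(delta_es = list(weights = w, peak_ms = 300,
                                              width_ms = 80, amplitude = 5)),
                         noise_sd = 0.5)
  ep <- standardize_epochs(generate_epochs(tg, lay, spec, seed = 83,
                                           time_ms = seq(0, 600, by = 50)))
  sl <- searchlight_decode(ep, "delta_es", lay, window_ms = c(250, 350),
                           seed = 84)
  best <- which.max(sl$values)
  expect_true(best %in% c(center, lay$neighbors[[center]]))
  expect_error(searchlight_decode(ep, "delta_es", lay,
                                  window_ms = c(500, 900), seed = 84),
               "window")
})

test_that("peak latency takes the first index on plateaus and averages", {
  tm <- seq(0, 500, by = 100)
  M <- rbind(c(0, 1, 1, 1, 0, 0),
             c(0, 0, 0.2, 0.9, 0.3, 0))
  pl <- peak_latency(M, time_ms = tm)
  expect_identical(pl$peaks_ms, c(100, 300))
  expect_identical(pl$group_mean_ms, 200)
})

test_that("decoder input contracts are enforced", {
  fx <- small_embedded_epochs(n_trials = 40, n_ch = 6, seed = 85,
                              time_ms = seq(0, 300, by = 100))
  expect_error(iterative_subset_decode(fx$epochs, "delta_es", subset_size = 50),
               "subset_size")
  expect_error(iterative_subset_decode(fx$epochs, rep(1, 40), n_iter = 2,
                                       subset_size = 3), "variance")
  expect_error(iterative_subset_decode(fx$epochs, "nope", n_iter = 2,
                                       subset_size = 3), "unknown target")
})
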