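make_summaries <- function(...) {
  base <- data.frame(subject_id = "s1", mean_draws = 8, accuracy = 0.95,
                     n_unique_draws = 6, mean_confidence = 70,
                     n_unique_confidence = 10, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("participant filters apply the published inclusion bounds", {
  ok <- filter_participants(make_summaries())
  expect_true(ok$included)
  expect_true(ok$conf_included)
  expect_identical(ok$reasons, "")

  r <- filter_participants(make_summaries(mean_draws = 1.5))
  expect_false(r$included)
  expect_match(r$reasons, "mean_draws")

  # accuracy must be strictly above 0.80
  r <- filter_participants(make_summaries(accuracy = 0.80))
  expect_false(r$included)
  expect_match(r$reasons, "accuracy")
  expect_true(filter_participants(make_summaries(accuracy = 0.801))$included)

  r <- filter_participants(make_summaries(n_unique_draws = 1))
  expect_false(r$included)
  expect_match(r$reasons, "unique_draws")

  # confidence criteria are a separate flag
  r <- filter_participants(make_summaries(mean_confidence = 99))
  expect_true(r$included)
  expect_false(r$conf_included)
  r <- filter_participants(make_summaries(mean_confidence = 15,
                                          n_unique_confidence = 3))
  expect_true(r$conf_included) # bounds are inclusive

  # filters are idempotent: refiltering the report changes nothing
  rep1 <- filter_participants(make_summaries(accuracy = 0.7))
  rep2 <- filter_participants(rep1)
  expect_identical(rep1$included, rep2$included)
  expect_identical(rep1$reasons, rep2$reasons)
})

test_that("the penalized logistic fit matches glm when the penalty vanishes", {
  set.seed(31)
  n <- 400
  rows <- data.frame(
    n_d = rnorm(n), delta_es = rnorm(n), es_prev = rnorm(n),
    decide = NA)
  eta <- -0.5 + 0.8 * rows$delta_es + 0.3 * rows$es_prev - 0.2 * rows$n_d
  rows$decide <- rbinom(n, 1, plogis(eta))
  fit <- fit_subject_glm(rows, "main", ridge_eps = 0, standardize = FALSE)
  ref <- glm(decide ~ n_d + delta_es + es_prev, binomial, rows)
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_equal(co$estimate, unname(coef(ref)[c("(Intercept)", "n_d",
                                               "delta_es", "es_prev")]),
               tolerance = 1e-6)
  expect_equal(co$se, unname(summary(ref)$coefficients[c("(Intercept)", "n_d",
                                                         "delta_es", "es_prev"),
                                                       "Std. Error"]),
               tolerance = 1e-5)
})

test_that("complete separation stays finite under the ridge penalty", {
  set.seed(32)
  rows <- data.frame(n_d = rnorm(50), delta_es = c(rnorm(25, 3), rnorm(25, -3)),
                     es_prev = rnorm(50))
  rows$decide <- as.integer(rows$delta_es > 0)
  fit <- fit_subject_glm(rows, "main", standardize = FALSE)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_true(all(fit$coefficients$se > 0))
})

test_that("degenerate outcomes and constant predictors are flagged", {
  rows <- data.frame(n_d = rnorm(30), delta_es = rnorm(30), es_prev = rnorm(30),
                     decide = 1L)
  fit <- fit_subject_glm(rows, "main")
  expect_false(fit$converged)
  expect_true(all(is.na(fit$coefficients$estimate)))

  rows$decide <- rbinom(30, 1, 0.4)
  rows$es_prev <- 2
  fit <- fit_subject_glm(rows, "main", standardize = FALSE)
  expect_identical(fit$non_identified, "es_prev")
  expect_true(is.na(fit$coefficients$estimate[fit$coefficients$term == "es_prev"]))
  expect_false(is.na(fit$coefficients$estimate[fit$coefficients$term == "delta_es"]))
})

test_that("rows with missing lagged regressors are dropped, not zero-filled", {
  set.seed(33)
  games <- generate_games("horizon", 60, seed = 41)
  ag <- simulate_agent(games, agent_params(), seed = 42)
  fit <- fit_subject_glm(ag$design, "recency")
  d <- ag$design
  complete <- complete.cases(d[, c("es_chosen_lag0", "es_chosen_lag1",
                                   "es_chosen_lag2")])
  expect_identical(fit$n_rows, sum(complete))
})

test_that("recency bias is positive for recency-weighted deciders and flips", {
  set.seed(34)
  sim_recency <- function(w, n = 3000) {
    rows <- data.frame(es_chosen_lag0 = rnorm(n), es_chosen_lag1 = rnorm(n),
                       es_chosen_lag2 = rnorm(n))
    eta <- -1 + w[1] * rows$es_chosen_lag0 + w[2] * rows$es_chosen_lag1 +
      w[3] * rows$es_chosen_lag2
    rows$decide <- rbinom(n, 1, plogis(eta))
    fit_subject_glm(rows, "recency", standardize = FALSE)
  }
  fit_fwd <- sim_recency(c(0.6, 0.25, 0.2))
  expect_gt(recency_bias(fit_fwd), 0)
  fit_rev <- sim_recency(c(0.25, 0.6, 0.2))
  expect_lt(recency_bias(fit_rev), 0)
  expect_error(recency_bias(fit_subject_glm(data.frame(
    n_d = rnorm(30), delta_es = rnorm(30), es_prev = rnorm(30),
    decide = rbinom(30, 1, 0.5)), "main")), "recency")
})

test_that("Tukey-fence outlier exclusion matches a brute-force scan", {
  set.seed(35)
  B <- matrix(rnorm(200 * 3), 200, 3)
  B[7, 2] <- quantile(B[, 2], 0.75) + 10 * IQR(B[, 2])
  keep <- exclude_beta_outliers(B)
  expect_false(keep[7])
  oracle <- rep(TRUE, nrow(B))
  for (j in 1:ncol(B)) {
    q <- quantile(B[, j], c(0.25, 0.75))
    lo <- q[1] - 1.5 * (q[2] - q[1])
    hi <- q[2] + 1.5 * (q[2] - q[1])
    oracle <- oracle & B[, j] >= lo & B[, j] <= hi
  }
  expect_identical(keep, oracle)
  # equal values sit inside the closed fence interval
  expect_true(all(exclude_beta_outliers(matrix(1, 10, 2))))
  # idempotent: excluding again from the retained set removes no one more
  # than a fresh scan of that set would
  keep2 <- exclude_beta_outliers(B[keep, , drop = FALSE])
  expect_identical(keep2, exclude_beta_outliers(B[keep, , drop = FALSE]))
})

test_that("Spearman association handles exact monotone and seeded bootstrap", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_assoc(x, x, n_boot = 0)$rho, 1)
  expect_equal(spearman_assoc(x, -x, n_boot = 0)$rho, -1)
  set.seed(36)
  y <- rnorm(40)
  z <- rnorm(40)
  a <- spearman_assoc(y, z, n_boot = 500, seed = 7)
  b <- spearman_assoc(y, z, n_boot = 500, seed = 7)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$rho && a$rho <= a$ci[2])
})

test_that("two-stage fixed effects recover a homogeneous population", {
  games <- generate_games("horizon", 160, seed = 51)
  pop <- generate_population(30, oc_effect_on_des = 0,
                             beta_sds = c(beta0 = 1e-6, beta_nd = 1e-6,
                                          beta_des = 1e-6, beta_esprev = 1e-6,
                                          beta_hor = 1e-6), seed = 52)
  coh <- simulate_cohort(games, pop, seed = 53)
  ts <- fit_two_stage(coh$design, "main_horizon", standardize = FALSE)
  est <- setNames(ts$fixed$estimate, ts$fixed$term)
  expect_lt(abs(est[["delta_es"]] - 0.6), 0.1)
  expect_lt(abs(est[["n_d"]] - 0.15), 0.1)
  expect_lt(abs(est[["es_prev"]] - 0.25), 0.1)
  # homogeneous subjects: between-subject heterogeneity is near zero
  expect_lt(ts$fixed$tau2[ts$fixed$term == "delta_es"], 0.01)
  expect_error(fit_two_stage(coh$design[coh$design$subject_id %in%
                                          unique(coh$design$subject_id)[1:5], ],
                             "main_horizon"), "estimable")
})
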