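formula_terms <- function(formula_id) {
  switch(formula_id,
    main = c("n_d", "delta_es", "es_prev"),
    main_horizon = c("n_d", "delta_es", "es_prev", "horizon"),
    recency = c("es_chosen_lag0", "es_chosen_lag1", "es_chosen_lag2"),
    stop("unknown formula_id: ", formula_id, call. = FALSE))
}

#' Fit a per-subject logistic stopping model
#'
#' Maximum-likelihood logistic regression of the per-draw decide indicator
#' on the stopping-model regressors, with a small quadratic (ridge) penalty
#' `ridge_eps` on the slopes so estimates stay finite under complete
#' separation. Three regressor sets are supported: `"main"`
#' (`N_d`, `dES`, `ES_{d-1}`), `"main_horizon"` (adds the coded horizon
#' condition) and `"recency"` (chosen-relative evidence at lags 0, 1, 2).
#' Rows with missing required regressors (early-draw lags, games without a
#' choice) are dropped before fitting.
#'
#' By default continuous regressors are z-scored within the table, so betas
#' are on a per-SD scale comparable across subjects; the coded horizon
#' column is left as is. Set `standardize = FALSE` to fit on the raw feature
#' scale (used e.g. for parameter recovery against a generator defined on
#' that scale). Constant regressors are flagged non-identified and get `NA`
#' coefficients.
#'
#' @param rows design rows for one subject ([build_design_table()] /
#'   [simulate_agent()] output).
#' @param formula_id `"main"`, `"main_horizon"` or `"recency"`.
#' @param ridge_eps ridge penalty on slopes (default `1e-4`).
#' @param standardize z-score continuous regressors before fitting.
#' @param conf_level Wald confidence level.
#' @return an object of class `fit_result`: list with `subject_id`,
#'   `formula_id`, `coefficients` (data.frame: term, estimate, se, ci_lo,
#'   ci_hi, z, p), `converged`, `n_rows`, `non_identified`.
#' @export
fit_subject_glm <- function(rows, formula_id = c("main", "main_horizon", "recency"),
                            ridge_eps = 1e-4, standardize = TRUE,
                            conf_level = 0.95) {
  formula_id <- match.arg(formula_id)
  terms <- formula_terms(formula_id)
  subject_id <- if ("subject_id" %in% names(rows)) rows$subject_id[1L] else NA_character_
  cols <- rows[, c(terms, "decide"), drop = FALSE]
  cols <- cols[complete.cases(cols), , drop = FALSE]
  y <- cols$decide
  res <- list(subject_id = subject_id, formula_id = formula_id,
              converged = FALSE, n_rows = nrow(cols),
              non_identified = character(0L), standardize = standardize,
              ridge_eps = ridge_eps)
  empty <- data.frame(term = c("(Intercept)", terms), estimate = NA_real_,
                      se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (nrow(cols) < length(terms) + 2L || length(unique(y)) < 2L) {
    res$coefficients <- empty
    class(res) <- "fit_result"
    return(res)
  }
  X0 <- as.matrix(cols[, terms, drop = FALSE])
  sds <- apply(X0, 2L, sd)
  res$non_identified <- terms[sds == 0]
  est_terms <- terms[sds > 0]
  X <- X0[, est_terms, drop = FALSE]
  if (standardize) {
    std <- est_terms != "horizon"
    X[, std] <- scale(X[, std, drop = FALSE])
  }
  fit <- ridge_logistic(cbind(`(Intercept)` = 1, X), y, ridge_eps)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  co <- data.frame(term = c("(Intercept)", est_terms), estimate = fit$beta,
                   se = fit$se, ci_lo = fit$beta - zc * fit$se,
                   ci_hi = fit$beta + zc * fit$se,
                   z = fit$beta / fit$se,
                   p = 2 * pnorm(-abs(fit$beta / fit$se)),
                   stringsAsFactors = FALSE)
  co <- merge(empty["term"], co, by = "term", all.x = TRUE, sort = FALSE)
  co <- co[match(empty$term, co$term), ]
  rownames(co) <- NULL
  res$coefficients <- co
  res$converged <- fit$converged
  class(res) <- "fit_result"
  res
}

# Newton-Raphson for logistic log-likelihood with quadratic penalty
# 0.5 * eps * ||slopes||^2 (intercept unpenalized). SEs from the penalized
# observed information.
ridge_logistic <- function(X, y, eps, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- c(0, rep(eps, p - 1L))
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + diag(pen, p)
    g <- crossprod(X, y - mu) - pen * beta
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    # step-halving to keep the penalized log-likelihood from diverging
    step <- 1
    repeat {
      cand <- beta + step * delta
      if (all(is.finite(cand)) && max(abs(cand)) < 1e6) break
      step <- step / 2
      if (step < 1e-8) break
    }
    beta <- beta + step * delta
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X, X * w) + diag(pen, p)
  se <- sqrt(diag(solve(H)))
  list(beta = drop(beta), se = se, converged = converged && all(is.finite(se)))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> formula=%s n=%d converged=%s\n",
              as.character(x$subject_id), x$formula_id, x$n_rows, x$converged))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Tidy per-subject fits into one table
#'
#' @param fits list of `fit_result` objects.
#' @return data.frame with subject, term, estimate, se, ci_lo, ci_hi,
#'   converged.
#' @export
tidy_fits <- function(fits) {
  out <- lapply(fits, function(f) {
    cbind(subject_id = f$subject_id, f$coefficients, converged = f$converged,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-stage hierarchical stopping-model fit
#'
#' Approximates the random-slopes mixed model with a two-stage estimator:
#' stage 1 fits [fit_subject_glm()] to each subject; stage 2 combines the
#' per-subject coefficients meta-analytically (random-effects model,
#' DerSimonian-Laird heterogeneity, via \pkg{metafor}), giving population
#' fixed effects whose standard errors account for both within-subject
#' sampling error and between-subject spread. When an OC covariate is
#' supplied, each coefficient is additionally regressed on OC in a
#' random-effects meta-regression; the OC slope is the interaction effect
#' (e.g. `dES x OC`).
#'
#' @param design stacked design rows for all subjects (must contain
#'   `subject_id`).
#' @param formula_id regressor set, as in [fit_subject_glm()].
#' @param oc optional per-subject OC scores: named vector or data.frame with
#'   `subject_id` and `oc`.
#' @param min_subjects minimum estimable subjects (default 10).
#' @param ... passed to [fit_subject_glm()].
#' @return list with `fixed` (term, estimate, se, z, p, tau2),
#'   `interactions` (same columns, OC moderator; `NULL` without `oc`),
#'   `subject_fits` (tidy stage-1 table) and `n_subjects`.
#' @export
fit_two_stage <- function(design, formula_id = "main", oc = NULL,
                          min_subjects = 10L, ...) {
  fits <- lapply(split(design, design$subject_id), fit_subject_glm,
                 formula_id = formula_id, ...)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1L))
  fits <- fits[ok]
  if (length(fits) < min_subjects) {
    stop(sprintf("only %d estimable subjects (need >= %d)",
                 length(fits), min_subjects), call. = FALSE)
  }
  tidy <- tidy_fits(fits)
  if (!is.null(oc)) {
    if (is.data.frame(oc)) {
      oc_vec <- oc$oc[match(unique(tidy$subject_id), oc$subject_id)]
    } else {
      oc_vec <- oc[match(unique(tidy$subject_id), names(oc))]
    }
  }
  terms <- setdiff(unique(tidy$term), "(Intercept)")
  one_term <- function(tm, mods = FALSE) {
    d <- tidy[tidy$term == tm & !is.na(tidy$estimate), ]
    m <- if (mods) {
      x <- oc_vec[match(d$subject_id, unique(tidy$subject_id))]
      metafor::rma(yi = d$estimate, sei = d$se, mods = ~x, method = "DL")
    } else {
      metafor::rma(yi = d$estimate, sei = d$se, method = "DL")
    }
    i <- if (mods) 2L else 1L
    data.frame(term = if (mods) paste0(tm, ":oc") else tm,
               estimate = unname(m$beta[i]), se = m$se[i], z = m$zval[i],
               p = m$pval[i], tau2 = m$tau2, stringsAsFactors = FALSE)
  }
  fixed <- do.call(rbind, lapply(c("(Intercept)", terms), one_term))
  interactions <- if (!is.null(oc)) {
    do.call(rbind, lapply(terms, one_term, mods = TRUE))
  } else NULL
  rownames(fixed) <- NULL
  if (!is.null(interactions)) rownames(interactions) <- NULL
  list(fixed = fixed, interactions = interactions, subject_fits = tidy,
       n_subjects = length(fits))
}

#' Recency-bias metric
#'
#' Difference between the stopping-model weights on current-draw and
#' previous-draw chosen-relative evidence, `beta(ES_d) - beta(ES_{d-1})`,
#' from a `"recency"`-formula fit. A positive value means the most recent
#' evidence carries more weight. A ratio variant is available but
#' non-default.
#'
#' @param fit a `fit_result` with `formula_id = "recency"`.
#' @param type `"difference"` (default) or `"ratio"`.
#' @return scalar; `NA` for non-converged fits.
#' @export
recency_bias <- function(fit, type = c("difference", "ratio")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "fit_result"))
  if (fit$formula_id != "recency") {
    stop("recency_bias needs a 'recency' formula fit", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) return(NA_real_)
  co <- fit$coefficients
  b0 <- co$estimate[co$term == "es_chosen_lag0"]
  b1 <- co$estimate[co$term == "es_chosen_lag1"]
  if (type == "difference") b0 - b1 else b0 / b1
}

#' Behavioural and confidence participant filters
#'
#' Applies the per-subject inclusion criteria for a 15-game session:
#' mean draws to decision within \[2, 23\], accuracy strictly above 0.80,
#' and at least 3 unique draws-to-decision values. A separate confidence
#' flag requires mean confidence within \[15, 98\] and at least 3 unique
#' confidence values. Bounds are configurable through `criteria`.
#'
#' @param summaries data.frame with `subject_id`, `mean_draws`, `accuracy`,
#'   `n_unique_draws`, and (for the confidence flag) `mean_confidence`,
#'   `n_unique_confidence` (as produced by [simulate_agent()] /
#'   [simulate_cohort()]).
#' @param criteria named list overriding any of `draws_range`,
#'   `min_accuracy`, `min_unique_draws`, `confidence_range`,
#'   `min_unique_confidence`.
#' @return data.frame of class `filter_report`: per subject the criteria
#'   values, `included` (behavioural), `conf_included`, and a `reasons`
#'   string listing failed criteria.
#' @export
filter_participants <- function(summaries, criteria = list()) {
  cr <- modifyList(list(draws_range = c(2, 23), min_accuracy = 0.80,
                        min_unique_draws = 3L, confidence_range = c(15, 98),
                        min_unique_confidence = 3L), criteria)
  fail <- function(cond, label) ifelse(is.na(cond) | cond, "", label)
  r1 <- fail(summaries$mean_draws >= cr$draws_range[1] &
             summaries$mean_draws <= cr$draws_range[2], "mean_draws")
  r2 <- fail(summaries$accuracy > cr$min_accuracy, "accuracy")
  r3 <- fail(summaries$n_unique_draws >= cr$min_unique_draws, "unique_draws")
  r4 <- fail(summaries$mean_confidence >= cr$confidence_range[1] &
             summaries$mean_confidence <= cr$confidence_range[2],
             "mean_confidence")
  r5 <- fail(summaries$n_unique_confidence >= cr$min_unique_confidence,
             "unique_confidence")
  reasons <- apply(cbind(r1, r2, r3, r4, r5), 1L, function(z) {
    paste(z[nzchar(z)], collapse = ",")
  })
  out <- data.frame(
    subject_id = summaries$subject_id,
    mean_draws = summaries$mean_draws, accuracy = summaries$accuracy,
    n_unique_draws = summaries$n_unique_draws,
    mean_confidence = summaries$mean_confidence %||% NA_real_,
    n_unique_confidence = summaries$n_unique_confidence %||% NA_real_,
    included = !nzchar(r1) & !nzchar(r2) & !nzchar(r3),
    conf_included = !nzchar(r4) & !nzchar(r5),
    reasons = reasons, stringsAsFactors = FALSE)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' Tukey-fence outlier exclusion over subject coefficients
#'
#' A subject is excluded if any coefficient in the supplied set falls
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles computed across
#' subjects per coefficient. The interval is closed, so identical values
#' (IQR = 0) are all retained.
#'
#' @param betas numeric matrix (subjects x coefficients) or a data.frame of
#'   numeric columns; rownames/`subject_id` column identify subjects.
#' @param k fence multiplier (default 1.5).
#' @return logical inclusion vector, one element per subject.
#' @export
exclude_beta_outliers <- function(betas, k = 1.5) {
  if (is.data.frame(betas)) {
    betas <- as.matrix(betas[, vapply(betas, is.numeric, logical(1L)),
                             drop = FALSE])
  }
  inside <- apply(betas, 2L, function(x) {
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2L] - q[1L]
    x >= q[1L] - k * iqr & x <= q[2L] + k * iqr
  })
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = nrow(betas))
  apply(inside, 1L, all)
}

#' Spearman rank association with bootstrap CI
#'
#' Spearman's rho with an asymptotic p-value (ties-robust t approximation,
#' as `cor.test(exact = FALSE)`) and a seeded case-resampling percentile
#' bootstrap confidence interval.
#'
#' @param x,y numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param n_boot bootstrap resamples for the CI (0 disables).
#' @param conf_level CI level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `rho`, `p`, `ci`, `n`, `alternative`.
#' @export
spearman_assoc <- function(x, y, alternative = "two.sided", n_boot = 10000L,
                           conf_level = 0.95, seed = NULL) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = alternative, exact = FALSE))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    n <- length(x)
    ci <- with_seed(seed, {
      rb <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        suppressWarnings(cor(x[i], y[i], method = "spearman"))
      }, numeric(1L))
      quantile(rb, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
               na.rm = TRUE, names = FALSE)
    })
  }
  list(rho = unname(ct$estimate), p = ct$p.value, ci = ci, n = length(x),
       alternative = alternative)
}
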