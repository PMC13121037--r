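#' Cumulative evidence strength for a game
#'
#' Computes, for every draw d, the cumulative counts of the two stimulus
#' types, `ES_dA = sum of A revealed up to d` and `ES_dB` likewise, and the
#' total evidence strength for the current majority,
#' `ES_d_total = ES_d_majority - ES_d_minority = |ES_dA - ES_dB|`, which is
#' zero exactly when the cumulative counts tie (no majority).
#'
#' @param game a [game_record()] with at least one draw.
#' @return a data.frame of class `evidence_series` with columns `draw`,
#'   `n_A`, `n_B`, `es_A`, `es_B`, `es_diff` (signed `es_A - es_B`),
#'   `es_total` and `majority` (`"A"`, `"B"` or `"tie"`).
#' @export
evidence_strength <- function(game) {
  stopifnot(inherits(game, "game_record"))
  if (length(game$n_A) < 1L) stop("game has no draws", call. = FALSE)
  es_A <- cumsum(game$n_A)
  es_B <- cumsum(game$n_B)
  es_diff <- es_A - es_B
  out <- data.frame(
    draw = seq_along(es_A), n_A = game$n_A, n_B = game$n_B,
    es_A = es_A, es_B = es_B, es_diff = es_diff,
    es_total = abs(es_diff),
    majority = ifelse(es_diff > 0L, "A", ifelse(es_diff < 0L, "B", "tie")),
    stringsAsFactors = FALSE)
  class(out) <- c("evidence_series", "data.frame")
  out
}

#' Per-draw update in evidence strength
#'
#' The evidence-strength update is the signed change in total evidence
#' strength from one draw to the next, `dES_d = ES_d_total - ES_{d-1}_total`,
#' with the convention `ES_0_total = 0` so that the first-draw update equals
#' the first-draw evidence. Each term carries its own draw's majority, so the
#' sign is preserved across majority flips.
#'
#' @param series an `evidence_series` from [evidence_strength()], or a bare
#'   numeric vector of `ES_d_total` values.
#' @return numeric vector of per-draw updates.
#' @export
evidence_update <- function(series) {
  es_total <- if (is.data.frame(series)) series$es_total else as.numeric(series)
  if (is.null(es_total)) stop("series lacks es_total", call. = FALSE)
  diff(c(0, es_total))
}

#' Chosen-relative evidence
#'
#' Evidence strength signed with respect to the eventually chosen stimulus,
#' `ES_d_chosen - ES_d_unchosen`: equal to `+ES_d_total` on draws where the
#' choice is the current majority and `-ES_d_total` where it is the current
#' minority. Defined only for games with a recorded choice.
#'
#' @param game a [game_record()] with a non-missing `choice`.
#' @return numeric vector, one signed value per draw.
#' @export
chosen_relative_evidence <- function(game) {
  stopifnot(inherits(game, "game_record"))
  if (is.na(game$choice)) stop("game has no recorded choice", call. = FALSE)
  s <- evidence_strength(game)
  if (game$choice == "A") s$es_diff else -s$es_diff
}

# Per-draw model features for one game: draw number, previous total evidence
# (ES_0 = 0), update, and the signed A-B difference used downstream for
# chosen-relative coding.
evidence_features <- function(game) {
  s <- evidence_strength(game)
  data.frame(
    game_id = game$game_id, n_d = s$draw,
    es_total = s$es_total,
    es_prev = c(0, s$es_total[-nrow(s)]),
    delta_es = evidence_update(s),
    es_diff = s$es_diff,
    stringsAsFactors = FALSE)
}

horizon_code <- function(horizon) {
  unname(c(none = 0, short = -0.5, long = 0.5)[horizon])
}

#' Assemble a per-draw model design table
#'
#' Builds one row per viewed draw, up to and including the decision draw
#' (post-decision draws, which the horizon task keeps presenting, are
#' dropped: the probability of deciding is undefined after a decision).
#' Non-decision games contribute all presented draws with `decide = 0` and
#' are flagged in the `non_decision` column. The horizon condition is coded
#' short = -0.5, long = +0.5 (0 for the grid variant). Chosen-relative
#' evidence at lags 0, 1 and 2 is included for the recency model; lags that
#' would index a draw before the first are `NA` (never zero-filled) and are
#' dropped by the modelling layer, as are the chosen-relative columns of
#' games without a choice.
#'
#' @param games list of [game_record()] objects.
#' @param subject_id subject identifier attached to every row.
#' @return a data.frame with columns `subject_id`, `game_id`, `n_d`,
#'   `es_prev`, `delta_es`, `horizon`, `es_chosen_lag0`, `es_chosen_lag1`,
#'   `es_chosen_lag2`, `decide`, `non_decision`.
#' @export
build_design_table <- function(games, subject_id = "s1") {
  if (inherits(games, "game_record")) games <- list(games)
  rows <- lapply(games, function(g) {
    f <- evidence_features(g)
    n_shown <- nrow(f)
    dd <- g$decision_draw
    keep <- if (is.na(dd)) n_shown else min(dd, n_shown)
    f <- f[seq_len(keep), , drop = FALSE]
    if (!is.na(g$choice)) {
      sgn <- if (g$choice == "A") 1 else -1
      lag0 <- sgn * f$es_diff
      lag1 <- c(NA, lag0[-keep])[seq_len(keep)]
      lag2 <- c(NA, NA, lag0[seq_len(max(keep - 2L, 0L))])[seq_len(keep)]
    } else {
      lag0 <- lag1 <- lag2 <- rep(NA_real_, keep)
    }
    data.frame(
      subject_id = subject_id, game_id = g$game_id,
      n_d = f$n_d, es_prev = f$es_prev, delta_es = f$delta_es,
      horizon = horizon_code(g$horizon),
      es_chosen_lag0 = lag0, es_chosen_lag1 = lag1, es_chosen_lag2 = lag2,
      decide = as.integer(!is.na(dd) & f$n_d == dd),
      non_decision = is.na(dd),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a design table as TSV
#'
#' @param design a data.frame from [build_design_table()].
#' @param path file path.
#' @export
write_design_table <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
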