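#' Construct a single game record
#'
#' A game record holds one game of a sequential information-gathering task:
#' the per-draw counts of the two stimulus types newly revealed at each draw,
#' the horizon condition, and (once an agent or participant has played it)
#' the decision draw, the binary choice and a confidence rating.
#'
#' Two task variants are supported. In the `grid` variant each draw uncovers
#' a single stimulus on a 25-location grid (so `n_A + n_B = 1` per draw and
#' at most 25 draws). In the `horizon` variant each draw reveals five stimuli
#' at once and the game ends after a pre-determined maximum number of draws:
#' 4--8 in the short-horizon condition, 10--14 in the long-horizon condition.
#'
#' @param game_id identifier (scalar).
#' @param variant `"grid"` or `"horizon"`.
#' @param n_A,n_B integer vectors, counts of each stimulus type newly
#'   revealed at each draw.
#' @param horizon `"short"`, `"long"` or `"none"` (grid variant).
#' @param max_draws maximum number of draws the game can present.
#' @param decision_draw draw on which a decision was declared, or `NA` for a
#'   non-decision game.
#' @param choice `"A"`, `"B"` or `NA`.
#' @param confidence confidence rating in \[0, 100\], or `NA`.
#' @param true_majority the generating majority stimulus (`"A"`/`"B"`), used
#'   to score accuracy; `NA` when unknown (real data).
#' @return an object of class `game_record`.
#' @export
game_record <- function(game_id, variant = c("grid", "horizon"),
                        n_A, n_B,
                        horizon = c("none", "short", "long"),
                        max_draws = NULL,
                        decision_draw = NA_integer_, choice = NA_character_,
                        confidence = NA_real_, true_majority = NA_character_) {
  variant <- match.arg(variant)
  horizon <- match.arg(horizon)
  n_A <- as.integer(n_A)
  n_B <- as.integer(n_B)
  if (length(n_A) != length(n_B)) {
    stop("n_A and n_B must have the same length", call. = FALSE)
  }
  if (length(n_A) < 1L) {
    stop("a game must contain at least one draw", call. = FALSE)
  }
  if (is.null(max_draws)) {
    max_draws <- if (variant == "grid") 25L else length(n_A)
  }
  g <- structure(
    list(game_id = game_id, variant = variant, horizon = horizon,
         max_draws = as.integer(max_draws),
         n_A = n_A, n_B = n_B,
         decision_draw = as.integer(decision_draw),
         choice = as.character(choice),
         confidence = as.numeric(confidence),
         true_majority = as.character(true_majority)),
    class = "game_record")
  validate_game(g)
  g
}

#' Validate a game record's structural invariants
#'
#' Checks per-draw stimulus totals (1 for the grid variant, 5 for the horizon
#' variant), draw-count limits, horizon ranges and the decision draw.
#'
#' @param game a [game_record()].
#' @return the game, invisibly; errors on violation.
#' @export
validate_game <- function(game) {
  stopifnot(inherits(game, "game_record"))
  tot <- game$n_A + game$n_B
  n <- length(game$n_A)
  if (any(game$n_A < 0L) || any(game$n_B < 0L)) {
    stop("negative stimulus counts", call. = FALSE)
  }
  if (game$variant == "grid") {
    if (any(tot != 1L)) stop("grid games reveal one stimulus per draw", call. = FALSE)
    if (n > 25L) stop("grid games have at most 25 draws", call. = FALSE)
  } else {
    if (any(tot != 5L)) stop("horizon games reveal five stimuli per draw", call. = FALSE)
    rng <- switch(game$horizon, short = 4:8, long = 10:14,
                  stop("horizon games need a short/long condition", call. = FALSE))
    if (!(game$max_draws %in% rng)) {
      stop(sprintf("max_draws %d outside the %s-horizon range", game$max_draws,
                   game$horizon), call. = FALSE)
    }
  }
  if (!is.na(game$decision_draw) && game$decision_draw > n) {
    stop("decision_draw exceeds the number of presented draws", call. = FALSE)
  }
  if (!is.na(game$confidence) &&
      (game$confidence < 0 || game$confidence > 100)) {
    stop("confidence must lie in [0, 100]", call. = FALSE)
  }
  invisible(game)
}

#' @export
print.game_record <- function(x, ...) {
  cat(sprintf("<game_record %s> variant=%s horizon=%s draws=%d/%d",
              as.character(x$game_id), x$variant, x$horizon,
              length(x$n_A), x$max_draws))
  if (!is.na(x$decision_draw)) {
    cat(sprintf(" decided@%d choice=%s", x$decision_draw, x$choice))
  } else {
    cat(" undecided")
  }
  cat("\n")
  invisible(x)
}

#' Convert games to a long per-draw table
#'
#' One row per draw with game-level fields repeated, matching the on-disk
#' TSV layout used by [write_game_table()].
#'
#' @param games a list of [game_record()] objects (or a single one).
#' @param subject_id optional subject identifier column.
#' @return a data.frame, one row per draw.
#' @export
games_to_table <- function(games, subject_id = NA_character_) {
  if (inherits(games, "game_record")) games <- list(games)
  out <- lapply(games, function(g) {
    n <- length(g$n_A)
    data.frame(subject_id = subject_id, game_id = g$game_id,
               variant = g$variant, draw = seq_len(n),
               n_A = g$n_A, n_B = g$n_B,
               horizon = g$horizon, max_draws = g$max_draws,
               decision_draw = g$decision_draw, choice = g$choice,
               confidence = g$confidence, true_majority = g$true_majority,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rebuild game records from a long per-draw table
#'
#' @param tab a data.frame as produced by [games_to_table()].
#' @return a list of [game_record()] objects.
#' @export
table_to_games <- function(tab) {
  split_ids <- interaction(tab$subject_id, tab$game_id, drop = TRUE)
  lapply(split(tab, split_ids), function(d) {
    d <- d[order(d$draw), ]
    game_record(game_id = d$game_id[1L], variant = d$variant[1L],
                n_A = d$n_A, n_B = d$n_B, horizon = d$horizon[1L],
                max_draws = d$max_draws[1L],
                decision_draw = d$decision_draw[1L], choice = d$choice[1L],
                confidence = d$confidence[1L],
                true_majority = d$true_majority[1L])
  })
}

#' Read / write game tables as TSV
#'
#' @param path file path.
#' @param games list of game records or an already-long data.frame.
#' @param subject_id passed to [games_to_table()] when `games` is a list.
#' @return `read_game_table` returns the long data.frame.
#' @export
read_game_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_game_table
#' @export
write_game_table <- function(games, path, subject_id = NA_character_) {
  tab <- if (is.data.frame(games)) games else games_to_table(games, subject_id)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
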