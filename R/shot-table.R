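#' Canonical shot-event tables
#'
#' A `shot_table` is a validated data frame with one row per field-goal
#' attempt and the canonical columns
#' `player_id, season, game_id, order_in_game, x_ft, y_ft, outcome,
#' point_value, return_points`.  `outcome` is `"S"` (made) or `"F"` (missed);
#' `return_points` is the number of points the shooter's team gained from
#' the attempt until the opponent regained possession and may be `NA`
#' (unknown).  `order_in_game` is the 1-based index of the attempt within
#' the player's own sequence in that game; a player is identified by the
#' (`player_id`, `season`) pair and is never pooled across seasons.
#'
#' Free throws are excluded by construction: the schema carries field goals
#' only, and the "previous" attempt always means the player's own
#' immediately preceding field goal within the same game.
#'
#' @param df data frame with the canonical columns.
#' @param source provenance string (`"user"`, `"synthetic"`, ...).
#' @param seed generating seed, if synthetic.
#' @param court a [court_spec()] used for the coordinate sanity bound.
#' @return A `shot_table` (data frame subclass), stably sorted by
#'   (player, season, game, order).
#' @export
shot_table <- function(df, source = "user", seed = NULL,
                       court = court_spec()) {
  cols <- shot_table_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stopf("schema error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[cols]
  df$player_id <- as.character(df$player_id)
  df$season <- as.character(df$season)
  df$game_id <- as.character(df$game_id)
  df$order_in_game <- as.integer(df$order_in_game)
  df$outcome <- as.character(df$outcome)
  df$point_value <- as.integer(df$point_value)
  df$return_points <- suppressWarnings(as.numeric(df$return_points))
  validate_shot_events(df, court)
  ord <- order(df$player_id, df$season, df$game_id, df$order_in_game,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("shot_table", "data.frame"),
            provenance = list(source = source, seed = seed))
}

#' @rdname shot_table
#' @export
shot_table_columns <- function() {
  c("player_id", "season", "game_id", "order_in_game", "x_ft", "y_ft",
    "outcome", "point_value", "return_points")
}

validate_shot_events <- function(df, court = court_spec(), margin = 5) {
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stopf("validation error: %s (rows %s)", what,
            paste(utils::head(which(cond), 5), collapse = ", "))
  }
  bad(!df$outcome %in% c("S", "F"), "outcome must be 'S' or 'F'")
  bad(!df$point_value %in% c(2L, 3L), "point_value must be 2 or 3")
  bad(!is.finite(df$x_ft) | !is.finite(df$y_ft), "non-finite coordinates")
  bad(df$order_in_game < 1L | is.na(df$order_in_game),
      "order_in_game must be a positive integer")
  bad(df$y_ft < 0, "y_ft must be >= 0")
  d <- shot_distance(df$x_ft, df$y_ft, court)
  bad(d > court$half_court_y + margin, "shot distance beyond half court")
  bad(!is.na(df$return_points) & df$return_points < 0,
      "return_points must be non-negative")
  bad(df$outcome == "S" & df$point_value == 3L & !is.na(df$return_points) &
        df$return_points < 3, "made 3pt must have return_points >= 3")

  # order_in_game must be a contiguous 1..N sequence per player-game
  key <- paste(df$player_id, df$season, df$game_id, sep = "|")
  by_game <- split(df$order_in_game, key)
  ok <- vapply(by_game, function(o) identical(sort(o), seq_along(o)),
               logical(1))
  if (!all(ok))
    stopf("validation error: non-contiguous order_in_game in group(s): %s",
          paste(utils::head(names(by_game)[!ok], 5), collapse = ", "))
  invisible(df)
}

#' @export
print.shot_table <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<shot_table: %d events, %d player-seasons, source=%s>\n",
              nrow(x), length(unique(player_key_of(x$player_id, x$season))),
              pv$source %||% "?"))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read / write the canonical shot CSV
#'
#' The canonical dialect is a UTF-8, comma-separated file with a mandatory
#' header naming exactly the columns of [shot_table_columns()].  An empty
#' `return_points` field means "unknown" (`NA`), not zero.
#'
#' @param path file path.
#' @param dialect only `"canonical"` is defined.
#' @return [read_shot_table()] returns a validated `shot_table`.
#' @export
read_shot_table <- function(path, dialect = "canonical") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(player_id = "character",
                                       season = "character",
                                       game_id = "character"))
  missing_cols <- setdiff(shot_table_columns(), names(df))
  if (length(missing_cols))
    stopf("schema error: file lacks column(s) %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    df <- df[shot_table_columns()]
    return(structure(df, class = c("shot_table", "data.frame"),
                     provenance = list(source = path, seed = NULL)))
  }
  shot_table(df, source = path)
}

#' @rdname read_shot_table
#' @param table a `shot_table`.
#' @export
write_shot_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[shot_table_columns()], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Within-game consecutive shot pairs
#'
#' Pairs each field goal with the player's own next field goal in the same
#' game (the attempt whose location the previous outcome may have shaped):
#' shots 1..N-1 of a game are antecedents of shots 2..N.  Pairs never span
#' two games, so a game with N shots contributes N-1 pairs.
#'
#' @param table a `shot_table`.
#' @param player_key optional `"player_id|season"` key to restrict to one
#'   player.
#' @return Data frame with row indices `ante` and `cons` into `table`
#'   (in `table`'s sorted order).
#' @export
consecutive_pairs <- function(table, player_key = NULL) {
  df <- as.data.frame(table)
  idx <- seq_len(nrow(df))
  if (!is.null(player_key)) {
    keep <- player_key_of(df$player_id, df$season) == player_key
    idx <- idx[keep]
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) < 2) return(data.frame(ante = integer(), cons = integer()))
  same <- df$player_id[-nrow(df)] == df$player_id[-1] &
    df$season[-nrow(df)] == df$season[-1] &
    df$game_id[-nrow(df)] == df$game_id[-1]
  data.frame(ante = idx[-length(idx)][same], cons = idx[-1][same])
}
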