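#' Distance bins
#'
#' Half-open `[lo, hi)` bins of constant width covering a distance range.
#'
#' @param range numeric length-2, feet.
#' @param width bin width, feet.
#' @return Data frame with `lo`, `hi`.
#' @export
make_bins <- function(range = c(2, 30), width = 2) {
  if (diff(range) <= 0) stopf("empty range")
  lo <- seq(range[1], range[2] - width, by = width)
  data.frame(lo = lo, hi = lo + width)
}

# distance cells = bins x point class; restricted to cells with at least
# `min_total` attempts in the cohort
default_cells <- function(table, range = c(2, 30), width = 2,
                          court = court_spec(), min_total = 1) {
  b <- make_bins(range, width)
  cells <- rbind(cbind(b, point_class = 2L), cbind(b, point_class = 3L))
  df <- as.data.frame(table)
  d <- shot_distance(df$x_ft, df$y_ft, court)
  n <- mapply(function(lo, hi, pc)
    sum(d >= lo & d < hi & df$point_value == pc),
    cells$lo, cells$hi, cells$point_class)
  cells <- cells[n >= min_total, , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

# per-player per-cell statistics; internal workhorse of the curve functions
player_cell_stats <- function(table, cells, court) {
  df <- as.data.frame(table)
  d <- shot_distance(df$x_ft, df$y_ft, court)
  pr <- consecutive_pairs(table)
  made_a <- df$outcome[pr$ante] == "S"
  cons3 <- df$point_value[pr$cons] == 3L
  key <- player_key_of(df$player_id, df$season)
  keys <- unique(key)
  out <- vector("list", length(keys))
  for (p in seq_along(keys)) {
    rows <- key == keys[p]
    mine_pair <- key[pr$ante] == keys[p]
    st <- cells
    st$player_key <- keys[p]
    st$n <- st$n_make <- st$nS <- st$nF <- 0L
    st$mean_dist <- st$p3_make <- st$p3_miss <- st$return_mean <- NA_real_
    for (cidx in seq_len(nrow(cells))) {
      in_cell <- rows & d >= cells$lo[cidx] & d < cells$hi[cidx] &
        df$point_value == cells$point_class[cidx]
      st$n[cidx] <- sum(in_cell)
      st$n_make[cidx] <- sum(in_cell & df$outcome == "S")
      if (st$n[cidx] > 0) {
        st$mean_dist[cidx] <- mean(d[in_cell])
        rp <- df$return_points[in_cell]
        if (all(!is.na(rp))) st$return_mean[cidx] <- mean(rp)
      }
      pa <- mine_pair & in_cell[pr$ante]
      st$nS[cidx] <- sum(pa & made_a)
      st$nF[cidx] <- sum(pa & !made_a)
      if (st$nS[cidx] > 0) st$p3_make[cidx] <-
          sum(pa & made_a & cons3) / st$nS[cidx]
      if (st$nF[cidx] > 0) st$p3_miss[cidx] <-
          sum(pa & !made_a & cons3) / st$nF[cidx]
    }
    out[[p]] <- st
  }
  do.call(rbind, out)
}

#' Player selection for distance-binned analyses
#'
#' A player-season is included when it has at least one made and one missed
#' field goal in every cell of the configured bin set.  An empty bin set
#' includes every player (vacuous criterion).
#'
#' @param table a [shot_table()].
#' @param cells data frame of cells (`lo`, `hi`, `point_class`), e.g. from
#'   [distance_bin()] rows; defaults to the cohort's populated 2-ft cells.
#' @param court a [court_spec()].
#' @return Character vector of included `"player_id|season"` keys.
#' @export
select_players_bins <- function(table, cells = NULL, court = court_spec()) {
  df <- as.data.frame(table)
  keys <- unique(player_key_of(df$player_id, df$season))
  if (is.null(cells)) cells <- default_cells(table, court = court)
  if (nrow(cells) == 0) return(keys)
  st <- player_cell_stats(table, cells, court)
  ok <- tapply(st$n_make > 0 & st$n - st$n_make > 0, st$player_key, all)
  names(ok)[ok]
}

aggregate_cells <- function(st, keys, value_col) {
  cells <- unique(st[c("lo", "hi", "point_class")])
  st <- st[st$player_key %in% keys, , drop = FALSE]
  res <- cells
  res$mean_dist <- rep(NA_real_, nrow(res))
  res$value <- rep(NA_real_, nrow(res))
  res$sem <- rep(NA_real_, nrow(res))
  res$n_players <- rep(0L, nrow(res))
  for (i in seq_len(nrow(cells))) {
    sel <- st$lo == cells$lo[i] & st$point_class == cells$point_class[i]
    v <- st[[value_col]][sel]
    v <- v[!is.na(v)]
    res$n_players[i] <- length(v)
    if (length(v)) {
      res$value[i] <- mean(v)
      res$sem[i] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA
      md <- st$mean_dist[sel]
      res$mean_dist[i] <- mean(md[!is.na(md)])
    }
  }
  res[order(res$point_class, res$lo), ]
}

#' Distance-resolved learning curve
#'
#' For each 2-ft distance bin (2pt and 3pt attempts binned separately),
#' computes per player the conditional probability that the next field
#' goal (within the game) is a 3pt attempt, separately after makes and
#' after misses, and their difference — a scalar learning magnitude per
#' distance — then averages over players with equal weight.
#'
#' @param table a [shot_table()].
#' @param cells cells to evaluate (default: populated cells on the 2-30 ft
#'   range at `bin_width` resolution).
#' @param bin_width bin width in feet for the default cells.
#' @param range distance range for the default cells.
#' @param court a [court_spec()].
#' @param players optional pre-selected player keys (default:
#'   [select_players_bins()] on the same cells).
#' @return Data frame (class `distance_curve`) with one row per cell:
#'   `lo, hi, point_class, mean_dist, p3_after_make, p3_after_miss,
#'   learning_diff, sem, n_players`.
#' @export
bin_learning_curve <- function(table, cells = NULL, bin_width = 2,
                               range = c(2, 30), court = court_spec(),
                               players = NULL) {
  if (is.null(cells))
    cells <- default_cells(table, range, bin_width, court)
  if (nrow(cells) == 0) stopf("empty range")
  st <- player_cell_stats(table, cells, court)
  if (is.null(players)) {
    ok <- tapply(st$n_make > 0 & st$n - st$n_make > 0, st$player_key, all)
    players <- names(ok)[ok]
  }
  st$learning_diff <- st$p3_make - st$p3_miss
  ld <- aggregate_cells(st, players, "learning_diff")
  pm <- aggregate_cells(st, players, "p3_make")
  pf <- aggregate_cells(st, players, "p3_miss")
  out <- data.frame(ld[c("lo", "hi", "point_class", "mean_dist")],
                    p3_after_make = pm$value, p3_after_miss = pf$value,
                    learning_diff = ld$value, sem = ld$sem,
                    n_players = ld$n_players)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Shooting percentage by distance
#'
#' Player-averaged ratio of made to attempted field goals per distance
#' cell; 2pt and 3pt attempts sharing a distance bin are separate entries.
#'
#' @inheritParams bin_learning_curve
#' @return Data frame (class `distance_curve`) with `shooting_pct`, `sem`,
#'   `n_players` per cell.
#' @export
shooting_pct_curve <- function(table, cells = NULL, bin_width = 2,
                               range = c(2, 30), court = court_spec(),
                               players = NULL) {
  if (is.null(cells))
    cells <- default_cells(table, range, bin_width, court)
  if (nrow(cells) == 0) stopf("empty range")
  st <- player_cell_stats(table, cells, court)
  if (is.null(players)) {
    ok <- tapply(st$n_make > 0 & st$n - st$n_make > 0, st$player_key, all)
    players <- names(ok)[ok]
  }
  st$pct <- ifelse(st$n > 0, st$n_make / st$n, NA)
  ag <- aggregate_cells(st, players, "pct")
  out <- data.frame(ag[c("lo", "hi", "point_class", "mean_dist")],
                    shooting_pct = ag$value, sem = ag$sem,
                    n_players = ag$n_players)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Return by distance
#'
#' Player-averaged return (points gained until opponent possession) per
#' distance cell.  Under the matching law the coarse 2pt and 3pt returns
#' would be equal; the distance-resolved profile shows whether they are
#' equal at a finer resolution.
#'
#' @inheritParams bin_learning_curve
#' @return Data frame (class `distance_curve`) with `return_mean`, `sem`,
#'   `n_players` per cell.
#' @export
return_vs_distance <- function(table, cells = NULL, bin_width = 2,
                               range = c(2, 30), court = court_spec(),
                               players = NULL) {
  if (anyNA(as.data.frame(table)$return_points))
    stopf("return_points missing; run compute_returns() first")
  if (is.null(cells))
    cells <- default_cells(table, range, bin_width, court)
  if (nrow(cells) == 0) stopf("empty range")
  st <- player_cell_stats(table, cells, court)
  if (is.null(players)) {
    ok <- tapply(st$n_make > 0 & st$n - st$n_make > 0, st$player_key, all)
    players <- names(ok)[ok]
  }
  ag <- aggregate_cells(st, players, "return_mean")
  out <- data.frame(ag[c("lo", "hi", "point_class", "mean_dist")],
                    return_mean = ag$value, sem = ag$sem,
                    n_players = ag$n_players)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Attach returns from possession context
#'
#' The return of a field goal is the number of points the shooter's team
#' gained from the attempt until the opponent regained possession: the
#' shot's own points if made, plus any follow-up points (e.g. a teammate
#' putback after a miss) before the change of possession.
#'
#' @param table a [shot_table()].
#' @param followup_points numeric vector, one value per event (in the
#'   table's sorted order): team points scored after the shot and before
#'   the opponent gained possession.
#' @return The table with `return_points` filled.
#' @export
compute_returns <- function(table, followup_points) {
  df <- as.data.frame(table)
  if (length(followup_points) != nrow(df))
    stopf("missing possession context: need one follow-up value per event")
  if (any(!is.finite(followup_points) | followup_points < 0))
    stopf("follow-up points must be non-negative")
  df$return_points <- ifelse(df$outcome == "S", df$point_value, 0) +
    followup_points
  shot_table(df, source = attr(table, "provenance")$source %||% "user",
             seed = attr(table, "provenance")$seed)
}

#' Matching-law analysis of 2pt/3pt allocation
#'
#' Per player: the fraction of attempts that are 3pt shots and the fraction
#' of income (total return) earned by them, plus the return per attempt of
#' each class.  The matching law predicts the two fractions are equal
#' (equivalently, equal return per attempt across classes).  The cohort is
#' summarized by the mean absolute deviation from the matching diagonal.
#' Players with no attempts of one class (or no income) are flagged and
#' excluded from cohort means.
#'
#' @param table a [shot_table()] with `return_points` available.
#' @return An object of class `matching_summary`: `records` (per player)
#'   and `summary` (cohort means and SEMs).
#' @export
matching_analysis <- function(table) {
  df <- as.data.frame(table)
  if (anyNA(df$return_points))
    stopf("return_points missing; run compute_returns() first")
  key <- player_key_of(df$player_id, df$season)
  recs <- lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    is3 <- sub$point_value == 3L
    att3 <- sum(is3); att2 <- sum(!is3)
    inc3 <- sum(sub$return_points[is3]); inc2 <- sum(sub$return_points[!is3])
    flagged <- att3 == 0 || att2 == 0 || (inc2 + inc3) == 0
    data.frame(player_key = k, n_attempts = att2 + att3,
               frac_3pt_attempts = att3 / (att2 + att3),
               frac_3pt_income = if (inc2 + inc3 > 0)
                 inc3 / (inc2 + inc3) else NA,
               return_2pt = if (att2 > 0) inc2 / att2 else NA,
               return_3pt = if (att3 > 0) inc3 / att3 else NA,
               flagged = flagged)
  })
  recs <- do.call(rbind, recs)
  ok <- recs[!recs$flagged, , drop = FALSE]
  if (nrow(ok) == 0) stopf("no player has attempts of both classes")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA
  summary <- list(
    n_players = nrow(ok),
    frac_3pt_attempts = mean(ok$frac_3pt_attempts),
    frac_3pt_income = mean(ok$frac_3pt_income),
    return_2pt = mean(ok$return_2pt), return_2pt_sem = sem(ok$return_2pt),
    return_3pt = mean(ok$return_3pt), return_3pt_sem = sem(ok$return_3pt),
    deviation_from_matching =
      mean(abs(ok$frac_3pt_attempts - ok$frac_3pt_income)))
  structure(list(records = recs, summary = summary),
            class = "matching_summary")
}

#' @export
print.matching_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Matching-law analysis (%d players)\n", s$n_players))
  cat(sprintf("  3pt attempt fraction %.3f, 3pt income fraction %.3f\n",
              s$frac_3pt_attempts, s$frac_3pt_income))
  cat(sprintf("  return/attempt: 2pt %.3f +- %.3f, 3pt %.3f +- %.3f\n",
              s$return_2pt, s$return_2pt_sem %||% NA,
              s$return_3pt, s$return_3pt_sem %||% NA))
  cat(sprintf("  mean |attempt frac - income frac| = %.4f\n",
              s$deviation_from_matching))
  invisible(x)
}
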