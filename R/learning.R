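#' Per-player conditional shot-location probabilities
#'
#' For a single player-season, estimates the a-priori probability `P_j` of
#' attempting a field goal from region `j` (from all of the player's
#' included attempts, first shots of games included) and the two
#' outcome-conditioned probabilities `P(j | S_i)` and `P(j | F_i)` that the
#' next attempt is from region `j` given the previous attempt was a made
#' (`S`) or missed (`F`) field goal from region `i`.  Conditioning uses only
#' within-game consecutive pairs; events outside every region are dropped
#' before pairing.
#'
#' @param shots a [shot_table()] restricted to one player-season.
#' @param map a `region_map`.
#' @param regroup `"fine"` estimates at region resolution; `"coarse"`
#'   relabels events to the three groups `THREE`, `LONG2`, `SHORT2` before
#'   estimation.
#' @param regions optional label set to estimate over (defaults to labels
#'   observed for this player; regions with zero attempts are excluded).
#' @return An object of class `conditional_table` with elements `prior`,
#'   `cond_make`, `cond_miss` (rows = antecedent region, `NA` where the
#'   antecedent count is zero), `ante_counts`, `pair_counts` and
#'   `prior_counts`.
#' @export
estimate_conditionals <- function(shots, map = region_map_nba(),
                                  regroup = c("fine", "coarse"),
                                  regions = NULL) {
  regroup <- match.arg(regroup)
  df <- as.data.frame(shots)
  if (nrow(df) == 0) stopf("empty shot table")
  keys <- unique(player_key_of(df$player_id, df$season))
  if (length(keys) != 1)
    stopf("expected one player-season, got %d", length(keys))

  lab <- map$assign(df$x_ft, df$y_ft)
  keep <- !is.na(lab)
  df <- df[keep, , drop = FALSE]
  lab <- lab[keep]
  if (nrow(df) == 0) stopf("no events fall inside the region map")

  if (regroup == "coarse") {
    lab <- region_group(lab, map)
    all_levels <- c("THREE", "LONG2", "SHORT2")
  } else {
    all_levels <- as.character(map$labels)
    lab <- as.character(lab)
  }
  levels_used <- if (is.null(regions)) {
    all_levels[all_levels %in% unique(lab)]
  } else {
    as.character(regions)
  }
  R <- length(levels_used)
  lab_i <- match(lab, levels_used)
  if (anyNA(lab_i)) stopf("events found outside the requested region set")

  prior_counts <- tabulate(lab_i, nbins = R)
  prior <- prior_counts / sum(prior_counts)
  names(prior) <- names(prior_counts) <- levels_used

  # within-game consecutive pairs on the included events
  same <- if (nrow(df) >= 2) df$game_id[-nrow(df)] == df$game_id[-1] else
    logical(0)
  a <- which(same); b <- a + 1L
  o <- ifelse(df$outcome[a] == "S", 1L, 2L)

  pair_counts <- array(0L, dim = c(R, 2L, R),
                       dimnames = list(levels_used, c("S", "F"), levels_used))
  if (length(a)) {
    flat <- lab_i[a] + R * (o - 1L) + 2L * R * (lab_i[b] - 1L)
    cnt <- tabulate(flat, nbins = 2L * R * R)
    pair_counts[] <- cnt
  }
  ante_counts <- apply(pair_counts, c(1, 2), sum)

  norm_rows <- function(o) {
    m <- matrix(pair_counts[, o, ], R, R,
                dimnames = list(levels_used, levels_used))
    n <- ante_counts[, o]
    out <- m / n
    out[n == 0, ] <- NA_real_
    out
  }
  cond_make <- norm_rows("S")
  cond_miss <- norm_rows("F")

  structure(list(
    player_key = keys, labels = levels_used,
    resolution = if (regroup == "coarse") "coarse3" else "fine",
    prior = prior, prior_counts = prior_counts,
    cond_make = cond_make, cond_miss = cond_miss,
    ante_counts = ante_counts, pair_counts = pair_counts,
    n_events = nrow(df), n_pairs = length(a)
  ), class = "conditional_table")
}

#' @export
print.conditional_table <- function(x, ...) {
  cat(sprintf("<conditional_table: %s, %d regions, %d events, %d pairs>\n",
              x$player_key, length(x$labels), x$n_events, x$n_pairs))
  invisible(x)
}

#' The learning matrix of a player
#'
#' The learning index from antecedent region `i` to region `j` is
#' \deqn{L_{ij} = (P(j | S_i) - P(j | F_i)) / P_j,}
#' the outcome-driven change in the probability of the next attempt coming
#' from region `j`, normalized by the prior.  A player whose behavior is
#' independent of outcomes has `L = 0`; a player who always repeats a made
#' shot's region and never a missed one has a positive diagonal and
#' non-positive off-diagonal entries.  Row `i` is valid only when the player
#' has at least one made and one missed antecedent from region `i`.
#'
#' @param ct a [estimate_conditionals()] result.
#' @return An object of class `learning_matrix` with `values` (matrix, `NA`
#'   rows where invalid), `valid` (logical per row) and `resolution`.
#' @export
learning_matrix <- function(ct) {
  stopifnot(inherits(ct, "conditional_table"))
  if (any(ct$prior == 0))
    stopf("undefined-column error: region(s) %s have prior 0; exclude upstream",
          paste(ct$labels[ct$prior == 0], collapse = ", "))
  values <- sweep(ct$cond_make - ct$cond_miss, 2, ct$prior, "/")
  valid <- ct$ante_counts[, "S"] > 0 & ct$ante_counts[, "F"] > 0
  values[!valid, ] <- NA_real_
  structure(list(values = values, valid = valid,
                 resolution = if (ct$resolution == "coarse3") "coarse3" else
                   "fine16",
                 labels = ct$labels, player_key = ct$player_key),
            class = "learning_matrix")
}

#' @export
print.learning_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<learning_matrix: %s, %s, %d/%d valid rows>\n",
              x$player_key, x$resolution, sum(x$valid), length(x$valid)))
  print(round(x$values, digits))
  invisible(x)
}

#' Coarse 3x3 learning matrix
#'
#' Re-estimates the learning index after regrouping events into the three
#' court groups (`THREE`, `LONG2`, `SHORT2`).  The index is re-estimated on
#' grouped events (not averaged from the 16x16 matrix) because the index is
#' nonlinear in the underlying probabilities.
#'
#' @param shots a [shot_table()] restricted to one player-season.
#' @param map a `region_map`.
#' @return A `learning_matrix` with resolution `"coarse3"`.
#' @export
coarse_matrix <- function(shots, map = region_map_nba()) {
  learning_matrix(estimate_conditionals(shots, map, regroup = "coarse"))
}

#' Player selection for region-resolution analyses
#'
#' A player-season is included when it has at least `min_per_region`
#' attempts from every region of the map and every row of its learning
#' matrix is well defined (at least one made and one missed antecedent pair
#' from every region).  Players failing either criterion are excluded from
#' the region-level analysis entirely.
#'
#' @param table a [shot_table()].
#' @param map a `region_map`.
#' @param min_per_region minimum attempts per region.
#' @return Character vector of `"player_id|season"` keys.
#' @export
select_players_fine <- function(table, map = region_map_nba(),
                                min_per_region = 10) {
  df <- as.data.frame(table)
  keys <- unique(player_key_of(df$player_id, df$season))
  keep <- vapply(keys, function(k) {
    sub <- df[player_key_of(df$player_id, df$season) == k, , drop = FALSE]
    lab <- map$assign(sub$x_ft, sub$y_ft)
    sub <- sub[!is.na(lab), , drop = FALSE]
    lab <- lab[!is.na(lab)]
    cnt <- table(factor(lab, levels = map$labels))
    if (any(cnt < min_per_region)) return(FALSE)
    ct <- estimate_conditionals(shot_subset(table, k), map,
                                regions = map$labels)
    all(ct$ante_counts > 0)
  }, logical(1))
  keys[keep]
}

# restrict a shot_table to one player key, preserving class/attributes
shot_subset <- function(table, key) {
  df <- as.data.frame(table)
  sub <- df[player_key_of(df$player_id, df$season) == key, , drop = FALSE]
  structure(sub, class = c("shot_table", "data.frame"),
            provenance = attr(table, "provenance"))
}

#' Equal-weight aggregation of learning matrices
#'
#' Averages per-player learning matrices entrywise with equal weight per
#' player, and reports the entrywise standard error of the mean (sample SD
#' over players divided by sqrt(n)).  The mean diagonal of the averaged
#' matrix summarizes the overall tendency to repeat made shots and avoid
#' missed ones; the standard deviation of its off-diagonal entries
#' summarizes the spatial heterogeneity of generalization.
#'
#' @param matrices list of `learning_matrix` objects of one resolution with
#'   all rows valid.
#' @return An object of class `aggregate_learning` with `mean`, `sem`,
#'   `n_players`, `diag_mean`, `offdiag_sd`.
#' @export
aggregate_learning <- function(matrices) {
  if (length(matrices) < 2) stopf("need at least 2 matrices to aggregate")
  res <- unique(vapply(matrices, function(m) m$resolution, character(1)))
  if (length(res) != 1) stopf("mixed resolutions: %s",
                              paste(res, collapse = ", "))
  if (!all(vapply(matrices, function(m) all(m$valid), logical(1))))
    stopf("all rows must be valid; exclude players with invalid rows")
  arr <- simplify2array(lapply(matrices, function(m) m$values))
  mean_m <- apply(arr, c(1, 2), mean)
  sem_m <- apply(arr, c(1, 2), stats::sd) / sqrt(length(matrices))
  off <- mean_m[row(mean_m) != col(mean_m)]
  structure(list(mean = mean_m, sem = sem_m, n_players = length(matrices),
                 resolution = res, labels = matrices[[1]]$labels,
                 diag_mean = mean(diag(mean_m)),
                 offdiag_sd = stats::sd(off)),
            class = "aggregate_learning")
}

#' @export
print.aggregate_learning <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<aggregate_learning: %s, %d players>\n  diag mean %.3f, off-diag SD %.3f\n",
    x$resolution, x$n_players, x$diag_mean, x$offdiag_sd))
  print(round(x$mean, digits))
  invisible(x)
}
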