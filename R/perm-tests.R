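#' Exact one-tailed binomial tail probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, computed
#' by direct summation of the exact terms.  Used as the sign test for the
#' number of positive diagonal entries of the cohort learning matrix.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return The exact tail probability.
#' @examples
#' binomial_tail(14, 16, 0.5)   # = 137/65536
#' @export
binomial_tail <- function(k, n, p0) {
  if (p0 < 0 || p0 > 1) stopf("p0 must be in [0, 1]")
  if (k < 0 || k > n) stopf("k must be in 0..n")
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

#' Surrogate shot table (permutation null)
#'
#' Builds the no-generalization null: independently for each player, the
#' prior region probabilities are estimated from the player's included
#' shots; every shot that follows another included shot in the same game
#' (a "consequent") then has its region replaced by an independent draw
#' from that prior.  Antecedent outcomes, per-game shot counts and the
#' pairing skeleton are preserved.  Redrawn shots are placed at the drawn
#' region's representative point and their `return_points` is cleared
#' (location-dependent).
#'
#' @param table a [shot_table()].
#' @param map a `region_map`.
#' @param seed RNG seed (fixed seed gives an identical surrogate).
#' @return A `shot_table`.
#' @export
surrogate_table <- function(table, map = region_map_nba(), seed = 1) {
  df <- as.data.frame(table)
  rep_pts <- region_representative(map)
  keys <- unique(player_key_of(df$player_id, df$season))
  for (p in seq_along(keys)) {
    set.seed(substream_seed(seed, p))
    rows <- which(player_key_of(df$player_id, df$season) == keys[p])
    lab <- map$assign(df$x_ft[rows], df$y_ft[rows])
    inc <- rows[!is.na(lab)]
    lab <- lab[!is.na(lab)]
    if (length(inc) < 2) next
    prior <- tabulate(match(lab, map$labels), length(map$labels))
    if (sum(prior) == 0) stopf("player %s has an undefined prior", keys[p])
    prior <- prior / sum(prior)
    cons <- inc[-1][df$game_id[inc[-1]] == df$game_id[inc[-length(inc)]]]
    if (!length(cons)) next
    new_lab <- map$labels[
      findInterval(stats::runif(length(cons)), cumsum(prior)) + 1L]
    ri <- match(new_lab, rep_pts$label)
    df$x_ft[cons] <- rep_pts$x[ri]
    df$y_ft[cons] <- rep_pts$y[ri]
    df$point_value[cons] <- ifelse(region_group(new_lab, map) == "THREE",
                                   3L, 2L)
    df$return_points[cons] <- NA_real_
  }
  shot_table(df, source = "surrogate",
             seed = seed, court = map$court)
}

new_perm_result <- function(observed, surrogate, n_rep, seed, statistic) {
  structure(list(observed = observed, surrogate = surrogate,
                 p_value = mean(surrogate > observed),
                 n_rep = n_rep, seed = seed, statistic = statistic),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  p_txt <- if (x$p_value == 0) sprintf("p < %g", 1 / x$n_rep) else
    sprintf("p = %g", x$p_value)
  cat(sprintf("Monte-Carlo permutation test: %s\n", x$statistic))
  cat(sprintf("  observed %.4f, %d surrogates, %s\n",
              x$observed, x$n_rep, p_txt))
  invisible(x)
}

#' Permutation test of off-diagonal heterogeneity
#'
#' Tests whether the standard deviation of the off-diagonal entries of the
#' cohort mean learning matrix exceeds what random region transitions
#' produce.  For each repetition, every player's consequent regions are
#' redrawn from that player's prior (with the original antecedents and
#' their outcomes, and the player's original prior as the normalizer), the
#' cohort matrix is recomputed and its off-diagonal SD recorded.  The
#' p-value is the fraction of repetitions whose surrogate statistic
#' strictly exceeds the observed one; `p = 0` is reportable as
#' `p < 1/n_rep`.
#'
#' Surrogate pair counts are drawn directly from the multinomial
#' distribution implied by independent prior draws, which is exactly
#' equivalent in distribution to redrawing each consequent shot.
#'
#' @param table a [shot_table()].
#' @param map a `region_map`.
#' @param n_rep number of Monte-Carlo repetitions.
#' @param seed master seed (per-player substreams).
#' @param min_per_region selection threshold (see [select_players_fine()]).
#' @return A `perm_test` object.
#' @export
perm_test_offdiag_sd <- function(table, map = region_map_nba(),
                                 n_rep = 10000, seed = 1,
                                 min_per_region = 10) {
  if (n_rep < 1) stopf("n_rep must be >= 1")
  keys <- select_players_fine(table, map, min_per_region)
  if (length(keys) < 2) stopf("fewer than 2 players pass selection")
  R <- length(map$labels)
  cts <- lapply(keys, function(k)
    estimate_conditionals(shot_subset(table, k), map, regions = map$labels))
  mats <- lapply(cts, learning_matrix)
  observed <- aggregate_learning(mats)$offdiag_sd

  acc <- array(0, dim = c(R, R, n_rep))
  for (p in seq_along(cts)) {
    set.seed(substream_seed(seed, p))
    ct <- cts[[p]]
    for (i in seq_len(R)) {
      nS <- ct$ante_counts[i, "S"]; nF <- ct$ante_counts[i, "F"]
      cS <- stats::rmultinom(n_rep, nS, ct$prior) / nS
      cF <- stats::rmultinom(n_rep, nF, ct$prior) / nF
      acc[i, , ] <- acc[i, , ] + (cS - cF) / ct$prior
    }
  }
  lbar <- matrix(acc, R * R, n_rep) / length(cts)
  off <- lbar[as.vector(row(diag(R)) != col(diag(R))), , drop = FALSE]
  n_off <- nrow(off)
  surr <- sqrt((colSums(off^2) - colSums(off)^2 / n_off) / (n_off - 1))
  new_perm_result(observed, surr, n_rep, seed, "offdiag_sd")
}

#' Distance bin descriptor
#'
#' @param lo,hi half-open distance band `[lo, hi)`, feet.
#' @param point_class 2 or 3.
#' @return One-row data frame (`lo`, `hi`, `point_class`).
#' @export
distance_bin <- function(lo, hi, point_class) {
  stopifnot(lo < hi, point_class %in% c(2, 3))
  data.frame(lo = lo, hi = hi, point_class = as.integer(point_class))
}

#' Permutation test between two distance bins
#'
#' Compares the player-averaged difference of a statistic between two
#' distance bins (typically the 2pt and 3pt bins straddling the
#' three-point line).  `statistic = "learning_diff"` uses the difference
#' between the conditional probabilities of a 3pt follow-up after a make
#' vs after a miss; its surrogate redraws, per player and bin, the 3pt
#' indicators of the consequent shots from the bin's pooled (outcome-free)
#' prior.  `statistic = "shooting_pct"` uses the shooting percentage; its
#' surrogate redraws outcomes from the player's percentage pooled across
#' the two bins.  Players need at least one made and one missed attempt in
#' each bin (and, for the learning statistic, at least one made and one
#' missed antecedent pair per bin).
#'
#' @param table a [shot_table()].
#' @param bin_a,bin_b [distance_bin()] descriptors.
#' @param statistic `"learning_diff"` or `"shooting_pct"`.
#' @param n_rep repetitions.
#' @param seed RNG seed.
#' @param court a [court_spec()].
#' @return A `perm_test` with an extra `n_players` element.
#' @export
perm_test_bin_difference <- function(table, bin_a, bin_b,
                                     statistic = c("learning_diff",
                                                   "shooting_pct"),
                                     n_rep = 10000, seed = 1,
                                     court = court_spec()) {
  statistic <- match.arg(statistic)
  if (n_rep < 1) stopf("n_rep must be >= 1")
  df <- as.data.frame(table)
  d <- shot_distance(df$x_ft, df$y_ft, court)
  in_bin <- function(bin) d >= bin$lo & d < bin$hi &
    df$point_value == bin$point_class
  ba <- in_bin(bin_a); bb <- in_bin(bin_b)
  if (!any(ba) || !any(bb)) stopf("empty bin")
  pr <- consecutive_pairs(table)
  cons3 <- df$point_value[pr$cons] == 3L
  made <- df$outcome[pr$ante] == "S"
  key <- player_key_of(df$player_id, df$season)

  per_player <- lapply(unique(key), function(k) {
    mine <- key[pr$ante] == k
    rows <- key == k
    stat_bin <- function(sel_events) {
      sel <- mine & sel_events[pr$ante]
      list(nS = sum(sel & made), kS = sum(sel & made & cons3),
           nF = sum(sel & !made), kF = sum(sel & !made & cons3),
           att = sum(rows & sel_events),
           mk = sum(rows & sel_events & df$outcome == "S"))
    }
    list(a = stat_bin(ba), b = stat_bin(bb))
  })

  if (statistic == "learning_diff") {
    ok <- vapply(per_player, function(s)
      s$a$nS > 0 && s$a$nF > 0 && s$b$nS > 0 && s$b$nF > 0 &&
        s$a$mk > 0 && s$a$att > s$a$mk && s$b$mk > 0 && s$b$att > s$b$mk,
      logical(1))
  } else {
    ok <- vapply(per_player, function(s)
      s$a$mk > 0 && s$a$att > s$a$mk && s$b$mk > 0 && s$b$att > s$b$mk,
      logical(1))
  }
  per_player <- per_player[ok]
  if (length(per_player) < 2) stopf("fewer than 2 players have both bins")

  obs_p <- vapply(per_player, function(s) {
    if (statistic == "learning_diff")
      (s$a$kS / s$a$nS - s$a$kF / s$a$nF) -
        (s$b$kS / s$b$nS - s$b$kF / s$b$nF)
    else s$a$mk / s$a$att - s$b$mk / s$b$att
  }, numeric(1))
  observed <- mean(obs_p)

  set.seed(substream_seed(seed, 0))
  surr <- numeric(n_rep)
  for (s in per_player) {
    if (statistic == "learning_diff") {
      pa <- (s$a$kS + s$a$kF) / (s$a$nS + s$a$nF)
      pb <- (s$b$kS + s$b$kF) / (s$b$nS + s$b$nF)
      rep_stat <- (stats::rbinom(n_rep, s$a$nS, pa) / s$a$nS -
                     stats::rbinom(n_rep, s$a$nF, pa) / s$a$nF) -
        (stats::rbinom(n_rep, s$b$nS, pb) / s$b$nS -
           stats::rbinom(n_rep, s$b$nF, pb) / s$b$nF)
    } else {
      p0 <- (s$a$mk + s$b$mk) / (s$a$att + s$b$att)
      rep_stat <- stats::rbinom(n_rep, s$a$att, p0) / s$a$att -
        stats::rbinom(n_rep, s$b$att, p0) / s$b$att
    }
    surr <- surr + rep_stat
  }
  surr <- surr / length(per_player)
  out <- new_perm_result(observed, surr, n_rep, seed,
                         paste0("bin_difference_", statistic))
  out$n_players <- length(per_player)
  out
}
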