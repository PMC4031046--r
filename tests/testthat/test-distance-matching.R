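test_that("bins are half-open 2-ft intervals and averages are exact", {
  b <- make_bins(c(2, 30), 2)
  expect_equal(b$lo, seq(2, 28, 2))
  expect_true(all(b$hi - b$lo == 2))
  expect_error(make_bins(c(5, 5)), "empty range")

  # single cell with shots at 22.1 and 23.9 ft -> mean distance 23.0
  rows <- list(
    data.frame(player_id = "p", season = "s1", game_id = "g1",
               order_in_game = 1:3,
               x_ft = c(22.1, 23.9, 0), y_ft = 5.25,
               outcome = c("S", "F", "S"), point_value = c(3L, 3L, 2L),
               return_points = NA_real_))
  tab <- shot_table(do.call(rbind, rows))
  crv <- shooting_pct_curve(tab, cells = distance_bin(22, 24, 3),
                            players = "p|s1")
  expect_equal(crv$mean_dist, 23.0)
  expect_equal(crv$shooting_pct, 0.5)
})

test_that("bin selection needs one make and one miss per cell", {
  mk <- function(id, out2) {
    data.frame(player_id = id, season = "s1", game_id = "g1",
               order_in_game = 1:4, x_ft = 0,
               y_ft = 5.25 + c(5, 5, 25, 25),
               outcome = c("S", "F", out2, "F"),
               point_value = c(2L, 2L, 3L, 3L), return_points = NA_real_)
  }
  tab <- shot_table(rbind(mk("both", "S"), mk("nomake3", "F")))
  cells <- rbind(distance_bin(4, 6, 2), distance_bin(24, 26, 3))
  keys <- select_players_bins(tab, cells)
  expect_true("both|s1" %in% keys)
  expect_false("nomake3|s1" %in% keys)
  # vacuous criterion: empty cell set includes everyone
  expect_setequal(select_players_bins(tab, cells[0, ]),
                  c("both|s1", "nomake3|s1"))
})

test_that("bin learning curve equals a brute-force pair count", {
  set.seed(10)
  map <- region_map_nba()
  for (seed in c(3, 14)) {
    tb <- random_table(seed, n_players = 3, max_games = 6, max_shots = 8)
    df <- as.data.frame(tb)
    d <- shot_distance(df$x_ft, df$y_ft)
    cells <- distance_bin(16, 26, 2)
    crv <- bin_learning_curve(tb, cells = cells,
                              players = unique(paste(df$player_id,
                                                     df$season,
                                                     sep = "|")))
    # brute force for every player, then equal-weight average
    pr <- consecutive_pairs(tb)
    vals <- sapply(unique(df$player_id), function(p) {
      sel <- df$player_id[pr$ante] == p &
        d[pr$ante] >= 16 & d[pr$ante] < 26 &
        df$point_value[pr$ante] == 2L
      s <- sel & df$outcome[pr$ante] == "S"
      f <- sel & df$outcome[pr$ante] == "F"
      if (!any(s) || !any(f)) return(NA_real_)
      mean(df$point_value[pr$cons[s]] == 3L) -
        mean(df$point_value[pr$cons[f]] == 3L)
    })
    if (all(is.na(vals))) {
      expect_equal(crv$n_players, 0)
    } else {
      expect_equal(crv$learning_diff, mean(vals, na.rm = TRUE))
      expect_equal(crv$n_players, sum(!is.na(vals)))
    }
  }
})

test_that("returns follow the possession walk", {
  tab <- toy_table(list(toy_row(ord = 1, region = 1, outcome = "S"),
                        toy_row(ord = 2, region = 16, outcome = "F"),
                        toy_row(ord = 3, region = 8, outcome = "F")))
  # made 3pt, opponent ball -> 3; missed + putback 2 -> 2; missed -> 0
  out <- compute_returns(tab, c(0, 2, 0))
  expect_equal(out$return_points, c(3, 2, 0))
  expect_error(compute_returns(tab, c(0, 2)), "possession context")
  expect_error(compute_returns(tab, c(0, -1, 0)), "non-negative")
})

test_that("matching identities hold exactly", {
  # constructed equality: 40/100 attempts are 3pt, 3pt income 60/150
  rows <- list()
  g <- 0
  add <- function(n, pv, ret_each) {
    for (i in seq_len(n)) {
      g <<- g + 1
      rows[[length(rows) + 1]] <<- data.frame(
        player_id = "p", season = "s1", game_id = paste0("g", g),
        order_in_game = 1L, x_ft = 0,
        y_ft = if (pv == 3) 31 else 10.25,
        outcome = if (ret_each >= pv) "S" else "F",
        point_value = pv,
        return_points = ret_each)
    }
  }
  add(20, 3L, 3); add(20, 3L, 0)           # 3pt income 60 of 40 attempts
  add(30, 2L, 2); add(15, 2L, 2); add(15, 2L, 0)  # 2pt income 90 of 60
  tab <- shot_table(do.call(rbind, rows))
  mt <- matching_analysis(tab)
  rec <- mt$records
  expect_equal(rec$frac_3pt_attempts, 0.4)
  expect_equal(rec$frac_3pt_income, 0.4)   # 60 / 150: on the matching line
  expect_equal(rec$return_2pt, 1.5)
  expect_equal(rec$return_3pt, 1.5)
  expect_equal(mt$summary$deviation_from_matching, 0)

  # income identity: fraction of income = sum of 3pt returns / all returns
  df <- as.data.frame(tab)
  expect_equal(rec$frac_3pt_income,
               sum(df$return_points[df$point_value == 3]) /
                 sum(df$return_points))
})

test_that("equal per-attempt returns imply matching algebraically", {
  set.seed(4)
  cfg <- synthetic_config(n_players = 3, n_games = 40, shots_per_game = 10,
                          seed = 77, putback_prob = 0)
  tab <- generate_cohort(cfg)
  mt <- matching_analysis(tab)
  rec <- mt$records
  # identity check: frac_income = fa*r3 / (fa*r3 + (1-fa)*r2)
  expect_equal(rec$frac_3pt_income,
               rec$frac_3pt_attempts * rec$return_3pt /
                 (rec$frac_3pt_attempts * rec$return_3pt +
                    (1 - rec$frac_3pt_attempts) * rec$return_2pt))
})

test_that("return versus distance matches the generative closed form", {
  # constant make probability per region and no putbacks:
  # expected return is pv * q in every populated cell
  map <- cal_map()
  cfg <- synthetic_config(map = map, make_prob = rep(0.4, 4),
                          putback_prob = 0, n_players = 4, n_games = 150,
                          shots_per_game = 10, seed = 55)
  tab <- generate_cohort(cfg)
  rvd <- return_vs_distance(tab, range = c(0, 28),
                            players = unique(paste(tab$player_id,
                                                   tab$season, sep = "|")))
  pop <- rvd[rvd$n_players == 4 & !is.na(rvd$return_mean), ]
  expect_gt(nrow(pop), 5)
  expected <- ifelse(pop$point_class == 3, 3, 2) * 0.4
  expect_true(all(abs(pop$return_mean - expected) < 6 * pop$sem + 0.05))

  # all-miss cohort: returns are zero everywhere
  cfg0 <- synthetic_config(map = map, make_prob = rep(0, 4),
                           putback_prob = 0, n_players = 2, n_games = 30,
                           shots_per_game = 6, seed = 56)
  tab0 <- generate_cohort(cfg0)
  rvd0 <- return_vs_distance(tab0, range = c(0, 28),
                             players = unique(paste(tab0$player_id,
                                                    tab0$season,
                                                    sep = "|")))
  expect_gt(sum(!is.na(rvd0$return_mean)), 0)
  expect_true(all(rvd0$return_mean[!is.na(rvd0$return_mean)] == 0))
})
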