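test_that("conditional probabilities match hand counts on a toy game", {
  # one game: (region 1, S), (region 1, F), (region 2, S)
  tab <- toy_table(list(toy_row(ord = 1, region = 1, outcome = "S"),
                        toy_row(ord = 2, region = 1, outcome = "F"),
                        toy_row(ord = 3, region = 2, outcome = "S")))
  ct <- estimate_conditionals(tab)
  expect_equal(unname(ct$prior), c(2 / 3, 1 / 3))
  expect_equal(ct$cond_make["1", "1"], 1)
  expect_equal(ct$cond_miss["1", "2"], 1)
  expect_true(all(is.na(ct$cond_make["2", ])))  # region 2 never antecedent

  lm <- learning_matrix(ct)
  expect_equal(lm$values["1", "1"], (1 - 0) / (2 / 3))  # = 1.5
  expect_equal(lm$values["1", "2"], (0 - 1) / (1 / 3))  # = -3
  expect_false(lm$valid["2"])
  expect_true(all(is.na(lm$values["2", ])))
})

test_that("pairs never cross games: two 1-shot games give no rows", {
  tab <- toy_table(list(toy_row(game = "g1", ord = 1, region = 1,
                                outcome = "S"),
                        toy_row(game = "g2", ord = 1, region = 2,
                                outcome = "F")))
  ct <- estimate_conditionals(tab)
  expect_equal(ct$n_pairs, 0)
  expect_true(all(is.na(ct$cond_make)))
  expect_true(all(is.na(ct$cond_miss)))
})

test_that("extreme repeat/avoid player has the forced learning matrix", {
  # 4 abstract regions, uniform prior; after S always repeat, after F
  # never repeat (uniform over the other 3):
  # L_ii = (1-0)/0.25 = 4, L_ij = (0-1/3)/0.25 = -4/3
  cm <- diag(4)
  cf <- matrix(1 / 3, 4, 4); diag(cf) <- 0
  ct <- structure(list(player_key = "x", labels = as.character(1:4),
                       resolution = "fine",
                       prior = setNames(rep(0.25, 4), 1:4),
                       cond_make = cm, cond_miss = cf,
                       ante_counts = matrix(5, 4, 2,
                                            dimnames = list(1:4,
                                                            c("S", "F")))),
                  class = "conditional_table")
  lm <- learning_matrix(ct)
  expect_equal(diag(lm$values), rep(4, 4))
  expect_equal(lm$values[row(lm$values) != col(lm$values)],
               rep(-4 / 3, 12))
})

test_that("a memoryless player yields a zero learning matrix", {
  ct <- structure(list(player_key = "x", labels = c("a", "b"),
                       resolution = "fine",
                       prior = c(a = 0.3, b = 0.7),
                       cond_make = matrix(c(0.3, 0.3, 0.7, 0.7), 2),
                       cond_miss = matrix(c(0.3, 0.3, 0.7, 0.7), 2),
                       ante_counts = matrix(1, 2, 2,
                                            dimnames = list(NULL,
                                                            c("S", "F")))),
                  class = "conditional_table")
  expect_true(all(learning_matrix(ct)$values == 0))
})

test_that("estimator agrees with brute-force pair enumeration", {
  map <- region_map_nba()
  for (seed in 1:40) {
    tb <- random_table(seed, n_players = 1, max_games = 5, max_shots = 8)
    bf <- brute_learning(tb, map)
    ct <- estimate_conditionals(tb, map)
    expect_equal(unname(ct$prior), unname(bf$prior))
    expect_equal(unname(ct$cond_make), unname(bf$cond_make))
    expect_equal(unname(ct$cond_miss), unname(bf$cond_miss))
    expect_equal(unname(learning_matrix(ct)$values), unname(bf$L))
  }
})

test_that("coarse matrix is re-estimated on grouped events", {
  # one pair (THREE,S)->THREE and one (THREE,F)->SHORT2 in separate games
  tab <- toy_table(list(
    toy_row(game = "g1", ord = 1, region = 1, outcome = "S"),
    toy_row(game = "g1", ord = 2, region = 7, outcome = "F"),
    toy_row(game = "g2", ord = 1, region = 1, outcome = "F"),
    toy_row(game = "g2", ord = 2, region = 16, outcome = "S")))
  cm <- coarse_matrix(tab)
  p_three <- 3 / 4
  expect_equal(cm$values["THREE", "THREE"], (1 - 0) / p_three)
  expect_equal(cm$resolution, "coarse3")
})

test_that("player selection enforces counts and row validity", {
  map <- cal_map()
  mk_player <- function(id, n_per_region, miss_region = NULL) {
    rows <- list()
    g <- 0
    for (r in 1:4) {
      n <- n_per_region[r]
      for (i in seq_len(ceiling(n / 2))) {
        g <- g + 1
        o1 <- if (!is.null(miss_region) && r == miss_region) "F" else
          c("S", "F")[1 + (i %% 2)]
        rows[[length(rows) + 1]] <- data.frame(
          player_id = id, season = "s1", game_id = paste0("g", g),
          order_in_game = 1:2, x_ft = 0,
          y_ft = 5.25 + c(2, 12, 18, 25)[r] - c(0, 0),
          outcome = c(o1, "S"), point_value = c(2L, 2L, 2L, 3L)[r],
          return_points = NA_real_)
      }
    }
    do.call(rbind, rows)
  }
  full <- shot_table(rbind(mk_player("rich", rep(12, 4)),
                           mk_player("poor", c(12, 12, 12, 8)),
                           mk_player("nomake", rep(12, 4),
                                     miss_region = 2)))
  keys <- select_players_fine(full, map, min_per_region = 10)
  expect_true("rich|s1" %in% keys)
  expect_false("poor|s1" %in% keys)      # 8 < 10 in one region
  expect_false("nomake|s1" %in% keys)    # no made antecedent from region 2
})

test_that("aggregation is an equal-weight mean with SEM", {
  mk <- function(v) structure(list(values = v,
                                   valid = rep(TRUE, nrow(v)),
                                   resolution = "fine16",
                                   labels = as.character(seq_len(nrow(v))),
                                   player_key = "x"),
                              class = "learning_matrix")
  m <- matrix(c(1, -1, 0.5, 2), 2)
  agg <- aggregate_learning(list(mk(m), mk(m)))
  expect_equal(agg$mean, m)
  expect_true(all(agg$sem == 0))
  agg2 <- aggregate_learning(list(mk(0 * m), mk(2 * m)))
  expect_equal(agg2$mean, m)
  expect_equal(agg2$diag_mean, mean(diag(m)))
  expect_equal(agg2$offdiag_sd, sd(m[row(m) != col(m)]))
  expect_error(aggregate_learning(list(mk(m))), "at least 2")

  # equal weighting: duplicating player A's games does not change player
  # B's contribution: mean stays the average of per-player matrices
  agg3 <- aggregate_learning(list(mk(m), mk(3 * m)))
  expect_equal(agg3$mean, 2 * m)
})
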