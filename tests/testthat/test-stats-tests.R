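test_that("binomial tail is exact", {
  expect_equal(binomial_tail(0, 16, 0.5), 1)
  expect_equal(binomial_tail(16, 16, 0.5), 2^-16)
  expect_equal(binomial_tail(14, 16, 0.5), 137 / 65536)
  expect_error(binomial_tail(3, 2, 0.5), "k must be")
  expect_error(binomial_tail(1, 2, 1.5), "p0 must be")

  # disjoint tails sum to one; cross-check against stats::pbinom
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:40, 1); k <- sample(0:n, 1); p <- runif(1)
    expect_equal(binomial_tail(k, n, p) +
                   (if (k > 0) sum(dbinom(0:(k - 1), n, p)) else 0), 1,
                 tolerance = 1e-12)
    expect_equal(binomial_tail(k, n, p),
                 pbinom(k - 1, n, p, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("surrogate tables preserve structure and destroy learning", {
  map <- cal_map()
  cfg <- synthetic_config(map = map, learning_rate = 1,
                          kernel = diag(4), n_players = 6, n_games = 50,
                          shots_per_game = 10, seed = 31)
  tab <- generate_cohort(cfg)

  s1 <- surrogate_table(tab, map, seed = 5)
  s2 <- surrogate_table(tab, map, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2)) # determinism
  s3 <- surrogate_table(tab, map, seed = 6)
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))

  # per-game shot counts and antecedent outcomes preserved
  counts <- function(t) table(paste(t$player_id, t$game_id))
  expect_equal(counts(s1), counts(tab))
  expect_equal(s1$outcome, tab$outcome)

  # strong win-stay learner: surrogate cohort matrix is ~0
  fit_obs <- fit_learning(tab, map, min_per_region = 5)
  fit_sur <- fit_learning(s1, map, min_per_region = 5)
  expect_gt(fit_obs$aggregate$diag_mean, 0.5)
  expect_lt(abs(fit_sur$aggregate$diag_mean),
            5 * mean(diag(fit_sur$aggregate$sem)))
})

test_that("a degenerate prior forces all surrogate consequents there", {
  # player shoots 95% from region 1; surrogate consequents follow the prior
  map <- cal_map()
  rows <- lapply(1:30, function(g) data.frame(
    player_id = "p", season = "s1", game_id = sprintf("g%02d", g),
    order_in_game = 1:2, x_ft = 0, y_ft = 5.25 + c(2, 2),
    outcome = c("S", "F"), point_value = 2L, return_points = NA_real_))
  tab <- shot_table(do.call(rbind, rows))
  s <- surrogate_table(tab, map, seed = 1)
  lab <- assign_region(s$x_ft, s$y_ft, map)
  expect_true(all(lab == 1L))
})

test_that("permutation p-values follow the strict-exceedance convention", {
  map <- cal_map()
  cfg <- synthetic_config(map = map, n_players = 5, n_games = 30,
                          shots_per_game = 8, seed = 17, learning_rate = 0)
  tab <- generate_cohort(cfg)
  pt <- perm_test_offdiag_sd(tab, map, n_rep = 50, seed = 2,
                             min_per_region = 5)
  expect_equal(pt$p_value, mean(pt$surrogate > pt$observed))
  expect_equal(pt$n_rep, 50)
  expect_true(pt$p_value >= 0 && pt$p_value <= 1)
  p1 <- perm_test_offdiag_sd(tab, map, n_rep = 1, seed = 2,
                             min_per_region = 5)
  expect_true(p1$p_value %in% c(0, 1))
  expect_error(perm_test_offdiag_sd(tab, map, n_rep = 0, seed = 1), "n_rep")
})

test_that("multinomial fast path matches an event-level surrogate oracle", {
  # independent null-route: redraw each consequent region per pair from the
  # player prior and recompute the statistic via brute counting
  map <- cal_map()
  cfg <- synthetic_config(map = map, n_players = 4, n_games = 40,
                          shots_per_game = 8, seed = 23, learning_rate = 0)
  tab <- generate_cohort(cfg)
  pt <- perm_test_offdiag_sd(tab, map, n_rep = 300, seed = 3,
                             min_per_region = 5)

  df <- as.data.frame(tab)
  key <- paste(df$player_id, df$season, sep = "|")
  pr <- consecutive_pairs(tab)
  lab <- assign_region(df$x_ft, df$y_ft, map)
  set.seed(777)
  oracle_stat <- replicate(300, {
    mats <- lapply(unique(key), function(k) {
      mine <- which(key[pr$ante] == k)
      prior <- tabulate(lab[key == k], 4) / sum(key == k)
      ante_r <- lab[pr$ante[mine]]
      ante_o <- df$outcome[pr$ante[mine]]
      cons_r <- sample(4, length(mine), TRUE, prob = prior)
      L <- matrix(NA_real_, 4, 4)
      for (i in 1:4) {
        cs <- cons_r[ante_r == i & ante_o == "S"]
        cf <- cons_r[ante_r == i & ante_o == "F"]
        L[i, ] <- (tabulate(cs, 4) / length(cs) -
                     tabulate(cf, 4) / length(cf)) / prior
      }
      L
    })
    m <- Reduce(`+`, mats) / length(mats)
    sd(m[row(m) != col(m)])
  })
  ks <- suppressWarnings(stats::ks.test(pt$surrogate, oracle_stat))
  expect_gt(ks$p.value, 0.01)
})

test_that("bin-difference test distinguishes planted from null effects", {
  b2 <- distance_bin(22, 24, 2)
  b3 <- distance_bin(22, 24, 3)

  # planted categorical kernel: learning difference is highly significant
  tab <- generate_cohort(planted_scenario(n_players = 60, n_games = 60,
                                          seed = 91))
  pl <- perm_test_bin_difference(tab, b3, b2, "learning_diff",
                                 n_rep = 500, seed = 4)
  expect_lt(pl$p_value, 0.01)
  expect_gt(pl$observed, 0)

  # equal make probabilities at equal distance: percentage difference is
  # within noise (same cohort, difficulty is continuous in distance)
  ps <- perm_test_bin_difference(tab, b3, b2, "shooting_pct",
                                 n_rep = 500, seed = 4)
  expect_gt(ps$p_value, 0.05)

  # memoryless cohort: learning statistic p is not extreme
  tab0 <- generate_cohort(planted_scenario(n_players = 40, n_games = 60,
                                           seed = 92))
  cfg0 <- synthetic_config(n_players = 40, n_games = 60,
                           shots_per_game = 15, learning_rate = 0,
                           seed = 93)
  p0 <- perm_test_bin_difference(generate_cohort(cfg0), b3, b2,
                                 "learning_diff", n_rep = 500, seed = 4)
  expect_gt(p0$p_value, 0.01)
  expect_error(perm_test_bin_difference(tab, distance_bin(40, 42, 3), b2,
                                        "learning_diff"), "empty bin")
})
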