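# shared fixtures: tiny hand-built tables and reduced study designs

# minimal canonical data frame; coordinates place each "region code" at a
# distinct location of the default map (1 = corner three, 2 = corner long-2,
# 16 = at the rim)
toy_coords <- function(region) {
  pts <- list(`1` = c(23.1, 8.2), `2` = c(18.5, 12), `16` = c(0, 5.25),
              `7` = c(0, 31), `8` = c(0, 25), `9` = c(0, 17))
  pts[[as.character(region)]]
}

toy_row <- function(player = "a", game = "g1", ord, region, outcome,
                    ret = NA) {
  xy <- toy_coords(region)
  data.frame(player_id = player, season = "s1", game_id = game,
             order_in_game = ord, x_ft = xy[1], y_ft = xy[2],
             outcome = outcome,
             point_value = classify_point_value(xy[1], xy[2]),
             return_points = ret)
}

toy_table <- function(rows) shot_table(do.call(rbind, rows))

# reduced 4-region abstract map used for fast calibration studies
cal_map <- function() {
  region_map_polar(1:4, c("SHORT2", "SHORT2", "LONG2", "THREE"),
                   a_lo = rep(0, 4), a_hi = rep(180, 4),
                   d_lo = c(0, 8, 16, 23.8), d_hi = c(8, 16, 22, 28))
}

# random valid shot tables for property tests (games of random length >= 1)
random_table <- function(seed, n_players = 2, max_games = 4,
                         max_shots = 6) {
  set.seed(seed)
  map <- region_map_nba()
  pl <- map$placement
  rows <- list()
  for (p in seq_len(n_players)) {
    for (g in seq_len(sample(max_games, 1))) {
      n <- sample(max_shots, 1)
      r <- sample(nrow(pl), n, replace = TRUE)
      d <- runif(n, pl$d_lo[r], pl$d_hi[r])
      a <- runif(n, pl$a_lo[r], pl$a_hi[r]) * pi / 180
      rows[[length(rows) + 1]] <- data.frame(
        player_id = paste0("p", p), season = "s1",
        game_id = paste0("g", g), order_in_game = seq_len(n),
        x_ft = d * cos(a), y_ft = 5.25 + d * sin(a),
        outcome = sample(c("S", "F"), n, replace = TRUE),
        point_value = ifelse(region_group(pl$label[r], map) == "THREE",
                             3L, 2L),
        return_points = NA_real_)
    }
  }
  shot_table(do.call(rbind, rows))
}

# brute-force learning-matrix computation, independent of the package
# estimator: explicit loops over events and pairs
brute_learning <- function(table, map) {
  df <- as.data.frame(table)
  lab <- assign_region(df$x_ft, df$y_ft, map)
  df <- df[!is.na(lab), ]; lab <- lab[!is.na(lab)]
  levs <- sort(unique(lab))
  R <- length(levs)
  prior <- sapply(levs, function(l) mean(lab == l))
  cm <- cf <- matrix(NA_real_, R, R)
  nS <- nF <- rep(0, R)
  pairs <- list()
  for (i in seq_len(nrow(df) - 1)) {
    if (df$game_id[i] == df$game_id[i + 1] &&
        df$player_id[i] == df$player_id[i + 1])
      pairs[[length(pairs) + 1]] <- c(i, i + 1)
  }
  for (i in seq_len(R)) {
    sel_S <- sel_F <- integer(0)
    for (pr in pairs) {
      if (lab[pr[1]] == levs[i]) {
        if (df$outcome[pr[1]] == "S") sel_S <- c(sel_S, pr[2])
        else sel_F <- c(sel_F, pr[2])
      }
    }
    nS[i] <- length(sel_S); nF[i] <- length(sel_F)
    if (nS[i] > 0) cm[i, ] <- sapply(levs, function(l)
      mean(lab[sel_S] == l))
    if (nF[i] > 0) cf[i, ] <- sapply(levs, function(l)
      mean(lab[sel_F] == l))
  }
  L <- sweep(cm - cf, 2, prior, "/")
  list(levels = levs, prior = prior, cond_make = cm, cond_miss = cf,
       L = L, nS = nS, nF = nF)
}

# independent brute-force Ward linkage: recomputes centroids from member
# lists at every step (no incremental state), exhaustive pair scan
brute_ward <- function(m, form = "sqrt") {
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  dist_ward <- function(A, B) {
    ca <- colMeans(m[A, , drop = FALSE]); cb <- colMeans(m[B, , drop = FALSE])
    w <- 2 * length(A) * length(B) / (length(A) + length(B))
    dd <- sqrt(sum((ca - cb)^2))
    if (form == "sqrt") sqrt(w) * dd else w * dd^2
  }
  while (length(clusters) > 1) {
    k <- length(clusters)
    dm <- matrix(Inf, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      dm[i, j] <- dist_ward(clusters[[i]], clusters[[j]])
    idx <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    heights <- c(heights, min(dm))
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[idx[1]]], clusters[[idx[2]]]))
    clusters[[idx[1]]] <- sort(c(clusters[[idx[1]]], clusters[[idx[2]]]))
    clusters[[idx[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# leaf membership sets per merge step of a ward_tree
tree_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    expand <- function(code) if (code < 0) -code else sets[[code]]
    sets[[s]] <- sort(c(expand(tree$merge[s, 1]), expand(tree$merge[s, 2])))
  }
  sets
}
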