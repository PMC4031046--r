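#' Configuration of the generative shot-sequence model
#'
#' A cohort of identical players shoots `n_games` games of
#' `shots_per_game` field goals each.  In `"one_step"` mode, the first shot
#' of a game is drawn from the base policy (region probabilities
#' proportional to `base_weights`); after a shot from region `i` with
#' outcome `o`, the next shot's region is drawn with probabilities
#' proportional to `w_j * exp(s * eta * K[i, j])` where `s = +1` after a
#' make and `-1` after a miss.  The policy then resets to the base weights
#' (one-step memory), so only the immediately preceding attempt conditions
#' behavior and the induced chain over (region, outcome) is exactly
#' solvable (see [oracle_statistics()]).  The multiplicative-exponential
#' update gives closed softmax conditionals; at small `eta` the learning
#' index is approximately `2*eta*(K_ij - sum_k P_k K_ik)`.
#'
#' Shot coordinates are drawn uniformly from the region's polar placement
#' rectangle, so the generated label always agrees with
#' [assign_region()].  The make probability is `make_prob(d)` evaluated at
#' the sampled distance (or a per-region constant).  Returns follow an
#' explicit possession model: a made shot returns its point value; a missed
#' shot yields a 2-point teammate putback with probability `putback_prob`
#' and 0 otherwise.
#'
#' `"melioration"` mode replaces the one-step kernel with a running
#' allocation between the 2pt and 3pt shot classes: per-class return
#' estimates are tracked (exponentially weighted) and the 3pt propensity
#' moves toward the class with the higher estimated return, while the make
#' probability diminishes with the running allocation frequency of the
#' class (`make_prob(d) * (1 - press_c * f_c)`).  Its fixed point is the
#' matching law: equal return per attempt across classes.
#'
#' @param map a `region_map` with placement rectangles.
#' @param base_weights positive base policy weights per region.  Defaults to
#'   the observed NBA share of attempts per region of the default 16-region
#'   partition.
#' @param make_prob function of distance (feet) returning a make
#'   probability, or a numeric vector per region.
#' @param learning_rate non-negative `eta`.
#' @param kernel generalization kernel `K` (regions x regions), or `NULL`
#'   for no transfer (`K = 0`).
#' @param n_players,n_games,shots_per_game cohort dimensions.
#' @param putback_prob probability a missed shot is followed by a 2-point
#'   teammate putback before the opponent gains possession.
#' @param mode `"one_step"` or `"melioration"`.
#' @param melioration parameters for melioration mode: `p3_init`, `lambda`
#'   (propensity step per unit return difference), `ema` (smoothing rate of
#'   the return/frequency trackers), `press3`, `press2` (diminishing-return
#'   pressures).
#' @param seed master seed; each player uses a derived substream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(map = region_map_nba(),
                             base_weights = NULL,
                             make_prob = linear_make_prob(),
                             learning_rate = 0.5,
                             kernel = NULL,
                             n_players = 100, n_games = 50,
                             shots_per_game = 20,
                             putback_prob = 0.15,
                             mode = c("one_step", "melioration"),
                             melioration = list(),
                             seed = 1) {
  mode <- match.arg(mode)
  R <- length(map$labels)
  if (is.null(base_weights)) {
    base_weights <- if (identical(map$kind, "nba"))
      nba_region_shares() else rep(1, R)
  }
  if (length(base_weights) != R || any(base_weights <= 0))
    stopf("base_weights must be %d positive values", R)
  if (is.null(kernel)) kernel <- matrix(0, R, R)
  kernel <- as.matrix(kernel)
  if (!all(dim(kernel) == c(R, R)) || any(!is.finite(kernel)))
    stopf("kernel must be a finite %dx%d matrix", R, R)
  if (learning_rate < 0) stopf("learning_rate must be non-negative")
  if (shots_per_game < 2) stopf("shots_per_game must be >= 2")
  if (is.numeric(make_prob)) {
    if (length(make_prob) != R || any(make_prob < 0 | make_prob > 1))
      stopf("make_prob vector must be %d probabilities", R)
  } else if (!is.function(make_prob)) {
    stopf("make_prob must be a function of distance or a vector")
  }
  if (putback_prob < 0 || putback_prob > 1)
    stopf("putback_prob must be a probability")
  mel <- utils::modifyList(list(p3_init = 0.5, lambda = 0.01, ema = 0.02,
                                press3 = 0.9, press2 = 0.3,
                                burn_in_games = 50),
                           melioration)
  structure(list(map = map, base_weights = base_weights,
                 make_prob = make_prob, learning_rate = learning_rate,
                 kernel = kernel, n_players = as.integer(n_players),
                 n_games = as.integer(n_games),
                 shots_per_game = as.integer(shots_per_game),
                 putback_prob = putback_prob, mode = mode,
                 melioration = mel, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config: %s, %d regions, %d players x %d games x %d shots, eta=%g, seed=%d>\n",
    x$mode, length(x$map$labels), x$n_players, x$n_games, x$shots_per_game,
    x$learning_rate, x$seed))
  invisible(x)
}

#' Observed NBA share of attempts per region of the default partition
#'
#' The published share of all field-goal attempts falling in each of the 16
#' regions of the default court partition (percent of attempts, regions
#' 1..16); used as the default base policy of the generator.
#'
#' @return Numeric vector of 16 shares summing to ~1.
#' @export
nba_region_shares <- function() {
  c(2.9, 5.6, 4.2, 5.7, 3.3, 3.3, 6.9, 5.5, 6.9, 3.8, 2.4, 4.1, 5.0, 4.0,
    2.4, 33.3) / 100
}

#' Kernel from a 3x3 group-level matrix
#'
#' Expands a group-level generalization matrix (rows/cols
#' `THREE, LONG2, SHORT2`) to the full region-level kernel
#' `K[i, j] = G[group(i), group(j)]`.
#'
#' @param map a `region_map`.
#' @param G 3x3 matrix with dimnames in `THREE, LONG2, SHORT2`.
#' @return Region-level kernel matrix.
#' @export
kernel_from_groups <- function(map, G) {
  g <- c("THREE", "LONG2", "SHORT2")
  G <- as.matrix(G)
  if (is.null(dimnames(G))) dimnames(G) <- list(g, g)
  gi <- match(map$groups, rownames(G))
  K <- G[gi, gi, drop = FALSE]
  dimnames(K) <- list(map$labels, map$labels)
  K
}

#' Group kernels: block-diagonal and planted-findings variants
#'
#' `group_kernel_blocks()` is the 3-block kernel (within-group transfer 1,
#' between-group 0) used for oracle-recovery and cluster-recovery studies.
#' `group_kernel_planted()` encodes the qualitative generalization pattern
#' of NBA cohorts: outcome of a 3pt attempt mostly transfers to other 3pt
#' attempts and suppresses short 2pt attempts; long-2pt outcomes transfer
#' to long-2pt (at the expense of short 2pt) with a small positive spillover
#' to 3pt; short-2pt outcomes have only weak effects.
#'
#' @return 3x3 matrix with dimnames `THREE, LONG2, SHORT2`.
#' @export
group_kernel_blocks <- function() {
  g <- c("THREE", "LONG2", "SHORT2")
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, 0, 1), 3, 3, byrow = TRUE, dimnames = list(g, g))
}

#' @rdname group_kernel_blocks
#' @export
group_kernel_planted <- function() {
  g <- c("THREE", "LONG2", "SHORT2")
  matrix(c(1.0, 0.0, -0.3,
           0.2, 0.8, -0.4,
           0.0, 0.0, 0.1), 3, 3, byrow = TRUE, dimnames = list(g, g))
}

#' The planted generalization scenario
#'
#' A documented configuration whose exact (oracle) coarse learning matrix
#' reproduces the qualitative sign pattern of the NBA findings by
#' construction: the (THREE, THREE) entry is by far the largest, the
#' (LONG2, LONG2) entry is positive with a negative (LONG2, SHORT2) entry,
#' short-2pt effects are small, the 2pt/3pt learning kernel is categorical
#' while the make probability is a continuous function of distance (equal
#' for both classes at equal distance).
#'
#' @param n_players,n_games,shots_per_game,seed cohort dimensions and seed.
#' @return A [synthetic_config()].
#' @export
planted_scenario <- function(n_players = 100, n_games = 80,
                             shots_per_game = 15, seed = 1) {
  map <- region_map_nba()
  synthetic_config(map = map,
                   kernel = kernel_from_groups(map, group_kernel_planted()),
                   learning_rate = 0.5,
                   n_players = n_players, n_games = n_games,
                   shots_per_game = shots_per_game, seed = seed)
}

# softmax next-region probabilities for every (antecedent, outcome) state,
# plus the base policy
policy_matrices <- function(config) {
  R <- length(config$map$labels)
  w <- config$base_weights
  eta <- config$learning_rate
  K <- config$kernel
  p0 <- w / sum(w)
  PS <- PF <- matrix(0, R, R)
  for (i in seq_len(R)) {
    ws <- w * exp(eta * K[i, ])
    wf <- w * exp(-eta * K[i, ])
    PS[i, ] <- ws / sum(ws)
    PF[i, ] <- wf / sum(wf)
  }
  list(p0 = p0, PS = PS, PF = PF)
}

region_pv <- function(map) ifelse(map$groups == "THREE", 3L, 2L)

#' Generate a synthetic cohort of shot sequences
#'
#' Simulates every player of the configuration and returns the canonical
#' shot table, with `return_points` filled by the possession model.  The
#' output is bit-identical for a fixed seed; each player consumes an
#' independent substream derived from the master seed.
#'
#' @param config a [synthetic_config()].
#' @return A [shot_table()] with provenance `source = "synthetic"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  players <- lapply(seq_len(config$n_players), function(p) {
    set.seed(substream_seed(config$seed, p))
    df <- if (config$mode == "one_step") simulate_player_one_step(config)
    else simulate_player_melioration(config)
    df$player_id <- sprintf("p%04d", p)
    df
  })
  df <- do.call(rbind, players)
  df$season <- "s1"
  shot_table(df, source = "synthetic", seed = config$seed)
}

simulate_player_one_step <- function(config) {
  map <- config$map
  pl <- map$placement
  R <- length(map$labels)
  pol <- policy_matrices(config)
  cum0 <- cumsum(pol$p0)
  cumS <- t(apply(pol$PS, 1, cumsum))
  cumF <- t(apply(pol$PF, 1, cumsum))
  pv <- region_pv(map)
  G <- config$n_games
  Tg <- config$shots_per_game
  lab_idx <- matrix(0L, G, Tg)
  dist_m <- ang_m <- matrix(0, G, Tg)
  out_m <- matrix(FALSE, G, Tg)

  draw_coords <- function(r) {
    d <- stats::runif(length(r), pl$d_lo[r], pl$d_hi[r])
    a <- stats::runif(length(r), pl$a_lo[r], pl$a_hi[r])
    list(d = d, a = a)
  }
  draw_outcome <- function(r, d) {
    q <- if (is.function(config$make_prob)) config$make_prob(d) else
      config$make_prob[r]
    stats::runif(length(r)) < q
  }

  for (t in seq_len(Tg)) {
    if (t == 1L) {
      r <- findInterval(stats::runif(G), cum0) + 1L
    } else {
      prev <- lab_idx[, t - 1L]
      made <- out_m[, t - 1L]
      u <- stats::runif(G)
      cm <- matrix(0, G, R)
      cm[made, ] <- cumS[prev[made], , drop = FALSE]
      cm[!made, ] <- cumF[prev[!made], , drop = FALSE]
      r <- rowSums(cm < u) + 1L
    }
    co <- draw_coords(r)
    lab_idx[, t] <- r
    dist_m[, t] <- co$d
    ang_m[, t] <- co$a
    out_m[, t] <- draw_outcome(r, co$d)
  }

  putback <- matrix(stats::runif(G * Tg) < config$putback_prob, G, Tg)
  ret <- ifelse(out_m, pv[lab_idx], ifelse(putback, 2, 0))
  a_rad <- deg2rad(ang_m)
  data.frame(
    player_id = "p", season = "s1",
    game_id = sprintf("g%04d", rep(seq_len(G), each = Tg)),
    order_in_game = rep(seq_len(Tg), times = G),
    x_ft = as.vector(t(dist_m * cos(a_rad))),
    y_ft = map$court$basket_y + as.vector(t(dist_m * sin(a_rad))),
    outcome = ifelse(as.vector(t(out_m)), "S", "F"),
    point_value = pv[as.vector(t(lab_idx))],
    return_points = as.vector(t(ret)),
    stringsAsFactors = FALSE
  )
}

simulate_player_melioration <- function(config) {
  map <- config$map
  pl <- map$placement
  pv <- region_pv(map)
  mel <- config$melioration
  is3 <- map$groups == "THREE"
  w <- config$base_weights
  w3 <- w * is3; w2 <- w * !is3
  if (sum(w3) == 0 || sum(w2) == 0)
    stopf("melioration mode needs both 2pt and 3pt regions")
  cum3 <- cumsum(w3 / sum(w3))
  cum2 <- cumsum(w2 / sum(w2))
  burn <- max(0L, as.integer(mel$burn_in_games))
  G <- config$n_games + burn; Tg <- config$shots_per_game
  n <- G * Tg
  p3 <- mel$p3_init
  f3 <- mel$p3_init
  rhat3 <- rhat2 <- 1.2
  lab <- integer(n); outc <- logical(n); dd <- aa <- ret <- numeric(n)
  base_q <- function(d) if (is.function(config$make_prob))
    config$make_prob(d) else stop("melioration needs make_prob(d)")
  for (s in seq_len(n)) {
    choose3 <- stats::runif(1) < p3
    r <- if (choose3) findInterval(stats::runif(1), cum3) + 1L else
      findInterval(stats::runif(1), cum2) + 1L
    d <- stats::runif(1, pl$d_lo[r], pl$d_hi[r])
    a <- stats::runif(1, pl$a_lo[r], pl$a_hi[r])
    fc <- if (choose3) f3 else 1 - f3
    press <- if (choose3) mel$press3 else mel$press2
    q <- clamp(base_q(d) * (1 - press * fc), 0.01, 0.99)
    made <- stats::runif(1) < q
    rp <- if (made) pv[r] else if (stats::runif(1) < config$putback_prob)
      2 else 0
    if (choose3) rhat3 <- (1 - mel$ema) * rhat3 + mel$ema * rp
    else rhat2 <- (1 - mel$ema) * rhat2 + mel$ema * rp
    f3 <- (1 - mel$ema) * f3 + mel$ema * as.numeric(choose3)
    p3 <- clamp(p3 + mel$lambda * (rhat3 - rhat2), 0.02, 0.98)
    lab[s] <- r; outc[s] <- made; dd[s] <- d; aa[s] <- a; ret[s] <- rp
  }
  a_rad <- deg2rad(aa)
  df <- data.frame(
    player_id = "p", season = "s1",
    game_id = sprintf("g%04d", rep(seq_len(G), each = Tg)),
    order_in_game = rep(seq_len(Tg), times = G),
    x_ft = dd * cos(a_rad),
    y_ft = map$court$basket_y + dd * sin(a_rad),
    outcome = ifelse(outc, "S", "F"),
    point_value = pv[lab],
    return_points = ret,
    stringsAsFactors = FALSE
  )
  if (burn > 0) {   # drop the pre-equilibrium transient, renumber games
    df <- df[-seq_len(burn * Tg), , drop = FALSE]
    df$game_id <- sprintf("g%04d", rep(seq_len(config$n_games), each = Tg))
  }
  df
}

#' Serialize a synthetic configuration as YAML
#'
#' The region map, numeric parameters and (for vector `make_prob`) the make
#' probabilities round-trip through a plain-text YAML file.  A functional
#' `make_prob` is stored as its linear coefficients when it was built by
#' [linear_make_prob()], otherwise serialization fails.
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @export
write_synthetic_config <- function(config, path) {
  mp <- config$make_prob
  mp_obj <- if (is.numeric(mp)) list(kind = "vector", values = mp)
  else if (!is.null(attr(mp, "linear_coef")))
    list(kind = "linear", coef = as.list(attr(mp, "linear_coef")))
  else stopf("cannot serialize an arbitrary make_prob function")
  crt <- config$map$court
  obj <- list(
    map = list(kind = config$map$kind,
               court = list(basket_y = crt$basket_y,
                            arc_radius = crt$arc_radius,
                            corner_offset = crt$corner_offset,
                            half_court_y = crt$half_court_y,
                            court_half_width = crt$court_half_width),
               params = config$map$params),
    base_weights = config$base_weights,
    make_prob = mp_obj,
    learning_rate = config$learning_rate,
    kernel = as.vector(config$kernel),
    n_players = config$n_players, n_games = config$n_games,
    shots_per_game = config$shots_per_game,
    putback_prob = config$putback_prob, mode = config$mode,
    melioration = config$melioration, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  crt <- do.call(court_spec, obj$map$court)
  map <- switch(obj$map$kind,
                nba = region_map_nba(crt, obj$map$params$r_inner,
                                     obj$map$params$r_mid),
                polar = region_map_polar(obj$map$params$labels,
                                         obj$map$params$groups,
                                         obj$map$params$a_lo,
                                         obj$map$params$a_hi,
                                         obj$map$params$d_lo,
                                         obj$map$params$d_hi, crt))
  R <- length(map$labels)
  mp <- if (obj$make_prob$kind == "vector") unlist(obj$make_prob$values)
  else do.call(linear_make_prob, obj$make_prob$coef)
  synthetic_config(map = map, base_weights = unlist(obj$base_weights),
                   make_prob = mp, learning_rate = obj$learning_rate,
                   kernel = matrix(unlist(obj$kernel), R, R),
                   n_players = obj$n_players, n_games = obj$n_games,
                   shots_per_game = obj$shots_per_game,
                   putback_prob = obj$putback_prob, mode = obj$mode,
                   melioration = obj$melioration, seed = obj$seed)
}

#' Linear make-probability profile
#'
#' `q(d) = clamp(intercept + slope * d, lo, hi)` — the default difficulty
#' model: success probability declines linearly with distance and is equal
#' for 2pt and 3pt attempts at the same distance.
#'
#' @param intercept,slope linear coefficients.
#' @param lo,hi clamp bounds.
#' @return A function of distance carrying its coefficients for
#'   serialization.
#' @export
linear_make_prob <- function(intercept = 0.62, slope = -0.01,
                             lo = 0.05, hi = 0.95) {
  f <- function(d) clamp(intercept + slope * d, lo, hi)
  attr(f, "linear_coef") <- c(intercept = intercept, slope = slope,
                              lo = lo, hi = hi)
  f
}
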