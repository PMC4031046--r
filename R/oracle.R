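#' Exact statistics of the one-step generative model
#'
#' The one-step model induces a Markov chain on (region, outcome) states:
#' the next region follows the softmax of the outcome-updated weights and
#' the next outcome is Bernoulli in the region's expected make probability.
#' Every quantity the estimation pipeline targets therefore has a closed
#' form, computed here: the stationary region distribution, the
#' finite-game prior actually estimated by the pipeline (the average of the
#' within-game marginals of shots `1..shots_per_game`, first shot from the
#' base policy), the exact conditionals `P(j|S_i)`, `P(j|F_i)`, the exact
#' fine and coarse learning matrices, distance-binned learning and
#' difficulty values and per-class expected returns.
#'
#' The expected make probability of a region integrates `make_prob(d)` over
#' the region's uniform distance band; because region and distance are
#' conditionally independent given the region, the chain over
#' (region, outcome) is exact, not an approximation.
#'
#' @param config a [synthetic_config()] with `mode = "one_step"`.
#' @param bins optional data frame of distance cells (`lo`, `hi`,
#'   `point_class`) for which exact binned statistics are computed.
#' @return An object of class `oracle_statistics`.
#' @export
oracle_statistics <- function(config, bins = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$mode != "one_step")
    stopf("oracle available for one_step mode only")
  map <- config$map
  pl <- map$placement
  R <- length(map$labels)
  if (any(config$base_weights <= 0))
    stopf("non-ergodic chain: some region has zero weight")
  pol <- policy_matrices(config)
  pv <- region_pv(map)
  pb <- config$putback_prob

  qfun_r <- function(r) {
    if (is.numeric(config$make_prob)) {
      q <- config$make_prob[r]; function(d) rep(q, length(d))
    } else config$make_prob
  }
  int_band <- function(r, f, lo = pl$d_lo[r], hi = pl$d_hi[r]) {
    if (hi <= lo) return(0)
    stats::integrate(f, lo, hi, rel.tol = 1e-11,
                     subdivisions = 500L)$value
  }
  width <- pl$d_hi - pl$d_lo
  qbar <- vapply(seq_len(R), function(r)
    int_band(r, qfun_r(r)) / width[r], numeric(1))

  # transition over states (r, o): columns blocks S then F
  st <- function(r, o) r + R * (o - 1L)   # o = 1 (S), 2 (F)
  TM <- matrix(0, 2 * R, 2 * R)
  for (i in seq_len(R)) for (o in 1:2) {
    pj <- if (o == 1) pol$PS[i, ] else pol$PF[i, ]
    TM[st(i, o), seq_len(R)] <- pj * qbar
    TM[st(i, o), R + seq_len(R)] <- pj * (1 - qbar)
  }

  Tg <- config$shots_per_game
  m <- matrix(0, Tg, 2 * R)
  m[1, ] <- c(pol$p0 * qbar, pol$p0 * (1 - qbar))
  if (Tg > 1) for (t in 2:Tg) m[t, ] <- m[t - 1, ] %*% TM

  region_marg <- m[, seq_len(R), drop = FALSE] +
    m[, R + seq_len(R), drop = FALSE]
  prior_finite <- colMeans(region_marg)

  # stationary distribution by power iteration (ergodic: all weights > 0)
  pi_s <- m[1, ]
  repeat {
    nxt <- as.vector(pi_s %*% TM)
    if (max(abs(nxt - pi_s)) < 1e-14) { pi_s <- nxt; break }
    pi_s <- nxt
  }
  prior_stationary <- pi_s[seq_len(R)] + pi_s[R + seq_len(R)]

  ante <- colSums(m[seq_len(max(Tg - 1, 1)), , drop = FALSE])
  ante <- ante / sum(ante)
  ante_m <- cbind(S = ante[seq_len(R)], F = ante[R + seq_len(R)])

  L <- sweep(pol$PS - pol$PF, 2, prior_finite, "/")
  dimnames(L) <- list(map$labels, map$labels)

  # coarse statistics on regrouped events
  grp <- c("THREE", "LONG2", "SHORT2")
  gi <- match(map$groups, grp)
  grp_sum <- function(v) vapply(1:3, function(g) sum(v[gi == g]),
                                numeric(1))
  prior_coarse <- stats::setNames(grp_sum(prior_finite), grp)
  condc <- function(P, w) {
    out <- matrix(NA_real_, 3, 3, dimnames = list(grp, grp))
    for (g in 1:3) {
      wi <- w * (gi == g)
      if (sum(wi) == 0) next
      wi <- wi / sum(wi)
      out[g, ] <- grp_sum(colSums(wi * P))   # P(next group | ante in g, o)
    }
    out
  }
  PcS <- condc(pol$PS, ante_m[, "S"])
  PcF <- condc(pol$PF, ante_m[, "F"])
  L_coarse <- sweep(PcS - PcF, 2, prior_coarse, "/")

  p3next_S <- rowSums(pol$PS[, gi == 1, drop = FALSE])
  p3next_F <- rowSums(pol$PF[, gi == 1, drop = FALSE])

  bins_out <- NULL
  if (!is.null(bins)) {
    bins_out <- bins
    bins_out$mean_dist <- bins_out$shooting_pct <- NA_real_
    bins_out$learning_diff <- bins_out$return_mean <- NA_real_
    cls <- ifelse(map$groups == "THREE", 3L, 2L)
    for (b in seq_len(nrow(bins))) {
      sel <- which(cls == bins$point_class[b] &
                     pl$d_hi > bins$lo[b] & pl$d_lo < bins$hi[b])
      if (!length(sel)) next
      lo <- pmax(pl$d_lo[sel], bins$lo[b])
      hi <- pmin(pl$d_hi[sel], bins$hi[b])
      qf <- lapply(sel, qfun_r)
      i_1 <- mapply(function(r, l, h, f) int_band(r, function(d)
        rep(1, length(d)) + 0 * d, l, h), sel, lo, hi, qf)
      i_q <- mapply(function(r, l, h, f) int_band(r, f, l, h),
                    sel, lo, hi, qf)
      i_d <- mapply(function(r, l, h, f) int_band(r, function(d) d, l, h),
                    sel, lo, hi, qf)
      i_ret <- mapply(function(r, l, h, f, pvr) int_band(r, function(d)
        f(d) * pvr + (1 - f(d)) * 2 * pb, l, h),
        sel, lo, hi, qf, pv[sel])
      wsh <- prior_finite[sel] / width[sel]      # shot-level weights
      tot <- sum(wsh * i_1)
      bins_out$mean_dist[b] <- sum(wsh * i_d) / tot
      bins_out$shooting_pct[b] <- sum(wsh * i_q) / tot
      bins_out$return_mean[b] <- sum(wsh * i_ret) / tot

      # antecedent-side weights: fraction of the region's band in the bin,
      # reweighted by outcome probability over the band
      band_q <- vapply(seq_along(sel), function(k)
        int_band(sel[k], qf[[k]]), numeric(1))
      wS <- ante_m[sel, "S"] * (i_q / pmax(band_q, 1e-300))
      wF <- ante_m[sel, "F"] *
        ((i_1 - i_q) / pmax(width[sel] - band_q, 1e-300))
      ldS <- if (sum(wS) > 0) sum(wS * p3next_S[sel]) / sum(wS) else NA
      ldF <- if (sum(wF) > 0) sum(wF * p3next_F[sel]) / sum(wF) else NA
      bins_out$learning_diff[b] <- ldS - ldF
    }
  }

  ret_r <- qbar * pv + (1 - qbar) * 2 * pb
  frac3 <- sum(prior_finite[gi == 1])
  inc3 <- sum(prior_finite[gi == 1] * ret_r[gi == 1])
  inc2 <- sum(prior_finite[gi != 1] * ret_r[gi != 1])

  structure(list(
    prior = stats::setNames(prior_finite, map$labels),
    prior_stationary = stats::setNames(prior_stationary, map$labels),
    cond_make = pol$PS, cond_miss = pol$PF,
    L = L, L_coarse = L_coarse, prior_coarse = prior_coarse,
    qbar = stats::setNames(qbar, map$labels),
    ante = ante_m,
    bins = bins_out,
    return_by_region = stats::setNames(ret_r, map$labels),
    return_2pt = inc2 / sum(prior_finite[gi != 1]),
    return_3pt = inc3 / sum(prior_finite[gi == 1]),
    frac_3pt_attempts = frac3,
    frac_3pt_income = inc3 / (inc2 + inc3),
    transition = TM,
    config = config
  ), class = "oracle_statistics")
}

#' @export
print.oracle_statistics <- function(x, digits = 3, ...) {
  cat(sprintf("<oracle_statistics: %d regions, shots_per_game=%d>\n",
              length(x$prior), x$config$shots_per_game))
  cat("coarse learning matrix (exact):\n")
  print(round(x$L_coarse, digits))
  invisible(x)
}
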