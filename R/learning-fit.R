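#' Fit the cohort learning model
#'
#' The central estimator of the package: applies the player selection
#' criteria, estimates each selected player's outcome-conditioned
#' shot-location probabilities and learning matrix at the requested
#' resolution, and aggregates over players with equal weight.
#'
#' @param table a [shot_table()].
#' @param map a `region_map`.
#' @param resolution `"fine"` (per-region matrix) or `"coarse"` (3x3 matrix
#'   over `THREE`/`LONG2`/`SHORT2`).
#' @param min_per_region selection threshold on attempts per region (always
#'   evaluated on the map's full region set).
#' @return An object of class `learning_fit` with components `aggregate`
#'   (an [aggregate_learning()]), `per_player` (list of
#'   [learning_matrix()]), `selected` (player keys), `n_candidates`, `map`,
#'   `resolution`.
#' @seealso [cluster_regions()], [perm_test_offdiag_sd()]
#' @examples
#' cfg <- synthetic_config(n_players = 8, n_games = 40, shots_per_game = 12,
#'                         seed = 7)
#' shots <- generate_cohort(cfg)
#' fit <- fit_learning(shots, cfg$map, resolution = "coarse",
#'                     min_per_region = 1)
#' coef(fit)
#' @export
fit_learning <- function(table, map = region_map_nba(),
                         resolution = c("fine", "coarse"),
                         min_per_region = 10) {
  resolution <- match.arg(resolution)
  keys_all <- unique(player_key_of(table$player_id, table$season))
  keys <- select_players_fine(table, map, min_per_region)
  mats <- lapply(keys, function(k) {
    sub <- shot_subset(table, k)
    if (resolution == "fine")
      learning_matrix(estimate_conditionals(sub, map, regions = map$labels))
    else
      coarse_matrix(sub, map)
  })
  ok <- vapply(mats, function(m) all(m$valid), logical(1))
  mats <- mats[ok]
  keys <- keys[ok]
  if (length(mats) < 2)
    stopf("fewer than 2 players pass the selection criteria")
  structure(list(
    aggregate = aggregate_learning(mats),
    per_player = stats::setNames(mats, keys),
    selected = keys,
    n_candidates = length(keys_all),
    map = map, resolution = resolution,
    min_per_region = min_per_region
  ), class = "learning_fit")
}

#' @export
print.learning_fit <- function(x, ...) {
  ag <- x$aggregate
  cat(sprintf("Learning-matrix fit (%s resolution)\n", x$resolution))
  cat(sprintf("  players: %d selected of %d candidates (>=%d FG/region, all rows valid)\n",
              length(x$selected), x$n_candidates, x$min_per_region))
  cat(sprintf("  diagonal mean: %.3f   off-diagonal SD: %.3f\n",
              ag$diag_mean, ag$offdiag_sd))
  invisible(x)
}

#' @export
summary.learning_fit <- function(object, ...) {
  ag <- object$aggregate
  pos_diag <- sum(diag(ag$mean) > 0)
  out <- list(resolution = object$resolution,
              n_players = ag$n_players,
              n_candidates = object$n_candidates,
              diag_mean = ag$diag_mean,
              offdiag_sd = ag$offdiag_sd,
              n_pos_diag = pos_diag,
              n_diag = nrow(ag$mean),
              sign_test_p = binomial_tail(pos_diag, nrow(ag$mean), 0.5),
              mean = ag$mean, sem = ag$sem)
  class(out) <- "summary.learning_fit"
  out
}

#' @export
print.summary.learning_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort learning matrix (%s), %d players\n",
              x$resolution, x$n_players))
  cat(sprintf("  diagonal mean         %.3f\n", x$diag_mean))
  cat(sprintf("  off-diagonal SD       %.3f\n", x$offdiag_sd))
  cat(sprintf("  positive diagonal     %d/%d (one-tailed binomial p = %.4g)\n",
              x$n_pos_diag, x$n_diag, x$sign_test_p))
  cat("\nMean matrix (rows = antecedent region):\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
coef.learning_fit <- function(object, ...) object$aggregate$mean

#' @export
plot.learning_fit <- function(x, ...) {
  m <- x$aggregate$mean
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "consequent region",
                  ylab = "antecedent region",
                  main = sprintf("Mean learning matrix (%s)", x$resolution),
                  ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m) %||% seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m) %||% seq_len(n)))
  graphics::box()
  invisible(x)
}

#' Export a learning fit as CSV + JSON report
#'
#' Writes the mean and SEM matrices as labeled CSVs and a JSON report with
#' the headline statistics.
#'
#' @param fit a [fit_learning()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_learning_report <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ag <- fit$aggregate
  lab <- ag$labels
  mean_m <- ag$mean; dimnames(mean_m) <- list(lab, lab)
  sem_m <- ag$sem; dimnames(sem_m) <- list(lab, lab)
  p_mean <- file.path(dir, sprintf("learning_mean_%s.csv", fit$resolution))
  p_sem <- file.path(dir, sprintf("learning_sem_%s.csv", fit$resolution))
  p_json <- file.path(dir, sprintf("learning_report_%s.json", fit$resolution))
  utils::write.csv(mean_m, p_mean)
  utils::write.csv(sem_m, p_sem)
  jsonlite::write_json(list(resolution = fit$resolution,
                            n_players = ag$n_players,
                            diag_mean = ag$diag_mean,
                            offdiag_sd = ag$offdiag_sd),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_mean, p_sem, p_json))
}
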