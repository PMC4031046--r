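#' Run the full analysis pipeline
#'
#' Orchestrates the package end to end: loads a canonical shot CSV or
#' generates a synthetic cohort, fits the fine and coarse learning
#' matrices, clusters regions prospectively and retrospectively, runs the
#' off-diagonal permutation test, computes distance curves and the
#' matching analysis, and writes a deterministic report bundle (CSV
#' matrices, Newick dendrograms, JSON test results, a run manifest).
#'
#' @param input path to a canonical shot CSV (exclusive with `synthetic`).
#' @param synthetic a [synthetic_config()] (exclusive with `input`).
#' @param out_dir output directory for the bundle.
#' @param map a `region_map` used for all region-level analyses.
#' @param seed seed for the permutation test.
#' @param n_rep permutation repetitions (>= 1).
#' @param bin_width distance bin width, feet.
#' @param min_per_region selection threshold.
#' @param ward_form `"sqrt"` or `"squared"` Ward heights.
#' @param analyses subset of
#'   `c("matrix", "cluster", "permtest", "distance", "matching")`.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(input = NULL, synthetic = NULL, out_dir,
                         map = region_map_nba(), seed = 1, n_rep = 1000,
                         bin_width = 2, min_per_region = 10,
                         ward_form = c("sqrt", "squared"),
                         analyses = c("matrix", "cluster", "permtest",
                                      "distance", "matching")) {
  ward_form <- match.arg(ward_form)
  if (is.null(input) == is.null(synthetic))
    stopf("specify exactly one of input / synthetic")
  if (n_rep < 1) stopf("n_rep must be >= 1")
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- if (!is.null(input)) read_shot_table(input) else
    generate_cohort(synthetic)
  if (!is.null(synthetic)) map <- synthetic$map

  files <- character(0)
  manifest <- list(seed = seed, n_rep = n_rep, bin_width = bin_width,
                   min_per_region = min_per_region, ward_form = ward_form,
                   n_events = nrow(table),
                   n_players = length(unique(
                     player_key_of(table$player_id, table$season))),
                   package_version =
                     as.character(utils::packageVersion("hooplearn")))

  fit <- NULL
  if (any(c("matrix", "cluster", "permtest") %in% analyses)) {
    fit <- tryCatch(fit_learning(table, map, "fine", min_per_region),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      manifest$matrix_error <- conditionMessage(fit)
      fit <- NULL
    }
  }

  if ("matrix" %in% analyses && !is.null(fit)) {
    files <- c(files, write_learning_report(fit, out_dir))
    cfit <- tryCatch(fit_learning(table, map, "coarse", min_per_region),
                     error = function(e) NULL)
    if (!is.null(cfit)) files <- c(files, write_learning_report(cfit, out_dir))
    manifest$n_selected_fine <- length(fit$selected)
  }

  if ("cluster" %in% analyses && !is.null(fit)) {
    for (axis in c("prospective", "retrospective")) {
      tree <- cluster_regions(fit, axis, form = ward_form)
      p_nwk <- file.path(out_dir, sprintf("dendrogram_%s.nwk", axis))
      write_newick(tree, p_nwk)
      D <- row_dissimilarity(fit$aggregate, axis)
      p_d <- file.path(out_dir, sprintf("dissimilarity_%s.csv", axis))
      utils::write.csv(D, p_d)
      p_r <- file.path(out_dir, sprintf("dissimilarity_%s_ordered.csv", axis))
      utils::write.csv(D[tree$order, tree$order], p_r)
      files <- c(files, p_nwk, p_d, p_r)
    }
  }

  if ("permtest" %in% analyses && !is.null(fit)) {
    pt <- perm_test_offdiag_sd(table, map, n_rep = n_rep, seed = seed,
                               min_per_region = min_per_region)
    p_json <- file.path(out_dir, "perm_test_offdiag_sd.json")
    jsonlite::write_json(list(statistic = pt$statistic,
                              observed = pt$observed, p_value = pt$p_value,
                              n_rep = pt$n_rep, seed = pt$seed),
                         p_json, auto_unbox = TRUE, digits = NA)
    files <- c(files, p_json)
    manifest$perm_p_value <- pt$p_value
  }

  if ("distance" %in% analyses) {
    crv <- bin_learning_curve(table, bin_width = bin_width,
                              court = map$court)
    pct <- shooting_pct_curve(table, bin_width = bin_width,
                              court = map$court)
    p1 <- file.path(out_dir, "learning_curve.csv")
    p2 <- file.path(out_dir, "shooting_pct_curve.csv")
    utils::write.csv(crv, p1, row.names = FALSE)
    utils::write.csv(pct, p2, row.names = FALSE)
    files <- c(files, p1, p2)
    manifest$n_selected_bins <- if (nrow(crv)) max(crv$n_players) else 0L
  }

  if ("matching" %in% analyses && !anyNA(table$return_points)) {
    mt <- matching_analysis(table)
    rvd <- return_vs_distance(table, bin_width = bin_width,
                              court = map$court)
    p1 <- file.path(out_dir, "matching_records.csv")
    p2 <- file.path(out_dir, "return_vs_distance.csv")
    utils::write.csv(mt$records, p1, row.names = FALSE)
    utils::write.csv(rvd, p2, row.names = FALSE)
    files <- c(files, p1, p2)
    manifest$matching <- mt$summary
  }

  manifest$files <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable summary of a pipeline bundle
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
report_summary <- function(out_dir) {
  mf_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json in %s", out_dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  missing_files <- setdiff(mf$files, list.files(out_dir))
  if (length(missing_files))
    stopf("bundle integrity error: missing %s",
          paste(missing_files, collapse = ", "))
  lines <- c(
    sprintf("Pipeline bundle: %s", out_dir),
    sprintf("  events: %d, player-seasons: %d", mf$n_events, mf$n_players))
  fine <- file.path(out_dir, "learning_report_fine.json")
  if (file.exists(fine)) {
    rep <- jsonlite::read_json(fine, simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "  fine matrix: %d players, diag mean %.3f, off-diag SD %.3f",
      rep$n_players, rep$diag_mean, rep$offdiag_sd))
  }
  if (!is.null(mf$perm_p_value))
    lines <- c(lines, sprintf("  off-diag SD permutation p = %s",
                              format(mf$perm_p_value)))
  if (!is.null(mf$matching))
    lines <- c(lines, sprintf(
      "  matching: returns 2pt %.3f / 3pt %.3f, deviation %.4f",
      mf$matching$return_2pt, mf$matching$return_3pt,
      mf$matching$deviation_from_matching))
  if (!is.null(mf$n_selected_bins))
    lines <- c(lines, sprintf("  distance analysis players: %d",
                              mf$n_selected_bins))
  cat(lines, sep = "\n")
  invisible(lines)
}
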