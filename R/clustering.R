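#' Prospective / retrospective dissimilarity of court regions
#'
#' The learning matrix is asymmetric: row `i` describes how outcomes in
#' region `i` affect all subsequent regions (prospective view), column `j`
#' how region `j` is affected by outcomes everywhere (retrospective view).
#' This computes the Euclidean distance between the rows (prospective) or
#' columns (retrospective) of the averaged matrix.
#'
#' @param agg an [aggregate_learning()] (or a plain numeric matrix).
#' @param axis `"prospective"` (rows) or `"retrospective"` (columns).
#' @param drop_self if `TRUE`, the self-coordinate (diagonal entry) is
#'   removed from each vector before computing distances.
#' @return A symmetric matrix with zero diagonal, labeled by region.
#' @export
row_dissimilarity <- function(agg, axis = c("prospective", "retrospective"),
                              drop_self = FALSE) {
  axis <- match.arg(axis)
  m <- cluster_vectors(agg, axis, drop_self)
  if (anyNA(m)) stopf("invalid entries present in the aggregate matrix")
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# region-labeled row vectors for clustering along the requested axis
cluster_vectors <- function(agg, axis = c("prospective", "retrospective"),
                            drop_self = FALSE) {
  axis <- match.arg(axis)
  m <- if (inherits(agg, "aggregate_learning")) agg$mean else as.matrix(agg)
  lab <- if (inherits(agg, "aggregate_learning")) agg$labels else
    rownames(m) %||% as.character(seq_len(nrow(m)))
  if (axis == "retrospective") m <- t(m)
  rownames(m) <- lab
  if (drop_self) {
    n <- nrow(m)
    m <- matrix(t(m)[as.vector(t(row(m) != col(m)))], nrow = n, byrow = TRUE,
                dimnames = list(lab, NULL))
  }
  m
}

#' Agglomerative Ward clustering
#'
#' Ward's linkage on labeled vectors: starting from singletons, repeatedly
#' merges the pair of clusters `A`, `B` minimizing
#' \deqn{d(A,B) = \sqrt{\frac{2 n_A n_B}{n_A + n_B}} \, \lVert c_A - c_B \rVert,}
#' where `c` are cluster centroids.  For singletons this reduces to the
#' Euclidean distance, so the merge heights extend the dissimilarity matrix
#' of [row_dissimilarity()].  `form = "squared"` reports the squared variant
#' (`2 n_A n_B / (n_A + n_B) * ||c_A - c_B||^2`); the merge order is
#' identical, only heights differ.  Distance ties are broken by the
#' lexicographically smallest pair of cluster ids, making the output
#' deterministic.
#'
#' @param vectors numeric matrix, one labeled row per object (or an
#'   [aggregate_learning()] plus `axis`).
#' @param form `"sqrt"` (default) or `"squared"` merge heights.
#' @param axis used when `vectors` is an `aggregate_learning`.
#' @return An object of class `ward_tree` with `merge`, `height`, `order`,
#'   `labels` (hclust-compatible via [as.hclust()]).
#' @export
ward_cluster <- function(vectors, form = c("sqrt", "squared"),
                         axis = c("prospective", "retrospective")) {
  form <- match.arg(form)
  if (inherits(vectors, "aggregate_learning"))
    vectors <- cluster_vectors(vectors, match.arg(axis))
  m <- as.matrix(vectors)
  n <- nrow(m)
  if (n < 2) stopf("need at least 2 vectors")
  if (anyNA(m)) stopf("vectors contain missing values")
  labels <- rownames(m) %||% as.character(seq_len(n))

  # active cluster state; id: -leaf for singletons, +merge index afterwards
  members <- as.list(seq_len(n))
  centroid <- lapply(seq_len(n), function(i) m[i, ])
  size <- rep(1L, n)
  id <- -seq_len(n)
  birth <- seq_len(n)           # creation rank, for lexicographic ties
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node <- vector("list", n - 1L)   # member leaf sets per merge

  ward_d <- function(i, j) {
    w <- 2 * size[i] * size[j] / (size[i] + size[j])
    dd <- sqrt(sum((centroid[[i]] - centroid[[j]])^2))
    if (form == "sqrt") sqrt(w) * dd else w * dd^2
  }

  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- ward_d(i, j)
        if (d < best_d ||
            (d == best_d &&
             lex_less(sort(c(birth[i], birth[j])),
                      sort(c(birth[best[1]], birth[best[2]]))))) {
          best <- c(i, j); best_d <- d
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))  # hclust: negatives first is moot
    height[step] <- best_d
    node[[step]] <- c(members[[i]], members[[j]])
    new_centroid <- (size[i] * centroid[[i]] + size[j] * centroid[[j]]) /
      (size[i] + size[j])
    members[[i]] <- node[[step]]
    centroid[[i]] <- new_centroid
    size[i] <- size[i] + size[j]
    id[i] <- step
    birth[i] <- min(birth[i], birth[j])
    members[[j]] <- NULL; centroid[[j]] <- NULL
    size <- size[-j]; id <- id[-j]; birth <- birth[-j]
  }

  structure(list(merge = merge, height = height,
                 order = dendro_order(merge, node),
                 labels = labels, form = form, n = n),
            class = "ward_tree")
}

lex_less <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

# display order: recursively place the smaller cluster first
dendro_order <- function(merge, node) {
  expand <- function(code) {
    if (code < 0) return(-code)
    a <- merge[code, 1]; b <- merge[code, 2]
    sa <- if (a < 0) 1L else length(node[[a]])
    sb <- if (b < 0) 1L else length(node[[b]])
    if (sb < sa) c(expand(b), expand(a)) else c(expand(a), expand(b))
  }
  expand(nrow(merge))
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("<ward_tree: %d leaves, %s heights>\n", x$n, x$form))
  cat("  merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom stats as.hclust
#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = paste0("ward.", x$form),
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' @export
plot.ward_tree <- function(x, ...) {
  plot(as.hclust(x), ...)
  invisible(x)
}

#' Flat clusters from a Ward tree
#'
#' Cuts the dendrogram by removing the `k - 1` highest merges.
#'
#' @param tree a [ward_cluster()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  if (k < 1 || k > tree$n) stopf("k must be between 1 and %d", tree$n)
  stats::cutree(as.hclust(tree), k = k)
}

#' Serialize a Ward tree as Newick
#'
#' Branch lengths reflect the merge heights (ultrametric tree).
#'
#' @param tree a `ward_tree`.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  ph <- ape::as.phylo(as.hclust(tree))
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Cluster the learning matrix regions of a fit
#'
#' Convenience wrapper: clusters the rows (prospective) or columns
#' (retrospective) of a cohort's mean learning matrix.
#'
#' @param fit a [fit_learning()] result or `aggregate_learning`.
#' @param axis `"prospective"` or `"retrospective"`.
#' @param form height form passed to [ward_cluster()].
#' @return A `ward_tree`.
#' @export
cluster_regions <- function(fit, axis = c("prospective", "retrospective"),
                            form = c("sqrt", "squared")) {
  agg <- if (inherits(fit, "learning_fit")) fit$aggregate else fit
  ward_cluster(cluster_vectors(agg, match.arg(axis)), form = match.arg(form))
}
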