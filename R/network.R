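# Thresholded brain-network construction from PLV matrices.

#' Default threshold grid
#'
#' Five absolute PLV thresholds, 0.72 to 0.76 in steps of 0.01, spanning the
#' range of top-20% mean PLV across conditions.
#'
#' @return numeric vector.
#' @export
threshold_grid <- function() seq(0.72, 0.76, by = 0.01)

#' Mean of the strongest fraction of pair PLVs
#'
#' Averages the `ceiling(fraction * C(N, 2))` largest unique-pair values of
#' a PLV matrix (the top-20% sparsity summary used to anchor the threshold
#' grid).
#'
#' @param plv a [plv_matrix()].
#' @param fraction fraction in (0, 1] (default 0.2).
#' @return scalar mean of the retained values.
#' @export
top_fraction_mean <- function(plv, fraction = 0.2) {
  stopifnot(inherits(plv, "plv_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  vals <- plv$values[upper.tri(plv$values)]
  if (!length(vals)) stop("top_fraction_mean: empty matrix")
  k <- ceiling(fraction * length(vals))
  mean(sort(vals, decreasing = TRUE)[seq_len(k)])
}

#' Build a thresholded undirected brain graph
#'
#' Edge (i, j) is present iff `PLV_ij >= threshold` (ties retained); present
#' edges keep their PLV as weight.
#'
#' @param plv a [plv_matrix()].
#' @param threshold absolute threshold `T` in `[0, 1]`, or
#' @param sparsity target edge fraction in (0, 1]; when given, the threshold
#'   is the value retaining the top `sparsity` fraction of pairs for this
#'   participant (adaptive mode).
#' @param montage montage for region annotation; `NULL` skips regions.
#' @return object of class `brain_graph`: `adjacency` (binary symmetric),
#'   `weights` (PLV on present edges, 0 elsewhere), `nodes`, `regions`,
#'   `threshold`, `band`, `condition`, `participant`.
#' @export
build_graph <- function(plv, threshold = NULL, sparsity = NULL,
                        montage = default_montage()) {
  stopifnot(inherits(plv, "plv_matrix"))
  if (is.null(threshold) == is.null(sparsity)) {
    stop("build_graph: give exactly one of threshold= or sparsity=")
  }
  if (!is.null(sparsity)) {
    if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
    vals <- sort(plv$values[upper.tri(plv$values)], decreasing = TRUE)
    k <- ceiling(sparsity * length(vals))
    threshold <- vals[k]
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  adj <- (plv$values >= threshold) * 1
  diag(adj) <- 0
  w <- plv$values * adj
  regions <- if (!is.null(montage)) {
    channel_regions(plv$channel_labels, montage)
  } else {
    rep(NA_character_, length(plv$channel_labels))
  }
  structure(list(adjacency = adj, weights = w,
                 nodes = plv$channel_labels, regions = regions,
                 threshold = threshold, band = plv$band,
                 condition = plv$condition, participant = plv$participant),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  n <- length(x$nodes)
  e <- sum(x$adjacency) / 2
  cat(sprintf(
    "brain_graph: %d nodes, %d edges (sparsity %.3f) at T=%.3g [%s/%s/%s]\n",
    n, e, graph_sparsity(x), x$threshold,
    x$participant, x$condition, x$band))
  invisible(x)
}

#' Edge fraction of a graph
#'
#' @param g a [brain_graph()].
#' @return edges / C(N, 2).
#' @export
graph_sparsity <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  n <- length(g$nodes)
  (sum(g$adjacency) / 2) / choose(n, 2)
}

#' Edge list of a graph
#'
#' @param g a [brain_graph()].
#' @return data.frame `node_a, node_b, weight`.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
  data.frame(node_a = g$nodes[idx[, 1]], node_b = g$nodes[idx[, 2]],
             weight = g$weights[idx], stringsAsFactors = FALSE)
}

#' Serialize / load a graph (edge-list CSV + JSON header)
#'
#' @param g a [brain_graph()].
#' @param path path of the `.csv` edge list; a `.json` header with
#'   threshold, band, condition, participant and the node/region table is
#'   written alongside.
#' @return the path, invisibly.
#' @export
write_graph <- function(g, path) {
  utils::write.csv(graph_edges(g), path, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = g$threshold, band = g$band, condition = g$condition,
         participant = g$participant,
         nodes = data.frame(label = g$nodes, region = g$regions)),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
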