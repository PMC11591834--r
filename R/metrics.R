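# Graph-theoretic metrics on thresholded brain networks.
#
# Distances come from a Floyd-Warshall all-pairs pass that also tracks the
# number of distinct shortest paths per pair (needed for betweenness).
# Edge length conventions ("distance modes"):
#   binary      - every edge has length 1
#   one_minus_w - length 1 - PLV (default: strong coupling = short distance;
#                 at the 0.72-0.76 threshold grid a hop costs ~0.25, which is
#                 the only convention consistent with characteristic path
#                 lengths of 0.1-0.7 on these networks)
#   inverse_w   - length 1 / PLV
# Betweenness and the clustering coefficients are defined on the binary
# adjacency; betweenness, nodal efficiency and characteristic path length
# use the selected distance mode.

distance_modes <- c("one_minus_w", "binary", "inverse_w")

# relative tolerance for calling two floating-point path lengths equal when
# counting shortest-path multiplicities
path_tie_tol <- 1e-10

#' All-pairs shortest paths with multiplicities (Floyd-Warshall)
#'
#' @param g a [brain_graph()].
#' @param distance_mode one of `"one_minus_w"` (default), `"binary"`,
#'   `"inverse_w"`.
#' @return object of class `distance_matrix`: `d` (node x node lengths,
#'   `Inf` for unreachable pairs), `counts` (number of equal-length shortest
#'   paths; 0 where unreachable), `nodes`, `distance_mode`.
#' @export
shortest_paths <- function(g, distance_mode = "one_minus_w") {
  stopifnot(inherits(g, "brain_graph"))
  distance_mode <- match.arg(distance_mode, distance_modes)
  n <- length(g$nodes)
  len <- switch(distance_mode,
    binary = ifelse(g$adjacency == 1, 1, Inf),
    one_minus_w = ifelse(g$adjacency == 1, 1 - g$weights, Inf),
    inverse_w = ifelse(g$adjacency == 1, 1 / g$weights, Inf))
  d <- len
  cnt <- ifelse(g$adjacency == 1, 1, 0)
  diag(d) <- 0
  diag(cnt) <- 0

  for (k in seq_len(n)) {
    alt <- outer(d[, k], d[k, ], "+")
    calt <- outer(cnt[, k], cnt[k, ])
    ok <- is.finite(alt)
    tol <- path_tie_tol * pmax(1, abs(d))
    shorter <- ok & (!is.finite(d) | d - alt > tol)
    equal <- ok & !shorter & is.finite(d) & abs(alt - d) <= tol
    # paths through k never help (or tie) for pairs involving k itself
    shorter[k, ] <- FALSE; shorter[, k] <- FALSE
    equal[k, ] <- FALSE; equal[, k] <- FALSE
    diag(shorter) <- FALSE; diag(equal) <- FALSE
    d[shorter] <- alt[shorter]
    cnt[shorter] <- calt[shorter]
    cnt[equal] <- cnt[equal] + calt[equal]
  }
  dimnames(d) <- dimnames(cnt) <- list(g$nodes, g$nodes)
  structure(list(d = d, counts = cnt, nodes = g$nodes,
                 distance_mode = distance_mode),
            class = "distance_matrix")
}

#' Betweenness centrality
#'
#' For node j: the sum over pairs `s < t` (both different from j) of the
#' fraction of shortest s-t paths passing through j, normalized by
#' `(N - 1)(N - 2) / 2` so the star-graph hub scores exactly 1.
#'
#' @param g a [brain_graph()].
#' @param dm matching [shortest_paths()] result (recomputed when `NULL`).
#' @return named numeric vector, one value per node.
#' @export
betweenness <- function(g, dm = NULL) {
  stopifnot(inherits(g, "brain_graph"))
  if (is.null(dm)) dm <- shortest_paths(g)
  n <- length(g$nodes)
  if (n < 3) {
    warning("betweenness undefined for N < 3; returning zeros")
    return(stats::setNames(numeric(n), g$nodes))
  }
  bc <- numeric(n)
  d <- dm$d; cnt <- dm$counts
  for (j in seq_len(n)) {
    through <- outer(d[, j], d[j, ], "+")
    sigma_j <- outer(cnt[, j], cnt[j, ])
    on_path <- is.finite(d) & is.finite(through) &
      abs(through - d) <= path_tie_tol * pmax(1, abs(d)) & cnt > 0
    on_path[j, ] <- FALSE; on_path[, j] <- FALSE
    diag(on_path) <- FALSE
    frac <- matrix(0, n, n)
    frac[on_path] <- sigma_j[on_path] / cnt[on_path]
    bc[j] <- sum(frac[upper.tri(frac)])
  }
  stats::setNames(bc / ((n - 1) * (n - 2) / 2), g$nodes)
}

#' Nodal efficiency
#'
#' `E_nodal(j) = (1 / (N - 1)) * sum_{k != j} 1 / d(j, k)`; unreachable
#' nodes contribute 0. In binary mode values lie in `[0, 1]`; with weighted
#' distances shorter than 1 they may exceed 1 and are reported unclamped.
#'
#' @param dm a [shortest_paths()] result.
#' @return named numeric vector.
#' @export
nodal_efficiency <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- length(dm$nodes)
  if (n < 2) stop("nodal_efficiency: needs at least 2 nodes")
  inv <- 1 / dm$d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  stats::setNames(rowSums(inv) / (n - 1), dm$nodes)
}

#' Local clustering coefficient (binary)
#'
#' `C_i = 2 E_i / (k_i (k_i - 1))` with `E_i` the number of edges among the
#' neighbors of i; nodes with fewer than 2 neighbors get 0.
#'
#' @param g a [brain_graph()].
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_local <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  a <- g$adjacency
  n <- length(g$nodes)
  cc <- numeric(n)
  deg <- rowSums(a)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(a[i, ] == 1)
    e_i <- sum(a[nb, nb]) / 2
    cc[i] <- 2 * e_i / (deg[i] * (deg[i] - 1))
  }
  stats::setNames(cc, g$nodes)
}

#' Global clustering coefficient
#'
#' Arithmetic mean of the local coefficients over all N nodes (zeros
#' included).
#'
#' @param cc_local vector from [clustering_local()].
#' @return scalar.
#' @export
clustering_global <- function(cc_local) {
  if (!length(cc_local)) return(0)
  mean(cc_local)
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path lengths (self-distances and
#' unreachable pairs excluded).
#'
#' @param dm a [shortest_paths()] result.
#' @return scalar; error when no pair is connected.
#' @export
characteristic_path_length <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  v <- dm$d[upper.tri(dm$d)]
  v <- v[is.finite(v)]
  if (!length(v)) {
    stop("characteristic_path_length: graph has no connected pair")
  }
  mean(v)
}

#' All metrics for one graph
#'
#' Computes betweenness centrality, nodal efficiency and local clustering
#' per node, plus global clustering and characteristic path length, all from
#' a single distance matrix. For a graph with no edges the node metrics are
#' zero and the characteristic path length is `NA`.
#'
#' @param g a [brain_graph()].
#' @param distance_mode see [shortest_paths()].
#' @return object of class `metric_table`: list with `nodes` (data.frame
#'   `node, region, bc, ne, cc_local`), `cc_global`, `cpl`, and the graph
#'   metadata (`threshold`, `band`, `condition`, `participant`,
#'   `distance_mode`).
#' @export
metrics_for_graph <- function(g, distance_mode = "one_minus_w") {
  stopifnot(inherits(g, "brain_graph"))
  dm <- shortest_paths(g, distance_mode)
  cc <- clustering_local(g)
  cpl <- if (sum(g$adjacency) == 0) NA_real_ else
    characteristic_path_length(dm)
  structure(list(
    nodes = data.frame(node = g$nodes, region = g$regions,
                       bc = as.numeric(betweenness(g, dm)),
                       ne = as.numeric(nodal_efficiency(dm)),
                       cc_local = as.numeric(cc),
                       stringsAsFactors = FALSE),
    cc_global = clustering_global(cc),
    cpl = cpl,
    threshold = g$threshold, band = g$band, condition = g$condition,
    participant = g$participant, distance_mode = distance_mode),
    class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf(
    "metric_table [%s/%s/%s, T=%.3g, %s]: mean BC %.4f, mean NE %.3f, CC %.3f, CPL %s\n",
    x$participant, x$condition, x$band, x$threshold, x$distance_mode,
    mean(x$nodes$bc), mean(x$nodes$ne), x$cc_global,
    ifelse(is.na(x$cpl), "NA", sprintf("%.3f", x$cpl))))
  invisible(x)
}

#' Long-format metric rows
#'
#' @param mt a [metrics_for_graph()] result.
#' @return data.frame `participant, condition, band, threshold, node,
#'   metric, value` (graph-level rows use node `"GLOBAL"`).
#' @export
metrics_long <- function(mt) {
  stopifnot(inherits(mt, "metric_table"))
  base <- data.frame(participant = mt$participant, condition = mt$condition,
                     band = mt$band, threshold = mt$threshold,
                     stringsAsFactors = FALSE)
  node_rows <- do.call(rbind, lapply(c("bc", "ne", "cc_local"), function(m) {
    cbind(base, node = mt$nodes$node, metric = m,
          value = mt$nodes[[m]], row.names = NULL)
  }))
  glob <- rbind(cbind(base, node = "GLOBAL", metric = "cc_global",
                      value = mt$cc_global),
                cbind(base, node = "GLOBAL", metric = "cpl",
                      value = mt$cpl))
  rbind(node_rows, glob)
}
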