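# Independent oracles and fixture builders.
#
# The graph oracle enumerates every simple path between every node pair by
# depth-first search and evaluates each metric straight from its defining
# formula. It shares no code with the package's Floyd-Warshall core beyond
# the tie tolerance, which both sides must agree on for shortest-path
# counting to be comparable.

oracle_tol <- 1e-10

# build a brain_graph directly from an adjacency (and optional weight)
# matrix, bypassing PLV machinery
make_graph <- function(adj, weights = NULL, labels = NULL) {
  n <- nrow(adj)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  if (is.null(weights)) weights <- adj
  dimnames(adj) <- dimnames(weights) <- list(labels, labels)
  structure(list(adjacency = adj, weights = weights * adj,
                 nodes = labels, regions = rep(NA_character_, n),
                 threshold = NA_real_, band = "test", condition = "test",
                 participant = "test"),
            class = "brain_graph")
}

# random undirected graph with given edge density; weights ~ U(0.5, 1)
random_graph <- function(n, density, weighted = TRUE) {
  adj <- matrix(0, n, n)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < density) {
        adj[i, j] <- adj[j, i] <- 1
        wij <- stats::runif(1, 0.5, 1)
        w[i, j] <- w[j, i] <- wij
      }
    }
  }
  make_graph(adj, if (weighted) w else NULL)
}

# enumerate all simple paths i -> j; returns list with min length and the
# multiset of intermediate-node sets of all minimal paths
oracle_paths <- function(len, i, j) {
  n <- nrow(len)
  best <- Inf
  minimal <- list()
  visit <- function(node, used, dist, inner) {
    if (dist > best + oracle_tol * max(1, best)) return()
    if (node == j) {
      if (dist < best - oracle_tol * max(1, abs(dist))) {
        best <<- dist
        minimal <<- list(inner)
      } else if (abs(dist - best) <= oracle_tol * max(1, abs(best))) {
        minimal[[length(minimal) + 1]] <<- inner
      }
      return()
    }
    for (k in seq_len(n)) {
      if (!used[k] && is.finite(len[node, k])) {
        used[k] <- TRUE
        visit(k, used, dist + len[node, k],
              if (k == j) inner else c(inner, k))
        used[k] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n)
  used[i] <- TRUE
  visit(i, used, 0, integer(0))
  # drop duplicate-length overshoot: keep only paths within tol of best
  keep <- vapply(minimal, function(x) TRUE, logical(1))
  list(dist = best, inner_sets = minimal[keep])
}

# direct-formula metrics for a small graph
oracle_metrics <- function(g, distance_mode = "one_minus_w") {
  n <- length(g$nodes)
  len <- switch(distance_mode,
    binary = ifelse(g$adjacency == 1, 1, Inf),
    one_minus_w = ifelse(g$adjacency == 1, 1 - g$weights, Inf),
    inverse_w = ifelse(g$adjacency == 1, 1 / g$weights, Inf))
  diag(len) <- Inf

  d <- matrix(Inf, n, n); diag(d) <- 0
  cnt <- matrix(0, n, n)
  paths <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pr <- oracle_paths(len, i, j)
      d[i, j] <- d[j, i] <- pr$dist
      cnt[i, j] <- cnt[j, i] <- length(pr$inner_sets)
      paths[[(i - 1) * n + j]] <- pr$inner_sets
    }
  }

  bc <- numeric(n)
  for (v in seq_len(n)) {
    total <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (i == v || j == v) next
        sets <- paths[[(i - 1) * n + j]]
        if (!length(sets)) next
        through <- sum(vapply(sets, function(s) v %in% s, logical(1)))
        total <- total + through / length(sets)
      }
    }
    bc[v] <- total / ((n - 1) * (n - 2) / 2)
  }

  inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  ne <- rowSums(inv) / (n - 1)

  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(g$adjacency[i, ] == 1)
    k <- length(nb)
    if (k >= 2) cc[i] <- sum(g$adjacency[nb, nb]) / (k * (k - 1))
  }

  fin <- d[upper.tri(d)]
  fin <- fin[is.finite(fin)]
  list(d = d, counts = cnt, bc = bc, ne = ne, cc_local = cc,
       cc_global = mean(cc),
       cpl = if (length(fin)) mean(fin) else NA_real_)
}

# Monte-Carlo mean resultant of a wrapped-normal phase difference
mc_wrapped_normal_plv <- function(sigma_x, sigma_y, n = 1e6, seed = 99) {
  set.seed(seed)
  d <- stats::rnorm(n, 0, sqrt(sigma_x^2 + sigma_y^2))
  Mod(mean(exp(1i * d)))
}

# named toy graphs used across tests
toy_star <- function(leaves = 5) {
  n <- leaves + 1
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  make_graph(adj)
}
toy_path3 <- function() {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  make_graph(adj, labels = c("A", "B", "C"))
}
toy_triangle <- function(w = NULL) {
  adj <- matrix(1, 3, 3); diag(adj) <- 0
  wm <- if (is.null(w)) NULL else matrix(w, 3, 3)
  make_graph(adj, wm)
}
# A-B, A-C, B-C, A-D
toy_paw <- function() {
  adj <- matrix(0, 4, 4, dimnames = NULL)
  adj[1, 2] <- adj[1, 3] <- adj[2, 3] <- adj[1, 4] <- 1
  adj <- adj + t(adj)
  make_graph(adj, labels = c("A", "B", "C", "D"))
}
toy_cycle4 <- function() {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- adj[4, 1] <- 1
  adj <- adj + t(adj)
  make_graph(adj)
}
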