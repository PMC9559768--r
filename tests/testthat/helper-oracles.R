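# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (and igraph): shortest paths by edge-list
# relaxation, path selection by exhaustive enumeration, point-in-polygon by
# winding number, simplification by full re-scan.

# Shortest distances from a set of source node indices by iterated
# relaxation over an undirected edge list (from, to, w). Returns a vector
# over nodes 1..n, Inf if unreachable.
oracle_relax_dist <- function(n, from, to, w, sources) {
  d <- rep(Inf, n)
  d[sources] <- 0
  repeat {
    d_new <- d
    cand_to <- tapply(d[from] + w, to, min)
    i_to <- as.integer(names(cand_to))
    d_new[i_to] <- pmin(d_new[i_to], cand_to)
    cand_fr <- tapply(d[to] + w, from, min)
    i_fr <- as.integer(names(cand_fr))
    d_new[i_fr] <- pmin(d_new[i_fr], cand_fr)
    if (all(d_new == d)) break
    d <- d_new
  }
  d
}

# Explicit cell graph of a friction grid (8-connected), as an edge list in
# column-major cell indices; independent of the package's grid_graph().
oracle_grid_edges <- function(values, cell_m) {
  nr <- nrow(values); nc <- ncol(values)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (is.na(values[r, cc])) next
      a <- (cc - 1) * nr + r
      for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(values[r2, c2])) next
        b <- (c2 - 1) * nr + r2
        from <- c(from, a); to <- c(to, b)
        w <- c(w, (values[r, cc] + values[r2, c2]) / 2 * cell_m * d[3])
      }
    }
  }
  list(from = from, to = to, w = w)
}

oracle_grid_times <- function(grid, fac_cells) {
  el <- oracle_grid_edges(grid$values, grid$cell_m)
  n <- length(grid$values)
  d <- oracle_relax_dist(n, el$from, el$to, el$w, fac_cells)
  d[is.na(grid$values)] <- Inf
  d
}

# All-optimal-path enumeration with lexicographic selection, on an
# adjacency list built from a plain edge table. node ids are integers.
oracle_adj <- function(nodes, edges) {
  adj <- vector("list", max(nodes))
  for (k in seq_along(edges$a)) {
    a <- edges$a[k]; b <- edges$b[k]; w <- edges$w[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w, k))
    adj[[b]] <- rbind(adj[[b]], c(a, w, k))
  }
  adj
}

# lexicographically smallest optimal s->d node sequence by DFS over the
# optimality condition; dist_d = oracle distances from d to every node.
oracle_lex_path <- function(adj, s, d, dist_d) {
  D <- dist_d[s]
  if (!is.finite(D)) return(NULL)
  eps <- 1e-9 * max(1, D)
  best <- NULL
  rec <- function(path, cost) {
    cur <- path[length(path)]
    if (cur == d) {
      if (is.null(best) || lex_less(path, best)) best <<- path
      return()
    }
    nb <- adj[[cur]]
    if (is.null(nb)) return()
    ord <- order(nb[, 1])
    for (i in ord) {
      nxt <- nb[i, 1]
      if (cost + nb[i, 2] + dist_d[nxt] <= D + eps) {
        rec(c(path, nxt), cost + nb[i, 2])
      }
    }
  }
  rec(s, 0)
  best
}

lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Brute-force targeted edge betweenness: for every origin, count in-range
# facilities (Euclidean), enumerate the lexicographically smallest optimal
# path to each, add 1/N per traversed edge. Edge weights in minutes are
# supplied directly; origins/facilities are given as snapped node ids.
oracle_tebc <- function(nodes, edges, origin_nodes, origin_xy,
                        fac_nodes, fac_xy, range_m) {
  adj <- oracle_adj(nodes, edges)
  score_terms <- lapply(seq_along(edges$a), function(i) numeric(0))
  for (i in seq_along(origin_nodes)) {
    d2 <- sqrt((fac_xy$x - origin_xy$x[i])^2 + (fac_xy$y - origin_xy$y[i])^2)
    inr <- which(d2 <= range_m)
    N <- length(inr)
    if (N == 0 || is.na(origin_nodes[i])) next
    for (fr in inr) {
      if (is.na(fac_nodes[fr])) next
      dist_d <- oracle_relax_dist(max(nodes), edges$a, edges$b, edges$w,
                                  fac_nodes[fr])
      p <- oracle_lex_path(adj, origin_nodes[i], fac_nodes[fr], dist_d)
      if (is.null(p) || length(p) < 2) next
      for (k in seq_len(length(p) - 1)) {
        hit <- which((edges$a == p[k] & edges$b == p[k + 1]) |
                       (edges$b == p[k] & edges$a == p[k + 1]))
        score_terms[[hit[1]]] <- c(score_terms[[hit[1]]], N)
      }
    }
  }
  # same exact reduction as the implementation: distinct N ascending
  vapply(score_terms, function(Ns) {
    if (!length(Ns)) return(0)
    tb <- table(Ns)
    sum(as.numeric(tb) / as.numeric(names(tb)))
  }, 0)
}

# Winding-number point-in-polygon (single ring), boundary counted inside.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  wn <- 0
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    if (point_segment_distance_oracle(px, py, x1, y1, x2, y2) <= 1e-9) return(TRUE)
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0) wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

point_segment_distance_oracle <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# Naive Visvalingam: full re-scan of all alive-vertex triangle areas at
# every iteration, same monotone carry and lowest-original-index tie rule.
oracle_visvalingam_order <- function(ring, retain_fraction) {
  n_total <- nrow(ring)
  target_total <- max(4L, as.integer(ceiling(retain_fraction * n_total)))
  pts <- ring[-n_total, , drop = FALSE]
  m <- nrow(pts)
  alive <- rep(TRUE, m)
  carry <- 0
  order_removed <- integer(0)
  tri <- function(a, b, c) {
    abs((pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[a, 2]) -
          (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[a, 1])) / 2
  }
  while (sum(alive) > target_total - 1L) {
    idx <- which(alive)
    areas <- vapply(seq_along(idx), function(j) {
      p <- idx[if (j == 1) length(idx) else j - 1]
      q <- idx[if (j == length(idx)) 1 else j + 1]
      tri(p, idx[j], q)
    }, 0)
    eff <- pmax(areas, carry)
    j <- which.min(eff)
    carry <- max(carry, areas[j])
    order_removed <- c(order_removed, idx[j])
    alive[idx[j]] <- FALSE
  }
  list(order = order_removed, keep = which(alive))
}

# Textbook Gini: mean absolute difference over twice the mean (double loop).
oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Tiny deterministic road network fixture: a 6-node two-route graph.
two_route_network <- function() {
  nodes <- tibble::tibble(node_id = 1:6,
                          x = c(0, 1000, 2000, 3000, 1000, 2000),
                          y = c(0, 0, 0, 0, 1500, 1500))
  edges <- tibble::tibble(
    edge_id = 1:6,
    node_a = c(1, 2, 3, 2, 5, 6),
    node_b = c(2, 3, 4, 5, 6, 4),
    road_class = c("primary", "trunk", "primary", "secondary", "secondary",
                   "secondary"))
  ia <- match(edges$node_a, nodes$node_id)
  ib <- match(edges$node_b, nodes$node_id)
  edges$length_m <- sqrt((nodes$x[ia] - nodes$x[ib])^2 +
                           (nodes$y[ia] - nodes$y[ib])^2)
  road_network(nodes, edges[, c("edge_id", "node_a", "node_b", "length_m",
                                "road_class")])
}

# Random connected road network for property tests.
random_test_network <- function(seed, n_nodes = 15) {
  withr::with_seed(seed, {
    x <- runif(n_nodes, 0, 10000)
    y <- runif(n_nodes, 0, 10000)
    a <- integer(0); b <- integer(0)
    for (i in 2:n_nodes) {
      d <- sqrt((x[1:(i - 1)] - x[i])^2 + (y[1:(i - 1)] - y[i])^2)
      a <- c(a, i); b <- c(b, which.min(d))
      if (i > 2 && runif(1) < 0.4) {
        a <- c(a, i); b <- c(b, order(d)[2])
      }
    }
    cls <- sample(c("trunk", "primary", "secondary", "tertiary", "track"),
                  length(a), replace = TRUE)
    edges <- tibble::tibble(edge_id = seq_along(a), node_a = a, node_b = b,
                            length_m = sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2),
                            road_class = cls)
    road_network(tibble::tibble(node_id = seq_len(n_nodes), x = x, y = y), edges)
  })
}
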