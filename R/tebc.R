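#' Population nuclei as routing origins
#'
#' Aggregates the population raster to coarser blocks (1 km by default) by
#' block sum and returns the centroid and population of every nonzero
#' block. These nuclei are the departure points of the criticality
#' analysis.
#'
#' @param pop a [population_grid()].
#' @param aggregation_cell_m block size in meters; must be an integer
#'   multiple of the population cell size.
#' @return An `origin_set` tibble: `origin_id`, `x`, `y`, `population`.
#' @export
population_nuclei <- function(pop, aggregation_cell_m = 1000) {
  ratio <- aggregation_cell_m / pop$cell_m
  fa_stopifnot(abs(ratio - round(ratio)) < 1e-9 && ratio >= 1,
               "aggregation_cell_m must be an integer multiple of the population cell size")
  nrb <- ceiling(nrow(pop$values) / ratio)
  ncb <- ceiling(ncol(pop$values) / ratio)
  target <- fa_grid(matrix(0, nrb, ncb), aggregation_cell_m, pop$x0, pop$y0,
                    crs = attr(pop, "crs"))
  agg <- resample_population(pop, target)
  nz <- which(agg$values > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    origin_id = seq_len(nrow(nz)),
    x = agg$x0 + (nz[, "col"] - 0.5) * aggregation_cell_m,
    y = agg$y0 - (nz[, "row"] - 0.5) * aggregation_cell_m,
    population = agg$values[nz])
  out <- out[order(out$x, out$y), ]
  out$origin_id <- seq_len(nrow(out))
  structure(out, class = c("origin_set", class(out)),
            aggregation_cell_m = aggregation_cell_m)
}

#' Destinations within range of an origin
#'
#' Facilities within Euclidean distance `range_m` (inclusive) of the origin
#' point — a planar buffer, not a network distance. `n` is counted before
#' any reachability check: unreachable in-range facilities still enter the
#' 1/N weight.
#'
#' @param origin list/row with `x`, `y`.
#' @param facilities tibble with `x`, `y`.
#' @param range_m buffer radius in meters (default 20 km).
#' @return List with `destinations` (the in-range facility subset) and `n`.
#' @export
select_destinations <- function(origin, facilities, range_m = 20000) {
  fa_stopifnot(range_m > 0, "`range_m` must be positive")
  d <- sqrt((facilities$x - origin$x)^2 + (facilities$y - origin$y)^2)
  keep <- d <= range_m
  list(destinations = facilities[keep, , drop = FALSE], n = sum(keep))
}

# Deterministic shortest path: the lexicographically smallest node-id
# sequence among all minimum-time paths from node s to node d.
# dist_from_d = distances from d to every vertex (row vector, graph order).
lex_shortest_path <- function(graph, s_idx, d_idx, dist_from_d) {
  D <- dist_from_d[s_idx]
  if (!is.finite(D)) return(NULL)
  ids <- as.numeric(igraph::V(graph)$name)
  path <- s_idx
  cur <- s_idx
  cost <- 0
  eps <- 1e-9 * max(1, D)
  while (cur != d_idx) {
    nb <- as.integer(igraph::neighbors(graph, cur))
    eids <- igraph::get_edge_ids(graph, rbind(rep(cur, length(nb)), nb))
    w <- igraph::E(graph)$weight[eids]
    ok <- cost + w + dist_from_d[nb] <= D + eps
    cand <- nb[ok]
    if (!length(cand)) return(NULL)   # numerical dead end; treat unreachable
    pick <- cand[which.min(ids[cand])]
    cost <- cost + w[ok][which.min(ids[cand])]
    path <- c(path, pick)
    cur <- pick
    if (length(path) > igraph::vcount(graph)) return(NULL)
  }
  path
}

#' Targeted edge betweenness centrality
#'
#' Scores every road segment by its usage frequency among shortest
#' (minimum-travel-time) paths from population nuclei to the health
#' facilities within a 20 km planar buffer of each nucleus. For an origin
#' `s` with `N_s` in-range facilities, every edge on the selected path to
#' each in-range facility gains `1/N_s`; pairs that are unreachable in the
#' graph contribute nothing but still count in `N_s`. With equal-cost path
#' ties the lexicographically smallest node-id sequence is selected, so
#' scores are reproducible. Origins or facilities that snap to no graph
#' node within `max_snap_m` are skipped and counted in the attributes.
#'
#' @param graph a `travel_graph` ([build_graph()], possibly flood-disrupted).
#' @param origins an [population_nuclei()] tibble (columns `x`, `y`,
#'   `population`).
#' @param facilities tibble with `x`, `y`.
#' @param range_m destination buffer radius in meters.
#' @param max_snap_m snapping tolerance for origins and facilities.
#' @return A `tebc_field` tibble: `edge_id`, `score`; attribute `origins`
#'   holds per-origin `n_destinations`, `n_reached` and `path_edges` (total
#'   edge count over its selected paths), attribute `n_skipped` the origins
#'   with no snap or no in-range destination.
#' @export
tebc_scores <- function(graph, origins, facilities, range_m = 20000,
                        max_snap_m = 2000) {
  edge_ids <- igraph::E(graph)$edge_id
  zero <- tibble::tibble(edge_id = sort(edge_ids), score = 0)
  if (igraph::vcount(graph) == 0 || nrow(origins) == 0 || nrow(facilities) == 0) {
    if (igraph::vcount(graph) == 0) warning("empty graph: all TEBC scores 0")
    return(structure(zero, class = c("tebc_field", class(zero)),
                     origins = tibble::tibble(origin_id = integer(0),
                                              n_destinations = integer(0),
                                              n_reached = integer(0),
                                              path_edges = integer(0)),
                     n_skipped = nrow(origins)))
  }
  o_snap <- snap_points(origins, graph, max_snap_m)
  f_snap <- snap_points(facilities, graph, max_snap_m)
  vnames <- igraph::V(graph)$name
  f_idx <- match(as.character(f_snap$node_id), vnames)
  usable_f <- which(!is.na(f_snap$node_id))
  dist_from_f <- matrix(Inf, nrow(facilities), length(vnames))
  if (length(usable_f)) {
    dist_from_f[usable_f, ] <- igraph::distances(graph, v = f_idx[usable_f])
  }
  edge_pos <- stats::setNames(seq_along(edge_ids), as.character(edge_ids))
  contrib_edge <- integer(0); contrib_N <- integer(0)
  org_stats <- tibble::tibble(origin_id = seq_len(nrow(origins)),
                              n_destinations = 0L, n_reached = 0L,
                              path_edges = 0L)
  n_skipped <- 0L
  for (i in seq_len(nrow(origins))) {
    sel <- select_destinations(origins[i, ], facilities, range_m)
    org_stats$n_destinations[i] <- sel$n
    if (is.na(o_snap$node_id[i]) || sel$n == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    s_idx <- match(as.character(o_snap$node_id[i]), vnames)
    dest_rows <- which(sqrt((facilities$x - origins$x[i])^2 +
                              (facilities$y - origins$y[i])^2) <= range_m)
    for (fr in dest_rows) {
      if (is.na(f_snap$node_id[fr])) next
      d_idx <- f_idx[fr]
      if (s_idx == d_idx) {
        org_stats$n_reached[i] <- org_stats$n_reached[i] + 1L
        next
      }
      path <- lex_shortest_path(graph, s_idx, d_idx, dist_from_f[fr, ])
      if (is.null(path)) next
      org_stats$n_reached[i] <- org_stats$n_reached[i] + 1L
      org_stats$path_edges[i] <- org_stats$path_edges[i] + length(path) - 1L
      eids <- igraph::get_edge_ids(graph, rbind(path[-length(path)], path[-1]))
      pe <- edge_pos[as.character(igraph::E(graph)$edge_id[eids])]
      contrib_edge <- c(contrib_edge, pe)
      contrib_N <- c(contrib_N, rep(sel$n, length(pe)))
    }
  }
  # exact reduction: per edge, sum count/N over distinct N in ascending order
  score <- rep(0, length(edge_ids))
  if (length(contrib_edge)) {
    tab <- tibble::tibble(e = contrib_edge, N = contrib_N)
    tab <- dplyr::summarise(dplyr::group_by(tab, .data$e, .data$N),
                            count = dplyr::n(), .groups = "drop")
    tab <- tab[order(tab$e, tab$N), ]
    add <- rowsum(tab$count / tab$N, tab$e)
    score[as.integer(rownames(add))] <- as.numeric(add)
  }
  out <- tibble::tibble(edge_id = edge_ids, score = score)
  out <- out[order(out$edge_id), ]
  structure(out, class = c("tebc_field", class(out)),
            origins = org_stats, n_skipped = n_skipped, range_m = range_m)
}

#' Normal-vs-flood criticality deltas
#'
#' Joins the normal and flooded TEBC fields and classes every edge:
#' `FLOODED` (removed by the flood), `LOST` (positive score reduced to zero
#' though the edge survived), `DECREASED`, `UNCHANGED` (|delta| <= eps), or
#' `BACKUP_INCREASED` (score rose — the edge absorbs rerouted access paths
#' and acts as a backup road).
#'
#' @param normal,flooded `tebc_field`s; the flooded field's edge universe
#'   must equal the normal one minus `flooded_edges`.
#' @param flooded_edges edge ids removed by the flood.
#' @param eps tolerance for `UNCHANGED`.
#' @return An `edge_criticality` tibble: `edge_id`, `score_normal`,
#'   `score_flood`, `delta`, `class`.
#' @export
tebc_delta <- function(normal, flooded, flooded_edges, eps = 1e-9) {
  missing_ok <- setdiff(normal$edge_id, flooded$edge_id)
  fa_stopifnot(length(setdiff(missing_ok, flooded_edges)) == 0 &&
                 length(setdiff(flooded$edge_id, normal$edge_id)) == 0,
               "edge sets differ beyond the flooded edges")
  sf <- flooded$score[match(normal$edge_id, flooded$edge_id)]
  sf[is.na(sf)] <- 0
  delta <- sf - normal$score
  cls <- rep("UNCHANGED", nrow(normal))
  cls[delta > eps] <- "BACKUP_INCREASED"
  cls[delta < -eps] <- "DECREASED"
  cls[normal$score > eps & sf <= eps & delta < -eps] <- "LOST"
  cls[normal$edge_id %in% flooded_edges] <- "FLOODED"
  out <- tibble::tibble(edge_id = normal$edge_id,
                        score_normal = normal$score, score_flood = sf,
                        delta = delta, class = cls)
  structure(out, class = c("edge_criticality", class(out)))
}

#' Dispersion of a TEBC field
#'
#' A similar score on every segment means many alternative routes (low
#' criticality); a wide range means the network depends on a few main axes.
#' Summarised as the maximum score and the Gini coefficient of the positive
#' scores.
#'
#' @param field a `tebc_field`.
#' @return A one-row tibble `max_score`, `gini`, `n_positive`; when every
#'   score is zero the Gini is reported as 0 with attribute
#'   `all_zero = TRUE`.
#' @export
tebc_dispersion <- function(field) {
  fa_stopifnot(nrow(field) > 0, "empty TEBC field")
  pos <- field$score[field$score > 0]
  if (length(pos) == 0) {
    out <- tibble::tibble(max_score = 0, gini = 0, n_positive = 0L)
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  tibble::tibble(max_score = max(field$score), gini = gini_coefficient(pos),
                 n_positive = length(pos))
}

# Gini of a non-negative vector: mean absolute difference over twice the mean.
gini_coefficient <- function(x) {
  n <- length(x)
  if (n == 1) return(0)
  xs <- sort(x)
  # sum_i sum_j |xi - xj| = 2 * sum_i (2i - n - 1) * x_(i)
  num <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  num / (2 * n^2 * mean(x))
}
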