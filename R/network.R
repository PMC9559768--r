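#' Road networks and travel-time graphs
#'
#' A road network is a planar-embedded undirected graph of classed road
#' segments: a node table (id, x, y in projected meters) and an edge table
#' (id, endpoints, length in meters, road class). A travel graph is the
#' igraph representation weighted in minutes under a speed profile.
#'
#' @param nodes tibble/data.frame with columns `node_id`, `x`, `y`.
#' @param edges tibble/data.frame with columns `edge_id`, `node_a`,
#'   `node_b`, `length_m`, `road_class`.
#' @param crs coordinate reference string.
#' @return An object of class `road_network`.
#' @export
road_network <- function(nodes, edges, crs = default_crs()) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  fa_stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
               "`nodes` needs columns node_id, x, y")
  fa_stopifnot(all(c("edge_id", "node_a", "node_b", "length_m", "road_class") %in%
                     names(edges)),
               "`edges` needs columns edge_id, node_a, node_b, length_m, road_class")
  fa_stopifnot(!anyDuplicated(nodes$node_id), "duplicate node_id")
  fa_stopifnot(!anyDuplicated(edges$edge_id), "duplicate edge_id")
  fa_stopifnot(!any(edges$node_a == edges$node_b), "self-loop edges are not allowed")
  fa_stopifnot(all(edges$node_a %in% nodes$node_id) &&
                 all(edges$node_b %in% nodes$node_id),
               "edge endpoints must reference node_ids")
  ia <- match(edges$node_a, nodes$node_id)
  ib <- match(edges$node_b, nodes$node_id)
  eu <- sqrt((nodes$x[ia] - nodes$x[ib])^2 + (nodes$y[ia] - nodes$y[ib])^2)
  fa_stopifnot(all(edges$length_m >= eu - 1e-3),
               "length_m below Euclidean endpoint distance")
  net <- structure(list(nodes = nodes, edges = edges), class = "road_network")
  attr(net, "crs") <- crs
  net
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(names(sort(table(x$edges$road_class), decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

ROAD_CLASSES <- c("trunk", "primary", "secondary", "tertiary",
                  "unclassified", "track", "path")

#' Speed profiles
#'
#' Travel speeds per road class in km/h, plus the off-road (bare-ground)
#' walking speed used when building friction surfaces. Driving does not
#' traverse `path`-class segments; walking traverses every class at a flat
#' speed. Defaults: driving trunk 80, primary 60, secondary 50, tertiary 40,
#' unclassified 30, track 10 km/h; walking 5 km/h on any class; off-road
#' 2.5 km/h (the bare-ground walking speed on which a 1 km cell costs
#' 24 min, against 6 min for a motorized vehicle on a track).
#'
#' @param mode `"driving"` or `"walking"`.
#' @param speeds named numeric vector of km/h overriding the defaults.
#' @param offroad_kmh off-road walking speed, km/h.
#' @return An object of class `speed_profile`.
#' @export
#' @examples
#' speed_profile("driving")$speeds[["track"]]  # 10 km/h
speed_profile <- function(mode = c("driving", "walking"), speeds = NULL,
                          offroad_kmh = 2.5) {
  mode <- match.arg(mode)
  def <- if (mode == "driving") {
    c(trunk = 80, primary = 60, secondary = 50, tertiary = 40,
      unclassified = 30, track = 10)
  } else {
    stats::setNames(rep(5, length(ROAD_CLASSES)), ROAD_CLASSES)
  }
  if (!is.null(speeds)) def[names(speeds)] <- speeds
  fa_stopifnot(all(def > 0), "speeds must be positive")
  structure(list(mode = mode, speeds = def, traversable = names(def),
                 offroad_kmh = offroad_kmh),
            class = "speed_profile")
}

# minutes to traverse length_m at speed_kmh
travel_minutes <- function(length_m, speed_kmh) {
  length_m / (speed_kmh * 1000 / 60)
}

#' Build a travel-time-weighted graph
#'
#' Keeps exactly the edges whose class the profile traverses; each edge is
#' weighted in minutes as `length_m / (speed_kmh * 1000 / 60)`. Node
#' coordinates and source `edge_id`s are carried as attributes so floods
#' and criticality scores can refer back to the road network.
#'
#' @param network a [road_network()].
#' @param profile a [speed_profile()].
#' @return An igraph object of class `travel_graph`.
#' @export
build_graph <- function(network, profile) {
  fa_stopifnot(inherits(network, "road_network"), "`network` must be a road_network")
  fa_stopifnot(inherits(profile, "speed_profile"), "`profile` must be a speed_profile")
  unknown <- setdiff(unique(network$edges$road_class), ROAD_CLASSES)
  if (length(unknown)) {
    bad <- network$edges$edge_id[network$edges$road_class %in% unknown][1]
    stop(sprintf("unknown road_class '%s' (edge_id %s)", unknown[1], bad),
         call. = FALSE)
  }
  edges <- network$edges[network$edges$road_class %in% profile$traversable, ,
                         drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$node_a),
                   to = as.character(edges$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$node_id),
                          x = network$nodes$x, y = network$nodes$y))
  igraph::E(g)$weight <- travel_minutes(
    edges$length_m, unname(profile$speeds[edges$road_class]))
  igraph::E(g)$edge_id <- edges$edge_id
  attr(g, "profile_mode") <- profile$mode
  class(g) <- c("travel_graph", class(g))
  g
}

graph_coords <- function(graph) {
  tibble::tibble(node_id = as.integer(igraph::V(graph)$name),
                 x = igraph::V(graph)$x, y = igraph::V(graph)$y)
}

#' Apply a flood mask to a travel graph
#'
#' Every node whose coordinates fall inside the flood union (boundary
#' included) is removed together with its incident edges; nothing else
#' changes. This mirrors node-based network disruption and shares its known
#' blind spot: an edge whose interior crosses the mask while both endpoints
#' stay dry is kept. `strict = TRUE` additionally drops such
#' interior-crossing edges.
#'
#' @param graph a [build_graph()] result.
#' @param flood a [flood_mask()]; an empty mask returns the graph unchanged.
#' @param strict also remove dry-ended edges whose segment crosses the mask.
#' @return A `travel_graph`; attribute `removed_nodes` lists removed node ids.
#' @export
apply_flood_to_graph <- function(graph, flood, strict = FALSE) {
  fa_stopifnot(inherits(flood, "flood_mask"), "`flood` must be a flood_mask")
  if (is_empty_mask(flood)) {
    attr(graph, "removed_nodes") <- integer(0)
    return(graph)
  }
  xy <- graph_coords(graph)
  wet <- points_in_mask(xy$x, xy$y, flood)
  g2 <- igraph::delete_vertices(graph, which(wet))
  if (strict && igraph::ecount(g2) > 0) {
    co <- graph_coords(g2)
    ends <- igraph::ends(g2, igraph::E(g2), names = TRUE)
    ia <- match(ends[, 1], as.character(co$node_id))
    ib <- match(ends[, 2], as.character(co$node_id))
    cross <- vapply(seq_len(nrow(ends)), function(k) {
      segment_crosses_mask(co$x[ia[k]], co$y[ia[k]], co$x[ib[k]], co$y[ib[k]], flood)
    }, TRUE)
    g2 <- igraph::delete_edges(g2, which(cross))
  }
  class(g2) <- c("travel_graph", class(g2))
  attr(g2, "profile_mode") <- attr(graph, "profile_mode")
  attr(g2, "removed_nodes") <- xy$node_id[wet]
  g2
}

segment_crosses_mask <- function(x1, y1, x2, y2, mask) {
  if (point_in_mask((x1 + x2) / 2, (y1 + y2) / 2, mask)) return(TRUE)
  for (polygon in mask$polygons) {
    for (ring in polygon) {
      n <- nrow(ring)
      for (k in seq_len(n - 1)) {
        if (segments_intersect(c(x1, y1), c(x2, y2),
                               ring[k, ], ring[k + 1, ])) return(TRUE)
      }
    }
  }
  FALSE
}

#' Snap points to the nearest network node
#'
#' Each point maps to the nearest node within `max_snap_m` (ties broken by
#' the smallest node id); points farther than that are flagged unsnapped
#' with `NA`.
#'
#' @param points data.frame/tibble with columns `x`, `y`.
#' @param network a [road_network()] or `travel_graph` (its remaining nodes).
#' @param max_snap_m maximum snapping distance in meters.
#' @return The input tibble with columns `node_id` (NA if unsnapped) and
#'   `snap_dist_m` appended.
#' @export
snap_points <- function(points, network, max_snap_m = 2000) {
  fa_stopifnot(max_snap_m > 0, "`max_snap_m` must be positive")
  nodes <- if (inherits(network, "road_network")) network$nodes else graph_coords(network)
  ord <- order(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  pts <- tibble::as_tibble(points)
  n <- nrow(pts)
  node_id <- rep(NA_integer_, n)
  dist_m <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sqrt((nodes$x - pts$x[i])^2 + (nodes$y - pts$y[i])^2)
    j <- which.min(d)   # first minimum = smallest node_id after ordering
    if (length(j) && d[j] <= max_snap_m) {
      node_id[i] <- as.integer(nodes$node_id[j])
      dist_m[i] <- d[j]
    }
  }
  pts$node_id <- node_id
  pts$snap_dist_m <- dist_m
  pts
}

#' Travel time from every node to its nearest facility
#'
#' Multi-source shortest-path times over the travel graph: each node gets
#' the minimum time in minutes to any snapped facility node. Facility nodes
#' score 0; nodes with no path to any facility are `NA` (unreachable).
#'
#' @param graph a `travel_graph`.
#' @param facilities tibble with columns `x`, `y` (e.g. [gen_facilities()]).
#' @param max_snap_m facility snapping tolerance in meters.
#' @return A tibble `node_id`, `x`, `y`, `time_min` of class `node_time_field`.
#' @export
node_access_times <- function(graph, facilities, max_snap_m = 2000) {
  co <- graph_coords(graph)
  out <- co
  if (igraph::vcount(graph) == 0 || nrow(facilities) == 0) {
    out$time_min <- rep(NA_real_, nrow(co))
    return(structure(out, class = c("node_time_field", class(out))))
  }
  snapped <- snap_points(facilities, graph, max_snap_m)
  src <- unique(stats::na.omit(snapped$node_id))
  if (length(src) == 0) {
    out$time_min <- rep(NA_real_, nrow(co))
    warning("no facility snapped to the graph; all nodes unreachable")
    return(structure(out, class = c("node_time_field", class(out))))
  }
  d <- igraph::distances(graph, v = match(as.character(src),
                                          igraph::V(graph)$name))
  tmin <- apply(d, 2, min)
  tmin[!is.finite(tmin)] <- NA_real_
  out$time_min <- as.numeric(tmin)
  structure(out, class = c("node_time_field", class(out)))
}
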