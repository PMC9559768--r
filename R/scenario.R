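#' Synthetic scenario configuration
#'
#' Controls the seeded scenario generator: a classed road network with a
#' sparse trunk skeleton and denser local roads, clustered population with
#' mostly empty 100 m cells, facilities jittered near network nodes, a
#' minutes-per-meter friction surface on 1 km cells, and a ribbon-shaped
#' flood polygon that severs part of the network.
#'
#' @param n_trunk_nodes,n_local_nodes node counts for the trunk skeleton and
#'   the attached local roads.
#' @param n_facilities number of health facilities.
#' @param n_population_clusters number of population settlement clusters.
#' @param total_population total person count; the generated raster sums to
#'   it exactly.
#' @param population_cell_m,friction_cell_m raster resolutions in meters;
#'   the population cell size must divide the friction cell size.
#' @param flood_width_m width of the flood ribbon.
#' @param flood_crosses_trunk anchor the ribbon on a trunk node so it severs
#'   the trunk skeleton.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_trunk_nodes = 12, n_local_nodes = 80,
                            n_facilities = 6, n_population_clusters = 8,
                            total_population = 50000,
                            population_cell_m = 100, friction_cell_m = 1000,
                            flood_width_m = 1500, flood_crosses_trunk = TRUE) {
  cfg <- list(n_trunk_nodes = as.integer(n_trunk_nodes),
              n_local_nodes = as.integer(n_local_nodes),
              n_facilities = as.integer(n_facilities),
              n_population_clusters = as.integer(n_population_clusters),
              total_population = as.integer(total_population),
              population_cell_m = population_cell_m,
              friction_cell_m = friction_cell_m,
              flood_width_m = flood_width_m,
              flood_crosses_trunk = isTRUE(flood_crosses_trunk))
  counts <- c(cfg$n_trunk_nodes, cfg$n_local_nodes, cfg$n_facilities,
              cfg$n_population_clusters, cfg$total_population)
  fa_stopifnot(all(counts >= 1), "all counts must be >= 1")
  fa_stopifnot(cfg$population_cell_m > 0 && cfg$friction_cell_m > 0,
               "cell sizes must be positive")
  ratio <- cfg$friction_cell_m / cfg$population_cell_m
  fa_stopifnot(abs(ratio - round(ratio)) < 1e-9,
               "population_cell_m must divide friction_cell_m")
  structure(cfg, class = "scenario_config")
}

#' Generate a synthetic classed road network
#'
#' Trunk nodes are spread over the extent and joined by their Euclidean
#' minimum spanning tree (class `trunk`) plus a few redundancy links (class
#' `primary`), giving a connected skeleton with detours. Local nodes attach
#' one by one to their nearest already-placed node via `secondary` /
#' `tertiary` / `unclassified` / `track` edges, with occasional second
#' links that close loops. Edge geometry is the straight segment between
#' endpoints, so `length_m` equals the Euclidean distance.
#'
#' @param seed integer seed; the generator is a pure function of
#'   `(seed, extent, config)`.
#' @param extent `c(xmin, ymin, xmax, ymax)` in projected meters.
#' @param config a [scenario_config()].
#' @return A [road_network()].
#' @export
gen_road_network <- function(seed, extent, config = scenario_config()) {
  check_extent(extent)
  nt <- config$n_trunk_nodes
  nl <- config$n_local_nodes
  withr::with_seed(fa_seed(seed, 11L), {
    w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
    tx <- runif(nt, extent[1] + 0.05 * w, extent[3] - 0.05 * w)
    ty <- runif(nt, extent[2] + 0.05 * h, extent[4] - 0.05 * h)
    edges <- list()
    if (nt > 1) {
      dmat <- as.matrix(stats::dist(cbind(tx, ty)))
      gfull <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                   weighted = TRUE)
      mst <- igraph::mst(gfull)
      me <- igraph::as_edgelist(mst)
      edges[[1]] <- tibble::tibble(node_a = as.integer(me[, 1]),
                                   node_b = as.integer(me[, 2]),
                                   road_class = "trunk")
      # redundancy links: each trunk node may link to its nearest non-neighbour
      extra_a <- integer(0); extra_b <- integer(0)
      add <- runif(nt) < 0.35
      for (i in which(add)) {
        nb <- as.integer(igraph::neighbors(mst, i))
        cand <- setdiff(order(dmat[i, ]), c(i, nb))
        if (length(cand)) {
          j <- cand[1]
          if (!any((extra_a == j & extra_b == i) | (extra_a == i & extra_b == j))) {
            extra_a <- c(extra_a, i); extra_b <- c(extra_b, j)
          }
        }
      }
      if (length(extra_a)) {
        edges[[2]] <- tibble::tibble(node_a = extra_a, node_b = extra_b,
                                     road_class = "primary")
      }
    }
    lx <- runif(nl, extent[1], extent[3])
    ly <- runif(nl, extent[2], extent[4])
    all_x <- c(tx, lx); all_y <- c(ty, ly)
    local_classes <- sample(c("secondary", "tertiary", "unclassified", "track"),
                            nl, replace = TRUE, prob = c(0.2, 0.3, 0.15, 0.35))
    la <- integer(nl); lb <- integer(nl)
    extra <- list()
    for (k in seq_len(nl)) {
      i <- nt + k
      prev <- seq_len(i - 1)
      d <- sqrt((all_x[prev] - all_x[i])^2 + (all_y[prev] - all_y[i])^2)
      j <- which.min(d)
      la[k] <- i; lb[k] <- j
      if (length(prev) > 1 && runif(1) < 0.15) {
        j2 <- order(d)[2]
        extra[[length(extra) + 1]] <- c(i, j2)
      }
    }
    edges[[length(edges) + 1]] <- tibble::tibble(node_a = la, node_b = lb,
                                                 road_class = local_classes)
    if (length(extra)) {
      ex <- do.call(rbind, extra)
      edges[[length(edges) + 1]] <- tibble::tibble(
        node_a = ex[, 1], node_b = ex[, 2],
        road_class = sample(c("tertiary", "track"), nrow(ex), replace = TRUE))
    }
    ed <- dplyr::bind_rows(edges)
    ed$edge_id <- seq_len(nrow(ed))
    ed$length_m <- sqrt((all_x[ed$node_a] - all_x[ed$node_b])^2 +
                          (all_y[ed$node_a] - all_y[ed$node_b])^2)
    nodes <- tibble::tibble(node_id = seq_along(all_x), x = all_x, y = all_y)
    road_network(nodes, ed[, c("edge_id", "node_a", "node_b", "length_m",
                               "road_class")])
  })
}

#' Generate a clustered population raster
#'
#' Persons are allocated to `n_population_clusters` settlement centers with
#' log-normal cluster masses, scattered around each center with a Gaussian
#' spread, and binned into `population_cell_m` cells. The raster sum equals
#' `total_population` exactly; most cells are empty, as in gridded census
#' products for sparsely settled regions.
#'
#' @inheritParams gen_road_network
#' @return A [population_grid()].
#' @export
gen_population_grid <- function(seed, extent, config = scenario_config()) {
  check_extent(extent)
  fa_stopifnot(config$total_population > 0, "total_population must be positive")
  withr::with_seed(fa_seed(seed, 23L), {
    w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
    k <- config$n_population_clusters
    cx <- runif(k, extent[1] + 0.1 * w, extent[3] - 0.1 * w)
    cy <- runif(k, extent[2] + 0.1 * h, extent[4] - 0.1 * h)
    mass <- rlnorm(k, meanlog = 0, sdlog = 1)
    counts <- as.vector(rmultinom(1, config$total_population, mass / sum(mass)))
    spread <- min(w, h) * 0.04
    px <- rep(cx, counts) + rnorm(sum(counts), 0, spread)
    py <- rep(cy, counts) + rnorm(sum(counts), 0, spread)
    eps <- config$population_cell_m * 1e-3
    px <- pmin(pmax(px, extent[1]), extent[3] - eps)
    py <- pmin(pmax(py, extent[2]), extent[4] - eps)
    nc <- ceiling(w / config$population_cell_m)
    nr <- ceiling(h / config$population_cell_m)
    col <- floor((px - extent[1]) / config$population_cell_m) + 1
    row <- floor((extent[4] - py) / config$population_cell_m) + 1
    v <- matrix(0, nr, nc)
    tab <- table(factor((col - 1) * nr + row, levels = seq_len(nr * nc)))
    v[] <- as.numeric(tab)
    population_grid(v, config$population_cell_m, extent[1], extent[4])
  })
}

#' Generate a friction surface from a road network
#'
#' Each friction cell costs `60 / (1000 * v)` minutes per meter, where `v`
#' (km/h) is the fastest road class rasterized into the cell — a road class
#' is "in" a cell when the cell center lies within half a cell diagonal of
#' a segment of that class — and the off-road walking speed otherwise. On
#' 1 km cells the defaults reproduce the 6 min (motorized track) and 24 min
#' (bare-ground walking) cell traversal times.
#'
#' @inheritParams gen_road_network
#' @param road_network a [road_network()] within the extent.
#' @param profile a [speed_profile()]; its `offroad_kmh` sets the off-road
#'   cost.
#' @return A [friction_grid()].
#' @export
gen_friction_grid <- function(road_network, extent, config = scenario_config(),
                              profile = speed_profile("driving")) {
  check_extent(extent)
  fa_stopifnot(config$friction_cell_m > 0, "cell size must be positive")
  cell <- config$friction_cell_m
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  nc <- ceiling(w / cell); nr <- ceiling(h / cell)
  g0 <- fa_grid(matrix(0, nr, nc), cell, extent[1], extent[4])
  cc <- grid_cell_centers(g0)
  halfdiag <- cell * sqrt(2) / 2
  best_speed <- rep(profile$offroad_kmh, nr * nc)
  nodes <- road_network$nodes
  ed <- road_network$edges
  ia <- match(ed$node_a, nodes$node_id)
  ib <- match(ed$node_b, nodes$node_id)
  for (e in seq_len(nrow(ed))) {
    cls <- ed$road_class[e]
    if (!cls %in% names(profile$speeds)) next
    v_kmh <- unname(profile$speeds[cls])
    ax <- nodes$x[ia[e]]; ay <- nodes$y[ia[e]]
    bx <- nodes$x[ib[e]]; by <- nodes$y[ib[e]]
    near <- cc$x >= min(ax, bx) - halfdiag & cc$x <= max(ax, bx) + halfdiag &
      cc$y >= min(ay, by) - halfdiag & cc$y <= max(ay, by) + halfdiag
    if (!any(near)) next
    d <- point_segment_distance(cc$x[near], cc$y[near], ax, ay, bx, by)
    hit <- which(near)[d <= halfdiag]
    best_speed[hit] <- pmax(best_speed[hit], v_kmh)
  }
  cost <- 60 / (1000 * best_speed)
  friction_grid(matrix(cost, nr, nc), cell, extent[1], extent[4])
}

#' Place health facilities near network nodes
#'
#' Facilities are placed within a small uniform jitter (at most 200 m) of
#' randomly chosen distinct network nodes.
#'
#' @param seed integer seed.
#' @param road_network a [road_network()].
#' @param n number of facilities (at most the node count).
#' @return A tibble `facility_id`, `x`, `y` of class `facility_set`.
#' @export
gen_facilities <- function(seed, road_network, n) {
  fa_stopifnot(n >= 1, "`n` must be >= 1")
  fa_stopifnot(n <= nrow(road_network$nodes),
               sprintf("n (%d) exceeds node count (%d)", n, nrow(road_network$nodes)))
  withr::with_seed(fa_seed(seed, 37L), {
    pick <- sample(nrow(road_network$nodes), n)
    r <- runif(n, 0, 200)
    th <- runif(n, 0, 2 * pi)
    out <- tibble::tibble(
      facility_id = seq_len(n),
      x = road_network$nodes$x[pick] + r * cos(th),
      y = road_network$nodes$y[pick] + r * sin(th))
    structure(out, class = c("facility_set", class(out)))
  })
}

#' Generate a ribbon-shaped flood mask
#'
#' A buffered near-vertical polyline crossing the full extent, emulating a
#' river-valley flood. If `config$flood_crosses_trunk` and a network is
#' supplied, the ribbon is anchored on a trunk(-or-primary) node so that at
#' least one trunk-skeleton edge has a node inside the polygon.
#'
#' @inheritParams gen_road_network
#' @param network optional [road_network()] used to anchor the ribbon.
#' @return A [flood_mask()] with one ribbon polygon.
#' @export
gen_flood_mask <- function(seed, extent, config = scenario_config(),
                           network = NULL) {
  check_extent(extent)
  fa_stopifnot(config$flood_width_m > 0, "flood_width_m must be positive")
  withr::with_seed(fa_seed(seed, 53L), {
    w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
    n_pts <- 9
    yy <- seq(extent[2], extent[4], length.out = n_pts)
    wiggle <- cumsum(rnorm(n_pts, 0, w * 0.03))
    anchor_x <- runif(1, extent[1] + 0.3 * w, extent[3] - 0.3 * w)
    anchor_y <- (extent[2] + extent[4]) / 2
    if (isTRUE(config$flood_crosses_trunk) && !is.null(network)) {
      trunk_edges <- network$edges[network$edges$road_class %in%
                                     c("trunk", "primary"), , drop = FALSE]
      trunk_ids <- unique(c(trunk_edges$node_a, trunk_edges$node_b))
      if (length(trunk_ids)) {
        node <- network$nodes[network$nodes$node_id ==
                                sample(trunk_ids, 1), , drop = FALSE]
        anchor_x <- node$x[1]; anchor_y <- node$y[1]
      }
    }
    # shift the wiggly line so it passes through (anchor_x, anchor_y)
    x_at_anchor <- stats::approx(yy, wiggle, xout = anchor_y, rule = 2)$y
    xx <- wiggle - x_at_anchor + anchor_x
    ring <- ribbon_polygon(xx, yy, config$flood_width_m)
    ring[, 1] <- pmin(pmax(ring[, 1], extent[1]), extent[3])
    ring[, 2] <- pmin(pmax(ring[, 2], extent[2]), extent[4])
    flood_mask(list(ring))
  })
}

# Buffer a polyline (near-vertical) into a simple ribbon polygon by
# offsetting each vertex along the local normal.
ribbon_polygon <- function(xx, yy, width_m) {
  n <- length(xx)
  dx <- c(xx[2] - xx[1], xx[-1] - xx[-n])
  dy <- c(yy[2] - yy[1], yy[-1] - yy[-n])
  len <- sqrt(dx^2 + dy^2)
  nx <- -dy / len; ny <- dx / len
  half <- width_m / 2
  left <- cbind(xx + nx * half, yy + ny * half)
  right <- cbind(xx - nx * half, yy - ny * half)
  ring <- rbind(left, right[n:1, , drop = FALSE], left[1, , drop = FALSE])
  ring
}

#' Generate a complete synthetic scenario
#'
#' Assembles network, facilities, population, friction and flood from one
#' seed; identical `(seed, config, extent)` yields identical scenarios.
#'
#' @inheritParams gen_road_network
#' @param profile a [speed_profile()] used for the friction surface.
#' @return A `scenario` list with elements `seed`, `extent`, `road_network`,
#'   `facilities`, `population`, `friction`, `flood`, `config`.
#' @export
gen_scenario <- function(seed, config = scenario_config(),
                         extent = c(0, 0, 20000, 20000),
                         profile = speed_profile("driving")) {
  check_extent(extent)
  net <- gen_road_network(seed, extent, config)
  structure(list(
    seed = seed,
    extent = extent,
    road_network = net,
    facilities = gen_facilities(seed, net, config$n_facilities),
    population = gen_population_grid(seed, extent, config),
    friction = gen_friction_grid(net, extent, config, profile),
    flood = gen_flood_mask(seed, extent, config, network = net),
    config = config), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> seed %s, extent %g x %g km\n", format(x$seed),
              (x$extent[3] - x$extent[1]) / 1000,
              (x$extent[4] - x$extent[2]) / 1000))
  print(x$road_network)
  cat(sprintf("  %d facilities, population %g, flood area %.3g km^2\n",
              nrow(x$facilities), sum(x$population$values),
              mask_area(x$flood) / 1e6))
  invisible(x)
}

#' Scenario presets
#'
#' `"small"` is a compact random scenario for fast checks, `"default"` the
#' standard random study scenario, and `"bridge"` a fixed, hand-designed
#' single-bridge scenario (see [bridge_scenario()]) whose accessibility and
#' criticality results are enumerable by hand.
#'
#' @param preset `"small"`, `"default"` or `"bridge"`.
#' @param seed integer seed.
#' @return A `scenario`.
#' @export
scenario_preset <- function(preset = c("default", "small", "bridge"), seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    small = gen_scenario(
      seed,
      scenario_config(n_trunk_nodes = 6, n_local_nodes = 30, n_facilities = 3,
                      n_population_clusters = 4, total_population = 20000,
                      flood_width_m = 1200),
      extent = c(0, 0, 10000, 10000)),
    default = gen_scenario(seed),
    bridge = bridge_scenario(seed))
}

#' The single-bridge fixture scenario
#'
#' A fixed 10 x 10 km scenario built for hand enumeration: a west
#' settlement (2000 people) and a riverside hamlet (300 people) reach the
#' single facility in the east across a river; the only crossings are a
#' trunk bridge with a mid-river node and a long northern detour whose span
#' has both endpoints on dry land. The flood is a 1 km vertical band along
#' the river: it removes the bridge's mid-river node and the hamlet's
#' junction node, so the hamlet loses access entirely, the settlement
#' reroutes over the detour (whose edges gain criticality), and the bridge
#' edges carry the maximum criticality score before the flood.
#'
#' @param seed recorded in the scenario; the geometry itself is fixed.
#' @return A `scenario`.
#' @export
bridge_scenario <- function(seed = 1) {
  extent <- c(0, 0, 10000, 10000)
  nodes <- tibble::tibble(
    node_id = 1:9,
    x = c(1000, 4000, 5000, 6000, 9000, 4000, 6000, 4800, 3800),
    y = c(3000, 3000, 3000, 3000, 3000, 8000, 8000, 1000, 800))
  mk <- function(a, b, cls) {
    tibble::tibble(node_a = a, node_b = b, road_class = cls)
  }
  ed <- dplyr::bind_rows(
    mk(1, 2, "primary"),    # settlement -> west abutment
    mk(2, 3, "trunk"),      # bridge west span (node 3 is mid-river)
    mk(3, 4, "trunk"),      # bridge east span
    mk(4, 5, "primary"),    # east abutment -> facility town
    mk(2, 6, "secondary"),  # detour: north on the west bank
    mk(6, 7, "secondary"),  # detour crossing; both endpoints dry
    mk(7, 4, "secondary"),  # detour: back south on the east bank
    mk(2, 8, "tertiary"),   # hamlet junction (node 8 sits in the flood band)
    mk(8, 9, "track"))      # hamlet spur
  ed$edge_id <- seq_len(nrow(ed))
  ed$length_m <- sqrt((nodes$x[ed$node_a] - nodes$x[ed$node_b])^2 +
                        (nodes$y[ed$node_a] - nodes$y[ed$node_b])^2)
  net <- road_network(nodes, ed[, c("edge_id", "node_a", "node_b",
                                    "length_m", "road_class")])
  facilities <- structure(
    tibble::tibble(facility_id = 1L, x = 9000, y = 3000),
    class = c("facility_set", "tbl_df", "tbl", "data.frame"))
  cfg <- scenario_config(n_trunk_nodes = 5, n_local_nodes = 4,
                         n_facilities = 1, n_population_clusters = 2,
                         total_population = 2300, flood_width_m = 1000)
  # deterministic population: 5x5 block of 80/cell at the settlement,
  # 3x3 block at the hamlet summing to 300
  pv <- matrix(0, 100, 100)
  pos <- grid_cell_of(fa_grid(pv, 100, 0, 10000), 1000, 3000)
  pv[pos$row + (-2:2), pos$col + (-2:2)] <- 80
  pos9 <- grid_cell_of(fa_grid(pv, 100, 0, 10000), 3800, 800)
  hm <- matrix(c(33, 33, 33, 33, 34, 33, 33, 34, 34), 3, 3)
  pv[pos9$row + (-1:1), pos9$col + (-1:1)] <- hm
  pop <- population_grid(pv, 100, 0, 10000)
  flood <- flood_mask(list(cbind(c(4500, 5500, 5500, 4500, 4500),
                                 c(0, 0, 10000, 10000, 0))))
  structure(list(
    seed = seed, extent = extent, road_network = net,
    facilities = facilities, population = pop,
    friction = gen_friction_grid(net, extent, cfg, speed_profile("driving")),
    flood = flood, config = cfg), class = "scenario")
}
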