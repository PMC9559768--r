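ext10 <- c(0, 0, 10000, 10000)
cfg_small <- scenario_config(n_trunk_nodes = 6, n_local_nodes = 30,
                             n_facilities = 3, n_population_clusters = 4,
                             total_population = 20000, flood_width_m = 1200)

test_that("config invariants are enforced", {
  expect_error(scenario_config(n_facilities = 0), ">= 1")
  expect_error(scenario_config(population_cell_m = 0), "positive")
  expect_error(scenario_config(population_cell_m = 300, friction_cell_m = 1000),
               "divide")
})

test_that("network generator is deterministic and well connected", {
  n1 <- gen_road_network(1, ext10, cfg_small)
  n2 <- gen_road_network(1, ext10, cfg_small)
  expect_identical(n1, n2)
  expect_equal(nrow(n1$nodes), cfg_small$n_trunk_nodes + cfg_small$n_local_nodes)
  expect_error(gen_road_network(1, c(0, 0, 0, 10000), cfg_small), "degenerate")
  # byte-identical GeoJSON on repeat
  p1 <- tempfile(); p2 <- tempfile()
  write_network_geojson(n1, p1); write_network_geojson(n2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # connectivity across seeds: >= 90% of nodes in the largest component
  for (seed in 1:20) {
    net <- gen_road_network(seed, ext10, cfg_small)
    g <- igraph::graph_from_data_frame(
      data.frame(a = net$edges$node_a, b = net$edges$node_b),
      directed = FALSE,
      vertices = data.frame(name = net$nodes$node_id))
    comp <- igraph::components(g)
    expect_gte(max(comp$csize) / nrow(net$nodes), 0.9)
  }
  # every edge length >= Euclidean endpoint distance holds by constructor
  expect_true(all(table(n1$edges$road_class) > 0))
})

test_that("population raster conserves the total and is mostly empty", {
  cfg <- scenario_config(total_population = 100000)
  pop <- gen_population_grid(3, c(0, 0, 20000, 20000), cfg)
  expect_equal(sum(pop$values), 100000)   # exact conservation
  expect_identical(pop$values, gen_population_grid(3, c(0, 0, 20000, 20000), cfg)$values)
  expect_gt(mean(pop$values == 0), 0.5)
  one <- gen_population_grid(5, ext10, scenario_config(n_population_clusters = 1,
                                                       total_population = 5000))
  expect_equal(sum(one$values), 5000)
  expect_gt(mean(one$values == 0), 0.5)
})

test_that("friction costs follow the fastest rasterized class, off-road elsewhere", {
  # one horizontal track across the middle of a 5x5 km extent
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 5000), y = c(2500, 2500))
  edges <- tibble::tibble(edge_id = 1L, node_a = 1L, node_b = 2L,
                          length_m = 5000, road_class = "track")
  net <- road_network(nodes, edges)
  cfg <- scenario_config(friction_cell_m = 1000)
  fr <- gen_friction_grid(net, c(0, 0, 5000, 5000), cfg, speed_profile("driving"))
  # row 3 cells (centers y = 2500) contain the track: 10 km/h -> 0.006 min/m
  expect_equal(unname(fr$values[3, ]), rep(0.006, 5))
  expect_equal(cell_traversal_time(1000, 10), 6)
  # far rows are off-road walking: 0.024 min/m = 24 min per km cell
  expect_equal(unname(fr$values[1, ]), rep(0.024, 5))
  # adding a faster primary on the same line wins (max-speed rule)
  edges2 <- dplyr::bind_rows(edges, tibble::tibble(
    edge_id = 2L, node_a = 1L, node_b = 2L, length_m = 5000,
    road_class = "primary"))
  net2 <- road_network(nodes, edges2)
  fr2 <- gen_friction_grid(net2, c(0, 0, 5000, 5000), cfg, speed_profile("driving"))
  expect_equal(unname(fr2$values[3, ]), rep(60 / (1000 * 60), 5))
  # road cells are never costlier than off-road
  expect_true(all(fr2$values <= 0.024 + 1e-12))
})

test_that("facilities sit near nodes, deterministically", {
  net <- gen_road_network(2, ext10, cfg_small)
  f1 <- gen_facilities(2, net, 5)
  f2 <- gen_facilities(2, net, 5)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 5)
  for (i in 1:5) {
    d <- sqrt((net$nodes$x - f1$x[i])^2 + (net$nodes$y - f1$y[i])^2)
    expect_lte(min(d), 200)
  }
  expect_error(gen_facilities(1, net, 1000), "exceeds node count")
})

test_that("flood ribbon crosses the trunk skeleton and scales with width", {
  net <- gen_road_network(4, ext10, cfg_small)
  mask <- gen_flood_mask(4, ext10, cfg_small, network = net)
  expect_identical(mask$polygons,
                   gen_flood_mask(4, ext10, cfg_small, network = net)$polygons)
  trunk <- net$edges[net$edges$road_class %in% c("trunk", "primary"), ]
  tn <- unique(c(trunk$node_a, trunk$node_b))
  xy <- net$nodes[net$nodes$node_id %in% tn, ]
  expect_true(any(points_in_mask(xy$x, xy$y, mask)))
  thin <- gen_flood_mask(4, ext10,
                         scenario_config(flood_width_m = 10,
                                         flood_crosses_trunk = FALSE))
  expect_lt(mask_area(thin) / (10000 * 10000), 0.01)
})

test_that("assembled scenarios are reproducible and internally consistent", {
  s1 <- scenario_preset("small", seed = 7)
  s2 <- scenario_preset("small", seed = 7)
  expect_identical(s1$road_network, s2$road_network)
  expect_identical(s1$population$values, s2$population$values)
  expect_identical(s1$flood$polygons, s2$flood$polygons)
  # geometries within extent
  expect_true(all(s1$road_network$nodes$x >= 0 & s1$road_network$nodes$x <= 10000))
  ring <- s1$flood$polygons[[1]][[1]]
  expect_true(all(ring >= -1e-9 & ring <= 10000 + 1e-9))
  # at least one facility connected to the largest component
  g <- build_graph(s1$road_network, speed_profile("walking"))
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  sn <- snap_points(s1$facilities, s1$road_network, 2000)
  expect_true(any(match(as.character(sn$node_id), igraph::V(g)$name) %in% big))
  # scenario sanity: most populated cells' nearest nodes reach a facility
  tt <- node_access_times(g, s1$facilities)
  nz <- which(s1$population$values > 0, arr.ind = TRUE)
  cx <- s1$population$x0 + (nz[, "col"] - 0.5) * s1$population$cell_m
  cy <- s1$population$y0 - (nz[, "row"] - 0.5) * s1$population$cell_m
  reach <- vapply(seq_len(nrow(nz)), function(i) {
    d <- sqrt((tt$x - cx[i])^2 + (tt$y - cy[i])^2)
    !is.na(tt$time_min[which.min(d)])
  }, TRUE)
  expect_gte(mean(reach), 0.5)
})

test_that("friction of road cells never exceeds the off-road cost", {
  sc <- scenario_preset("small", seed = 9)
  offroad <- 60 / (1000 * speed_profile("driving")$offroad_kmh)
  expect_true(all(sc$friction$values <= offroad + 1e-12))
  expect_true(all(sc$friction$values > 0))
})

test_that("scenario round-trips through its on-disk formats", {
  sc <- scenario_preset("small", seed = 3)
  dir <- tempfile()
  write_scenario(sc, dir)
  sc2 <- read_scenario(dir)
  expect_equal(sc2$road_network$nodes, sc$road_network$nodes, tolerance = 1e-9)
  expect_equal(sc2$road_network$edges, sc$road_network$edges, tolerance = 1e-9)
  expect_equal(sc2$facilities$x, sc$facilities$x, tolerance = 1e-9)
  expect_equal(sc2$population$values, sc$population$values)
  expect_equal(sc2$friction$values, sc$friction$values, tolerance = 1e-9)
  expect_equal(sc2$flood$polygons[[1]][[1]], sc$flood$polygons[[1]][[1]],
               tolerance = 1e-9)
  expect_equal(unclass(sc2$config), unclass(sc$config))
})
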