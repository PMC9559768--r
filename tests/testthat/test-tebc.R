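test_that("population nuclei are nonzero-block centroids with summed counts", {
  v <- matrix(0, 20, 20)
  v[3:12, 5:14] <- 5   # one 10x10 patch of 100 m cells, 5 persons each
  pop <- population_grid(v, 100, 0, 2000)
  nuc <- population_nuclei(pop, 1000)
  # direct blocking oracle
  blocks <- matrix(0, 2, 2)
  for (r in 1:20) for (cc in 1:20) {
    blocks[(r - 1) %/% 10 + 1, (cc - 1) %/% 10 + 1] <-
      blocks[(r - 1) %/% 10 + 1, (cc - 1) %/% 10 + 1] + v[r, cc]
  }
  expect_equal(nrow(nuc), sum(blocks > 0))
  expect_equal(sum(nuc$population), sum(v))
  expect_true(all(nuc$x %in% c(500, 1500) & nuc$y %in% c(500, 1500)))
  expect_error(population_nuclei(pop, 250), "integer multiple")
  empty <- population_grid(matrix(0, 20, 20), 100, 0, 2000)
  expect_equal(nrow(population_nuclei(empty, 1000)), 0)
  withr::with_seed(8, {
    vr <- matrix(rpois(400, 0.3), 20, 20)
    nr <- population_nuclei(population_grid(vr, 100, 0, 2000), 1000)
    want <- 0
    for (br in 1:2) for (bc in 1:2) {
      want <- want + (sum(vr[(br - 1) * 10 + 1:10, (bc - 1) * 10 + 1:10]) > 0)
    }
    expect_equal(nrow(nr), want)
  })
})

test_that("destination selection uses an inclusive Euclidean 20 km buffer", {
  fac <- tibble::tibble(facility_id = 1:3,
                        x = c(19900, 20001, 5000), y = c(0, 0, 0))
  sel <- select_destinations(list(x = 0, y = 0), fac, 20000)
  expect_equal(sel$n, 2)
  expect_setequal(sel$destinations$facility_id, c(1L, 3L))
  none <- select_destinations(list(x = 1e6, y = 1e6), fac, 20000)
  expect_equal(none$n, 0)
})

test_that("TEBC applies the 1/N weighting on a path graph", {
  # path A(1)-B(2)-C(3), facility at C, origins at A and B
  nodes <- tibble::tibble(node_id = 1:3, x = c(0, 1000, 2000), y = 0)
  edges <- tibble::tibble(edge_id = 1:2, node_a = 1:2, node_b = 2:3,
                          length_m = 1000, road_class = "primary")
  net <- road_network(nodes, edges)
  g <- build_graph(net, speed_profile("driving"))
  origins <- tibble::tibble(origin_id = 1:2, x = c(0, 1000), y = c(0, 0),
                            population = c(10, 10))
  fac <- tibble::tibble(facility_id = 1L, x = 2000, y = 0)
  sc <- tebc_scores(g, origins, fac, range_m = 20000)
  expect_equal(sc$score[sc$edge_id == 2], 2)   # both origins use B-C
  expect_equal(sc$score[sc$edge_id == 1], 1)   # only A uses A-B
  # two in-range facilities on edge-disjoint paths: each edge scores 1/2
  nodes2 <- tibble::tibble(node_id = 1:3, x = c(0, -1000, 1000), y = 0)
  edges2 <- tibble::tibble(edge_id = 1:2, node_a = 1L, node_b = 2:3,
                           length_m = 1000, road_class = "primary")
  g2 <- build_graph(road_network(nodes2, edges2), speed_profile("driving"))
  fac2 <- tibble::tibble(facility_id = 1:2, x = c(-1000, 1000), y = 0)
  sc2 <- tebc_scores(g2, tibble::tibble(origin_id = 1L, x = 0, y = 0,
                                        population = 1), fac2)
  expect_equal(sc2$score, c(0.5, 0.5))
})

test_that("equal-cost ties resolve to the lexicographically smallest node path", {
  # square 1-2-4 and 1-3-4 with identical weights; origin 1, facility 4
  nodes <- tibble::tibble(node_id = 1:4,
                          x = c(0, 1000, 1000, 2000), y = c(0, 500, -500, 0))
  ed <- tibble::tibble(edge_id = 1:4,
                       node_a = c(1, 2, 1, 3), node_b = c(2, 4, 3, 4),
                       length_m = 1200, road_class = "primary")
  g <- build_graph(road_network(nodes, ed), speed_profile("driving"))
  sc <- tebc_scores(g, tibble::tibble(origin_id = 1L, x = 0, y = 0,
                                      population = 1),
                    tibble::tibble(facility_id = 1L, x = 2000, y = 0))
  expect_equal(sc$score[sc$edge_id %in% c(1, 2)], c(1, 1))  # via node 2
  expect_equal(sc$score[sc$edge_id %in% c(3, 4)], c(0, 0))
})

test_that("TEBC matches the brute-force enumerator on random graphs", {
  n_match <- 0
  for (seed in 1:50) {
    net <- random_test_network(seed, n_nodes = sample(10:30, 1))
    g <- build_graph(net, speed_profile("driving"))
    withr::with_seed(seed * 1000 + 1, {
      n_org <- sample(1:5, 1)
      n_fac <- sample(1:3, 1)
      origins <- tibble::tibble(
        origin_id = seq_len(n_org),
        x = runif(n_org, 0, 10000), y = runif(n_org, 0, 10000),
        population = 1)
      fac <- tibble::tibble(facility_id = seq_len(n_fac),
                            x = runif(n_fac, 0, 10000),
                            y = runif(n_fac, 0, 10000))
    })
    range_m <- 8000
    got <- tebc_scores(g, origins, fac, range_m, max_snap_m = 20000)
    sp <- speed_profile("driving")
    edges_o <- list(a = net$edges$node_a, b = net$edges$node_b,
                    w = net$edges$length_m /
                      (unname(sp$speeds[net$edges$road_class]) * 1000 / 60))
    o_snap <- snap_points(origins, net, 20000)
    f_snap <- snap_points(fac, net, 20000)
    want <- oracle_tebc(net$nodes$node_id, edges_o,
                        o_snap$node_id, origins, f_snap$node_id, fac, range_m)
    expect_equal(got$score[order(got$edge_id)], want[order(net$edges$edge_id)],
                 tolerance = 1e-12)
    if (max(want) > 0) n_match <- n_match + 1
  }
  expect_gt(n_match, 30)  # the comparison must be non-vacuous
})

test_that("TEBC mass conservation holds on scenario runs", {
  for (seed in c(1, 2, 3)) {
    sc <- scenario_preset("small", seed = seed)
    g <- build_graph(sc$road_network, speed_profile("driving"))
    origins <- population_nuclei(sc$population, 1000)
    field <- tebc_scores(g, origins, sc$facilities, 20000)
    org <- attr(field, "origins")
    ok <- org$n_destinations > 0
    want <- sum(org$path_edges[ok] / org$n_destinations[ok])
    expect_equal(sum(field$score), want, tolerance = 1e-9)
  }
})

test_that("unreachable in-range facilities still count in N", {
  # origin at 1; facility F1 connected, facility F2 in range but isolated
  nodes <- tibble::tibble(node_id = 1:4, x = c(0, 1000, 5000, 6000),
                          y = c(0, 0, 0, 0))
  ed <- tibble::tibble(edge_id = 1:2, node_a = c(1, 3), node_b = c(2, 4),
                       length_m = 1000, road_class = "primary")
  g <- build_graph(road_network(nodes, ed), speed_profile("driving"))
  fac <- tibble::tibble(facility_id = 1:2, x = c(1000, 5000), y = 0)
  sc <- tebc_scores(g, tibble::tibble(origin_id = 1L, x = 0, y = 0,
                                      population = 1), fac, range_m = 20000,
                    max_snap_m = 100)
  # N = 2, only F1 reached: edge 1 scores 1/2, nothing else
  expect_equal(sc$score[sc$edge_id == 1], 0.5)
  expect_equal(sc$score[sc$edge_id == 2], 0)
  org <- attr(sc, "origins")
  expect_equal(org$n_destinations, 2L)
  expect_equal(org$n_reached, 1L)
})

test_that("delta classification distinguishes flooded, lost and backup edges", {
  net <- two_route_network()
  g <- build_graph(net, speed_profile("driving"))
  origins <- tibble::tibble(origin_id = 1L, x = 0, y = 0, population = 100)
  fac <- tibble::tibble(facility_id = 1L, x = 3000, y = 0)
  band <- flood_mask(list(cbind(c(1800, 2200, 2200, 1800, 1800),
                                c(-100, -100, 700, 700, -100))))  # node 3
  gf <- apply_flood_to_graph(g, band)
  tn <- tebc_scores(g, origins, fac)
  tf <- tebc_scores(gf, origins, fac)
  d <- tebc_delta(tn, tf, flooded_edges = setdiff(tn$edge_id, tf$edge_id))
  cls <- stats::setNames(d$class, d$edge_id)
  expect_equal(unname(cls[c("2", "3")]), c("FLOODED", "FLOODED"))
  expect_equal(unname(cls[c("4", "5", "6")]),
               rep("BACKUP_INCREASED", 3))       # the detour absorbs the path
  expect_equal(unname(cls["1"]), "UNCHANGED")    # first leg used either way
  expect_equal(d$score_flood[d$edge_id %in% c(2, 3)], c(0, 0))
  # identical fields are all UNCHANGED
  d0 <- tebc_delta(tn, tn, flooded_edges = integer(0))
  expect_true(all(d0$class == "UNCHANGED"))
  # mismatched universes beyond the flooded edges are rejected
  expect_error(tebc_delta(tn, tf, flooded_edges = integer(0)), "edge sets differ")
})

test_that("dispersion summarises score inequality with the Gini coefficient", {
  f_eq <- structure(tibble::tibble(edge_id = 1:5, score = rep(2, 5)),
                    class = c("tebc_field", "tbl_df", "tbl", "data.frame"))
  expect_equal(tebc_dispersion(f_eq)$gini, 0)
  f_dom <- structure(tibble::tibble(edge_id = 1:100,
                                    score = c(rep(1e-6, 99), 100)),
                     class = c("tebc_field", "tbl_df", "tbl", "data.frame"))
  expect_gt(tebc_dispersion(f_dom)$gini, 0.95)
  withr::with_seed(6, {
    x <- rexp(40)
    f <- structure(tibble::tibble(edge_id = 1:40, score = x),
                   class = c("tebc_field", "tbl_df", "tbl", "data.frame"))
    expect_equal(tebc_dispersion(f)$gini, oracle_gini(x), tolerance = 1e-12)
  })
  f0 <- structure(tibble::tibble(edge_id = 1:3, score = 0),
                  class = c("tebc_field", "tbl_df", "tbl", "data.frame"))
  d0 <- tebc_dispersion(f0)
  expect_equal(d0$gini, 0)
  expect_true(attr(d0, "all_zero"))
})
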