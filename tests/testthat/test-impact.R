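mk_time_grid <- function(v, cell_m = 100, x0 = 0, y0 = NULL) {
  if (is.null(y0)) y0 <- nrow(v) * cell_m
  floodaccess:::time_field_grid(v, cell_m, x0, y0)
}

test_that("cells take the minimum time of nodes within the reach radius", {
  nt <- structure(tibble::tibble(node_id = 1:2, x = c(550, 560), y = c(550, 560),
                                 time_min = c(40, 15)),
                  class = c("node_time_field", "tbl_df", "tbl", "data.frame"))
  pop <- population_grid(matrix(1, 10, 10), 100, 0, 1000)
  tf <- network_access_grid(nt, pop, reach_radius_m = 500)
  # cell (6,6) center (550,450): both nodes in radius -> min 15
  expect_equal(tf$values[6, 6], 15)
  # far corner (1,10) center (950, 950): dist to nodes ~ 560 -> unreachable
  expect_true(is.na(tf$values[1, 10]))
  # single-node case returns that node's time
  nt1 <- nt[1, ]
  class(nt1) <- class(nt)
  expect_equal(network_access_grid(nt1, pop, 500)$values[6, 6], 40)
  # empty node set -> everything unreachable
  nt0 <- nt[0, ]
  class(nt0) <- class(nt)
  expect_true(all(is.na(network_access_grid(nt0, pop, 500)$values)))
})

test_that("population by bin conserves the raster total", {
  withr::with_seed(14, {
    tv <- matrix(runif(400, 0, 90), 20, 20)
    tv[sample(400, 30)] <- NA
    tf <- mk_time_grid(tv, 100)
    pv <- matrix(rpois(400, 3), 20, 20)
    pop <- population_grid(pv, 100, 0, 2000)
    tab <- population_by_bin(bin_times(tf, 10, 60), pop)
    expect_equal(nrow(tab), 6 + 2)
    expect_equal(sum(tab$population), sum(pv), tolerance = 1e-9)
    # naive per-cell accumulation oracle
    want_bin0 <- sum(pv[!is.na(tv) & tv < 10])
    expect_equal(tab$population[1], want_bin0)
    want_beyond <- sum(pv[!is.na(tv) & tv >= 60])
    expect_equal(tab$population[tab$label == "BEYOND_CAP"], want_beyond)
    expect_equal(tab$population[tab$label == "UNREACHABLE"], sum(pv[is.na(tv)]))
  })
  # empty population: all rows zero
  tf <- mk_time_grid(matrix(5, 4, 4))
  tab0 <- population_by_bin(bin_times(tf, 10, 60),
                            population_grid(matrix(0, 4, 4), 100, 0, 400))
  expect_true(all(tab0$population == 0))
})

test_that("finer population rasters are block-summed onto the access frame", {
  tv <- matrix(c(5, 25, 65, NA), 2, 2)
  tf <- mk_time_grid(tv, 1000, 0, 2000)
  pv <- matrix(1, 20, 20)  # 100 m cells, 1 person each
  pop <- population_grid(pv, 100, 0, 2000)
  tab <- population_by_bin(bin_times(tf, 10, 60), pop)
  expect_equal(sum(tab$population), 400)
  expect_equal(tab$population[tab$label == "[0,10) min"], 100)
  expect_equal(tab$population[tab$label == "UNREACHABLE"], 100)
  expect_error(resample_population(
    population_grid(matrix(1, 3, 3), 300, 0, 900),
    floodaccess:::fa_grid(matrix(0, 1, 1), 1000, 0, 1000)),
    "integer multiple")
})

test_that("loss field classifies increase, lost access and clamps negatives", {
  before <- mk_time_grid(matrix(c(20, 20, 30, NA), 2, 2))
  after <- mk_time_grid(matrix(c(40, NA, 25, NA), 2, 2))
  lf <- access_loss(before, after)
  expect_equal(lf$increase[1, 1], 20)
  expect_equal(lf$category[1, 1], 1L)      # increased
  expect_equal(lf$category[2, 1], 2L)      # lost access
  expect_equal(lf$category[1, 2], 0L)      # improved -> clamped to no change
  expect_equal(lf$increase[1, 2], 0)
  expect_equal(lf$n_clamped, 1L)
  expect_equal(lf$category[2, 2], 0L)      # unreachable in both
  # beyond-cap after counts as lost when a cap is given
  lf2 <- access_loss(mk_time_grid(matrix(20, 1, 1)),
                     mk_time_grid(matrix(70, 1, 1)), cap_min = 60)
  expect_equal(lf2$category[1, 1], 2L)
  expect_error(access_loss(before, mk_time_grid(matrix(1, 3, 3), 100, 0, 300)),
               "frame mismatch")
})

test_that("loss table partitions the population over increase ranges", {
  withr::with_seed(15, {
    b <- matrix(runif(400, 0, 60), 20, 20)
    extra <- matrix(rexp(400, 1 / 60), 20, 20)
    a <- b + extra
    a[1:3, 1] <- NA   # lost cells
    before <- mk_time_grid(b); after <- mk_time_grid(a)
    pop <- population_grid(matrix(rpois(400, 2), 20, 20), 100, 0, 2000)
    lt <- loss_table(access_loss(before, after), pop, breaks = c(60, 120, 180))
    expect_equal(sum(lt$population), sum(pop$values), tolerance = 1e-9)
    expect_equal(lt$label[1], "NO_CHANGE")
    expect_equal(lt$label[nrow(lt)], "LOST_ACCESS")
    expect_equal(lt$population[nrow(lt)], sum(pop$values[1:3, 1]))
  })
})

test_that("designed bridge fixture: population-weighted loss matches enumeration", {
  sc <- scenario_preset("bridge")
  res <- run_pipeline(sc, speed_profile("driving"))
  lt <- res$impact$loss_table_network
  # hand enumeration: the hamlet (300 people) is cut off, the settlement
  # (2000 people) detours but keeps access
  expect_equal(lt$population[lt$label == "LOST_ACCESS"], 300)
  expect_equal(sum(lt$population), 2300, tolerance = 1e-9)
  # per-cell oracle on the 100x100 grid: every populated cell either keeps
  # its access (west settlement) or loses it (hamlet)
  lf <- res$impact$loss_network
  pv <- sc$population$values
  lost_pop <- sum(pv[lf$category == 2L])
  expect_equal(lost_pop, 300)
  inc_cells <- pv > 0 & lf$category == 1L
  expect_equal(sum(pv[inc_cells]), 2000)
  # the settlement's increase is the detour minus the bridge route time
  sp <- speed_profile("driving")$speeds
  t_before <- 3000 / (sp[["primary"]] * 1000 / 60) +
    2000 / (sp[["trunk"]] * 1000 / 60) + 3000 / (sp[["primary"]] * 1000 / 60)
  t_after <- 3000 / (sp[["primary"]] * 1000 / 60) +
    12000 / (sp[["secondary"]] * 1000 / 60) + 3000 / (sp[["primary"]] * 1000 / 60)
  expect_equal(unique(lf$increase[inc_cells]), t_after - t_before,
               tolerance = 1e-9)
})

test_that("area within threshold equals the direct cell count", {
  tv <- matrix(c(rep(5, 50), rep(70, 30), rep(NA, 20)), 10, 10)
  bins <- bin_times(mk_time_grid(tv, 1000, 0, 10000), 10, 120)
  expect_equal(area_within_threshold(bins, 10), 50)   # 50 cells of 1 km^2
  expect_equal(area_within_threshold(bins, 120), 80)
  expect_equal(area_within_threshold(bins, 0), 0)
  expect_error(area_within_threshold(bins, 15), "multiple")
  withr::with_seed(16, {
    tv2 <- matrix(runif(400, 0, 200), 20, 20)
    bins2 <- bin_times(mk_time_grid(tv2, 500, 0, 10000), 10, 360)
    expect_equal(area_within_threshold(bins2, 60),
                 sum(tv2 < 60) * 0.25)
  })
})

test_that("method comparison reports K + 2 rows and flags schema mismatches", {
  tf <- mk_time_grid(matrix(runif(100, 0, 80), 10, 10))
  pop <- population_grid(matrix(1, 10, 10), 100, 0, 1000)
  t1 <- population_by_bin(bin_times(tf, 10, 60), pop)
  rep1 <- compare_methods(t1, t1)
  expect_equal(nrow(rep1), 8)
  expect_true(all(rep1$diff == 0))
  t2 <- population_by_bin(bin_times(tf, 10, 120), pop)
  expect_error(compare_methods(t1, t2), "differing bin schemes")
})

test_that("network engine strands off-road population that the raster engine reaches", {
  n_consistent <- 0
  for (seed in 1:10) {
    sc <- scenario_preset("small", seed = seed)
    res <- run_pipeline(sc, speed_profile("driving"))
    unr <- function(tab) tab$population[tab$label %in% c("BEYOND_CAP", "UNREACHABLE")]
    n_consistent <- n_consistent +
      (sum(unr(res$impact$tables$network_normal)) >=
         sum(unr(res$impact$tables$raster_normal)))
  }
  expect_equal(n_consistent, 10)
})
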