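#' Run the full accessibility and criticality pipeline
#'
#' Executes, in order: flood-mask preprocessing, the network-based and
#' raster-based accessibility engines under normal and flooded conditions,
#' population impact and loss-of-access tabulation, targeted edge
#' betweenness centrality for both conditions with its delta
#' classification, and the raster-vs-network comparison. All stages are
#' deterministic: identical scenario and parameters give identical outputs.
#'
#' @param scenario a `scenario` ([gen_scenario()], [scenario_preset()], or
#'   [read_scenario()]).
#' @param profile a [speed_profile()]; the cap defaults to 60 min for
#'   driving and 360 min for walking.
#' @param interval_min access bin width, minutes.
#' @param cap_min access cap, minutes (`NULL` = profile default).
#' @param range_m TEBC destination buffer radius, meters.
#' @param reach_radius_m cell-to-node radius for grid isochrone membership.
#' @param max_snap_m snapping tolerance, meters.
#' @param connectivity raster movement neighbourhood, 8 or 16.
#' @param strict_edge_flooding also drop dry-ended edges crossing the mask.
#' @param simplify_retain if non-`NULL`, Visvalingam retain fraction applied
#'   to each flood-mask ring before use.
#' @param loss_breaks increase-range bounds for the loss tables, minutes.
#' @param out_dir if non-`NULL`, tables and disrupted network are written
#'   there and hashed into the manifest.
#' @return A `pipeline_result` list: time fields, impact and loss tables
#'   per engine and condition, TEBC fields/delta/dispersion, the
#'   comparison report and a `manifest`.
#' @export
run_pipeline <- function(scenario, profile = speed_profile("driving"),
                         interval_min = 10, cap_min = NULL,
                         range_m = 20000, reach_radius_m = 500,
                         max_snap_m = 2000, connectivity = 8,
                         strict_edge_flooding = FALSE,
                         simplify_retain = NULL,
                         loss_breaks = NULL, out_dir = NULL) {
  fa_stopifnot(inherits(scenario, "scenario"), "`scenario` must be a scenario")
  cap_min <- cap_min %||% if (profile$mode == "driving") 60 else 360
  fa_stopifnot(abs(cap_min / interval_min - round(cap_min / interval_min)) < 1e-9,
               "cap must be divisible by the interval")
  loss_breaks <- loss_breaks %||%
    if (cap_min <= 60) seq(10, 50, by = 10) else seq(60, 300, by = 60)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  counts <- list()

  # 1 flood preprocessing
  flood <- stage("flood_preprocess", {
    m <- scenario$flood
    if (!is.null(simplify_retain)) m <- simplify_mask(m, simplify_retain)
    m
  })

  # 2 network engine
  net_res <- stage("network_access", {
    g <- build_graph(scenario$road_network, profile)
    gf <- apply_flood_to_graph(g, flood, strict = strict_edge_flooding)
    counts$nodes_removed <- length(attr(gf, "removed_nodes"))
    list(graph = g, graph_flood = gf,
         times = node_access_times(g, scenario$facilities, max_snap_m),
         times_flood = node_access_times(gf, scenario$facilities, max_snap_m))
  })

  # 3 raster engine
  ras_res <- stage("raster_access", {
    fr <- scenario$friction
    frf <- apply_flood_to_friction(fr, flood)
    counts$cells_flooded <- attr(frf, "n_flooded_cells")
    list(times = least_cost_time(fr, scenario$facilities, connectivity),
         times_flood = least_cost_time(frf, scenario$facilities, connectivity))
  })

  # 4 impact tabulation
  imp <- stage("impact", {
    pop <- scenario$population
    net_grid <- network_access_grid(net_res$times, pop, reach_radius_m)
    net_grid_f <- network_access_grid(net_res$times_flood, pop, reach_radius_m)
    tabs <- list(
      network_normal = population_by_bin(bin_times(net_grid, interval_min, cap_min), pop),
      network_flood = population_by_bin(bin_times(net_grid_f, interval_min, cap_min), pop),
      raster_normal = population_by_bin(bin_times(ras_res$times, interval_min, cap_min), pop),
      raster_flood = population_by_bin(bin_times(ras_res$times_flood, interval_min, cap_min), pop))
    loss_net <- access_loss(net_grid, net_grid_f, cap_min)
    loss_ras <- access_loss(ras_res$times, ras_res$times_flood, cap_min)
    counts$cells_clamped <- loss_net$n_clamped + loss_ras$n_clamped
    list(net_grid = net_grid, net_grid_flood = net_grid_f, tables = tabs,
         loss_network = loss_net, loss_raster = loss_ras,
         loss_table_network = loss_table(loss_net, pop, loss_breaks),
         loss_table_raster = loss_table(loss_ras, pop, loss_breaks))
  })

  # 5 criticality
  crit <- stage("tebc", {
    origins <- population_nuclei(scenario$population, 1000)
    tn <- tebc_scores(net_res$graph, origins, scenario$facilities, range_m,
                      max_snap_m)
    tf <- tebc_scores(net_res$graph_flood, origins, scenario$facilities,
                      range_m, max_snap_m)
    counts$origins_skipped <- attr(tf, "n_skipped")
    flooded_edges <- setdiff(tn$edge_id, tf$edge_id)
    list(origins = origins, normal = tn, flood = tf,
         delta = tebc_delta(tn, tf, flooded_edges),
         dispersion_normal = tebc_dispersion(tn),
         dispersion_flood = tebc_dispersion(tf))
  })

  # 6 comparison
  comp <- stage("comparison", {
    compare_methods(
      imp$tables$raster_normal, imp$tables$network_normal,
      raster_area_km2 = area_within_threshold(
        bin_times(ras_res$times, interval_min, cap_min), cap_min),
      network_area_km2 = area_within_threshold(
        bin_times(imp$net_grid, interval_min, cap_min), cap_min))
  })

  manifest <- list(
    stages = c("flood_preprocess", "network_access", "raster_access",
               "impact", "tebc", "comparison"),
    parameters = list(profile = profile$mode, interval_min = interval_min,
                      cap_min = cap_min, range_m = range_m,
                      reach_radius_m = reach_radius_m, max_snap_m = max_snap_m,
                      connectivity = connectivity,
                      strict_edge_flooding = strict_edge_flooding,
                      seed = scenario$seed),
    counts = counts)

  res <- list(network = net_res, raster = ras_res, impact = imp,
              tebc = crit, comparison = comp, manifest = manifest)
  if (!is.null(out_dir)) {
    res$manifest$files <- write_pipeline_outputs(res, scenario, out_dir)
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = I(10))
  }
  structure(res, class = "pipeline_result")
}

write_pipeline_outputs <- function(res, scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    p
  }
  paths <- c(
    wcsv(res$impact$tables$network_normal, "impact_network_normal.csv"),
    wcsv(res$impact$tables$network_flood, "impact_network_flood.csv"),
    wcsv(res$impact$tables$raster_normal, "impact_raster_normal.csv"),
    wcsv(res$impact$tables$raster_flood, "impact_raster_flood.csv"),
    wcsv(res$impact$loss_table_network, "loss_network.csv"),
    wcsv(res$impact$loss_table_raster, "loss_raster.csv"),
    wcsv(res$tebc$delta, "tebc_delta.csv"),
    wcsv(res$comparison, "comparison.csv"))
  p <- file.path(out_dir, "network_disrupted.geojson")
  write_network_geojson(scenario$road_network, p,
                        removed_nodes = attr(res$network$graph_flood,
                                             "removed_nodes"))
  paths <- c(paths, p)
  tibble::tibble(path = basename(paths),
                 md5 = unname(tools::md5sum(paths)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  profile %s, %d-min bins capped at %g min\n",
              x$manifest$parameters$profile, x$manifest$parameters$interval_min,
              x$manifest$parameters$cap_min))
  cat(sprintf("  flood: %d nodes removed, %d raster cells forbidden\n",
              x$manifest$counts$nodes_removed, x$manifest$counts$cells_flooded))
  lostn <- x$impact$loss_table_network$population[
    x$impact$loss_table_network$label == "LOST_ACCESS"]
  lostr <- x$impact$loss_table_raster$population[
    x$impact$loss_table_raster$label == "LOST_ACCESS"]
  cat(sprintf("  population losing all access: network %g, raster %g\n",
              lostn, lostr))
  cat(sprintf("  TEBC: max %.3g normal / %.3g flooded; %d backup edges\n",
              max(x$tebc$normal$score), max(x$tebc$flood$score),
              sum(x$tebc$delta$class == "BACKUP_INCREASED")))
  invisible(x)
}
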