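#' GeoJSON input/output
#'
#' Readers and writers for the vector domain types. Networks are written as
#' a FeatureCollection of node Points (property `node_id`, plus `removed`
#' when a disrupted network is written) and edge LineStrings (properties
#' `edge_id`, `node_a`, `node_b`, `length_m`, `road_class`); facilities as
#' Points; flood masks as a MultiPolygon. Coordinates are projected meters;
#' the CRS string is carried in a top-level `crs` member and must match
#' across the inputs of a pipeline. Write-then-read restores each object
#' within 1e-9 coordinate tolerance.
#'
#' @param network,facilities,mask objects to write.
#' @param path file path.
#' @param removed_nodes optional node ids flagged `removed = TRUE`.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name geojson_io
NULL

gj_write <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(12),
                       null = "null", na = "null")
  invisible(path)
}

gj_read <- function(path) {
  out <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf("malformed GeoJSON '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  fa_stopifnot(!is.null(out$type), sprintf("'%s' is not GeoJSON: no type member", path))
  out
}

gj_crs <- function(doc) {
  if (!is.null(doc$crs)) as.character(doc$crs) else default_crs()
}

#' @rdname geojson_io
#' @export
write_network_geojson <- function(network, path, removed_nodes = integer(0)) {
  nodes <- network$nodes
  edges <- network$edges
  feats <- c(
    lapply(seq_len(nrow(nodes)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(nodes$x[i], nodes$y[i])),
           properties = list(kind = "node", node_id = nodes$node_id[i],
                             removed = nodes$node_id[i] %in% removed_nodes))
    }),
    lapply(seq_len(nrow(edges)), function(i) {
      ia <- match(edges$node_a[i], nodes$node_id)
      ib <- match(edges$node_b[i], nodes$node_id)
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(c(nodes$x[ia], nodes$y[ia]),
                                              c(nodes$x[ib], nodes$y[ib]))),
           properties = list(kind = "edge", edge_id = edges$edge_id[i],
                             node_a = edges$node_a[i], node_b = edges$node_b[i],
                             length_m = edges$length_m[i],
                             road_class = edges$road_class[i]))
    }))
  gj_write(list(type = "FeatureCollection",
                crs = attr(network, "crs") %||% default_crs(),
                features = feats), path)
}

#' @rdname geojson_io
#' @export
read_network_geojson <- function(path) {
  doc <- gj_read(path)
  feats <- doc$features
  kinds <- vapply(feats, function(f) f$properties$kind %||% "", "")
  nf <- feats[kinds == "node"]
  ef <- feats[kinds == "edge"]
  fa_stopifnot(length(nf) > 0 && length(ef) > 0,
               sprintf("'%s': expected node and edge features", path))
  nodes <- tibble::tibble(
    node_id = vapply(nf, function(f) as.integer(f$properties$node_id), 1L),
    x = vapply(nf, function(f) as.numeric(f$geometry$coordinates[[1]]), 1),
    y = vapply(nf, function(f) as.numeric(f$geometry$coordinates[[2]]), 1))
  edges <- tibble::tibble(
    edge_id = vapply(ef, function(f) as.integer(f$properties$edge_id), 1L),
    node_a = vapply(ef, function(f) as.integer(f$properties$node_a), 1L),
    node_b = vapply(ef, function(f) as.integer(f$properties$node_b), 1L),
    length_m = vapply(ef, function(f) as.numeric(f$properties$length_m), 1),
    road_class = vapply(ef, function(f) as.character(f$properties$road_class), ""))
  road_network(nodes[order(nodes$node_id), ], edges[order(edges$edge_id), ],
               crs = gj_crs(doc))
}

#' @rdname geojson_io
#' @export
write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[i], facilities$y[i])),
         properties = list(facility_id = facilities$facility_id[i]))
  })
  gj_write(list(type = "FeatureCollection",
                crs = attr(facilities, "crs") %||% default_crs(),
                features = feats), path)
}

#' @rdname geojson_io
#' @export
read_facilities_geojson <- function(path) {
  doc <- gj_read(path)
  out <- tibble::tibble(
    facility_id = vapply(doc$features, function(f)
      as.integer(f$properties$facility_id), 1L),
    x = vapply(doc$features, function(f) as.numeric(f$geometry$coordinates[[1]]), 1),
    y = vapply(doc$features, function(f) as.numeric(f$geometry$coordinates[[2]]), 1))
  out <- structure(out, class = c("facility_set", class(out)))
  attr(out, "crs") <- gj_crs(doc)
  out
}

#' @rdname geojson_io
#' @export
write_floodmask_geojson <- function(mask, path) {
  coords <- lapply(mask$polygons, function(poly) {
    lapply(poly, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
  })
  props <- list()
  if (!is.null(attr(mask, "retain_fraction"))) {
    props$simplify_retain_fraction <- attr(mask, "retain_fraction")
  }
  gj_write(list(type = "Feature",
                crs = attr(mask, "crs") %||% default_crs(),
                geometry = list(type = "MultiPolygon", coordinates = coords),
                properties = props), path)
}

#' @rdname geojson_io
#' @export
read_floodmask_geojson <- function(path) {
  doc <- gj_read(path)
  geom <- if (identical(doc$type, "Feature")) doc$geometry else doc
  fa_stopifnot(geom$type %in% c("Polygon", "MultiPolygon"),
               sprintf("'%s': expected Polygon or MultiPolygon", path))
  to_ring <- function(r) {
    do.call(rbind, lapply(r, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  }
  polys <- if (geom$type == "Polygon") {
    list(lapply(geom$coordinates, to_ring))
  } else {
    lapply(geom$coordinates, function(poly) lapply(poly, to_ring))
  }
  flood_mask(polys, crs = gj_crs(doc))
}

#' Write a scenario to a directory
#'
#' Network and facilities as GeoJSON, population and friction as Esri ASCII
#' grids, flood mask as GeoJSON, and the configuration (with seed, extent
#' and CRS) as JSON.
#'
#' @param scenario a `scenario` (e.g. [gen_scenario()]).
#' @param dir output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_geojson(scenario$road_network, file.path(dir, "network.geojson"))
  write_facilities_geojson(scenario$facilities, file.path(dir, "facilities.geojson"))
  write_floodmask_geojson(scenario$flood, file.path(dir, "flood.geojson"))
  write_ascii_grid(scenario$population, file.path(dir, "population.asc"))
  write_ascii_grid(scenario$friction, file.path(dir, "friction.asc"))
  jsonlite::write_json(
    list(seed = scenario$seed, extent = scenario$extent,
         crs = attr(scenario$road_network, "crs") %||% default_crs(),
         config = unclass(scenario$config)),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = I(10))
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#'
#' @param dir scenario directory.
#' @return A `scenario`.
#' @export
read_scenario <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scenario.json"), simplifyVector = TRUE)
  cfg <- do.call(scenario_config, meta$config)
  structure(list(
    seed = meta$seed,
    extent = as.numeric(meta$extent),
    road_network = read_network_geojson(file.path(dir, "network.geojson")),
    facilities = read_facilities_geojson(file.path(dir, "facilities.geojson")),
    population = read_ascii_grid(file.path(dir, "population.asc"), "population"),
    friction = read_ascii_grid(file.path(dir, "friction.asc"), "friction"),
    flood = read_floodmask_geojson(file.path(dir, "flood.geojson")),
    config = cfg), class = "scenario")
}
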