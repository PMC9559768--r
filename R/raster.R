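#' Minutes to traverse one raster cell
#'
#' On a 1 km cell this is 6 min at the 10 km/h motorized track speed and
#' 24 min at the 2.5 km/h bare-ground walking speed — the time resolution
#' of the raster accessibility method.
#'
#' @param cell_m cell edge length in meters (> 0).
#' @param speed_kmh travel speed in km/h (> 0).
#' @return Minutes to cross the cell.
#' @export
#' @examples
#' cell_traversal_time(1000, 10)   # 6
#' cell_traversal_time(1000, 2.5)  # 24
cell_traversal_time <- function(cell_m, speed_kmh) {
  fa_stopifnot(is.numeric(cell_m) && all(cell_m > 0), "`cell_m` must be positive")
  fa_stopifnot(is.numeric(speed_kmh) && all(speed_kmh > 0),
               "`speed_kmh` must be positive")
  cell_m / (speed_kmh * 1000 / 60)
}

#' Forbid travel through flooded cells
#'
#' Cells whose center lies inside the flood union (boundary included)
#' become impassable (`NA`); all other cells are unchanged. An empty mask
#' returns the grid as is.
#'
#' @param grid a [friction_grid()].
#' @param flood a [flood_mask()].
#' @return A `friction_grid` with flooded cells set to `NA`; attribute
#'   `n_flooded_cells` counts them.
#' @export
apply_flood_to_friction <- function(grid, flood) {
  fa_stopifnot(inherits(grid, "friction_grid"), "`grid` must be a friction_grid")
  if (is_empty_mask(flood)) {
    attr(grid, "n_flooded_cells") <- 0L
    return(grid)
  }
  check_same_crs(grid, flood)
  cc <- grid_cell_centers(grid)
  wet <- points_in_mask(cc$x, cc$y, flood)
  v <- grid$values
  v[cbind(cc$row[wet], cc$col[wet])] <- NA_real_
  out <- friction_grid(v, grid$cell_m, grid$x0, grid$y0, crs = attr(grid, "crs"))
  attr(out, "n_flooded_cells") <- sum(wet)
  out
}

# Build the 8- (or 16-) connected cell graph of a friction grid.
# Step cost between adjacent cells = mean of their frictions x step length.
grid_graph <- function(grid, connectivity = 8) {
  fa_stopifnot(connectivity %in% c(8, 16), "`connectivity` must be 8 or 16")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- matrix(seq_len(nr * nc), nr, nc)   # column-major cell index
  offs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  if (connectivity == 16) {
    offs <- c(offs, list(c(1, 2, sqrt(5)), c(2, 1, sqrt(5)),
                         c(-1, 2, sqrt(5)), c(-2, 1, sqrt(5))))
  }
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; mult <- o[3]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- idx[r1, c1, drop = FALSE]
    b <- idx[r1 + dr, c1 + dc, drop = FALSE]
    ca <- v[a]; cb <- v[b]
    ok <- !is.na(ca) & !is.na(cb)
    from <- c(from, a[ok]); to <- c(to, b[ok])
    w <- c(w, (ca[ok] + cb[ok]) / 2 * grid$cell_m * mult)
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Least-cost travel time over a friction surface
#'
#' Multi-source shortest paths on the 8-connected (optionally 16-connected)
#' cell graph of the friction grid: the step cost between adjacent cells is
#' the mean of their minutes-per-meter costs times the center distance
#' (`cell_m`, or `cell_m * sqrt(2)` diagonally). Facility cells get time 0;
#' cells with no passable path are unreachable (`NA`).
#'
#' @param grid a [friction_grid()] (flood-disrupted or not).
#' @param facilities tibble with columns `x`, `y`; each facility maps to its
#'   containing cell (several in one cell collapse to one source).
#' @param connectivity 8 or 16 movement directions.
#' @return A `time_field` grid of minutes.
#' @export
least_cost_time <- function(grid, facilities, connectivity = 8) {
  fa_stopifnot(inherits(grid, "friction_grid"), "`grid` must be a friction_grid")
  fa_stopifnot(nrow(facilities) >= 1, "at least one facility is required")
  pos <- grid_cell_of(grid, facilities$x, facilities$y)
  inside <- !is.na(pos$row)
  cells <- unique((pos$col[inside] - 1L) * nrow(grid$values) + pos$row[inside])
  passable <- cells[!is.na(grid$values[cells])]
  if (length(passable) == 0) {
    bad <- which(inside)
    stop(sprintf("all facilities fall on impassable or outside cells (facilities %s)",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  g <- grid_graph(grid, connectivity)
  d <- igraph::distances(g, v = passable)
  tmin <- if (length(passable) == 1) as.numeric(d) else apply(d, 2, min)
  tmin[!is.finite(tmin)] <- NA_real_
  tmin[is.na(grid$values)] <- NA_real_
  time_field_grid(matrix(tmin, nrow(grid$values), ncol(grid$values)),
                  grid$cell_m, grid$x0, grid$y0, crs = attr(grid, "crs"))
}

#' Bin a travel-time field into access intervals
#'
#' Time `t` in `[k * interval, (k + 1) * interval)` falls in bin `k`;
#' `t >= cap` is beyond the cap (out of range for the profile: 60 min
#' driving, 360 min walking); unreachable elements stay unreachable. The
#' interval must divide the cap exactly.
#'
#' @param field a cell `time_field` grid, a `node_time_field` tibble, or a
#'   numeric vector of minutes (`NA` = unreachable).
#' @param interval_min bin width, minutes.
#' @param cap_min cap, minutes.
#' @return An `access_bins` object: integer codes per element (0..K-1 for
#'   bins, K for beyond-cap, `NA` for unreachable) plus the bin scheme.
#' @export
bin_times <- function(field, interval_min = 10, cap_min = 60) {
  fa_stopifnot(interval_min > 0 && cap_min > 0, "interval and cap must be positive")
  K <- cap_min / interval_min
  fa_stopifnot(abs(K - round(K)) < 1e-9,
               sprintf("interval (%g) must divide cap (%g)", interval_min, cap_min))
  K <- as.integer(round(K))
  code1 <- function(t) {
    k <- floor(t / interval_min)
    k[t >= cap_min] <- K
    as.integer(k)
  }
  if (inherits(field, "fa_grid")) {
    codes <- matrix(code1(field$values), nrow(field$values), ncol(field$values))
    frame <- field
  } else if (inherits(field, "node_time_field")) {
    codes <- code1(field$time_min)
    frame <- NULL
  } else {
    codes <- code1(as.numeric(field))
    frame <- NULL
  }
  structure(list(codes = codes, interval_min = interval_min, cap_min = cap_min,
                 K = K, frame = frame),
            class = "access_bins")
}

#' @export
print.access_bins <- function(x, ...) {
  cat(sprintf("<access_bins> %d bins of %g min, cap %g min; %d elements (%d beyond cap, %d unreachable)\n",
              x$K, x$interval_min, x$cap_min, length(x$codes),
              sum(x$codes == x$K, na.rm = TRUE), sum(is.na(x$codes))))
  invisible(x)
}

#' Labels of an access-bin scheme
#'
#' @param bins an [bin_times()] result.
#' @return Character vector: one `"[lo,hi) min"` label per bin, then
#'   `"BEYOND_CAP"` and `"UNREACHABLE"`.
#' @export
bin_labels <- function(bins) {
  k <- seq_len(bins$K) - 1
  c(sprintf("[%g,%g) min", k * bins$interval_min, (k + 1) * bins$interval_min),
    "BEYOND_CAP", "UNREACHABLE")
}
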