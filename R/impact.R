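#' Materialize node travel times on the population grid
#'
#' Grid-level isochrone membership: each population cell receives the
#' minimum travel time over all network nodes within `reach_radius_m` of
#' its center; cells with no node in radius are unreachable. This stands in
#' for vector isochrone polygons at the resolution of the population
#' raster.
#'
#' @param node_times a [node_access_times()] tibble.
#' @param pop a [population_grid()] giving the target frame.
#' @param reach_radius_m radius in meters within which a cell "sees" a node.
#' @return A `time_field` grid on the population frame.
#' @export
network_access_grid <- function(node_times, pop, reach_radius_m = 500) {
  fa_stopifnot(reach_radius_m > 0, "`reach_radius_m` must be positive")
  nr <- nrow(pop$values); nc <- ncol(pop$values)
  tv <- matrix(NA_real_, nr, nc)
  cell <- pop$cell_m
  rad_cells <- ceiling(reach_radius_m / cell)
  for (i in seq_len(nrow(node_times))) {
    ti <- node_times$time_min[i]
    if (is.na(ti)) next
    pos <- grid_cell_of(pop, node_times$x[i], node_times$y[i])
    if (is.na(pos$row)) next
    rows <- max(1, pos$row - rad_cells):min(nr, pos$row + rad_cells)
    cols <- max(1, pos$col - rad_cells):min(nc, pos$col + rad_cells)
    cxs <- pop$x0 + (cols - 0.5) * cell
    cys <- pop$y0 - (rows - 0.5) * cell
    d2 <- outer((cys - node_times$y[i])^2, (cxs - node_times$x[i])^2, `+`)
    win <- tv[rows, cols, drop = FALSE]
    upd <- d2 <= reach_radius_m^2 & (is.na(win) | win > ti)
    win[upd] <- ti
    tv[rows, cols] <- win
  }
  time_field_grid(tv, cell, pop$x0, pop$y0, crs = attr(pop, "crs"))
}

#' Population by access-time bin
#'
#' Sums population counts per access bin. If the population raster is finer
#' than the binned grid it is first block-summed onto the bin frame (counts
#' are never interpolated), so the table always conserves the raster total.
#'
#' @param access an [bin_times()] result on a cell grid.
#' @param pop a [population_grid()].
#' @return An `impact_table` tibble: `label`, `lo_min`, `hi_min`,
#'   `population`; the K bins first, then `BEYOND_CAP` and `UNREACHABLE`.
#' @export
population_by_bin <- function(access, pop) {
  fa_stopifnot(inherits(access, "access_bins") && !is.null(access$frame),
               "`access` must be binned cell field (bin_times on a grid)")
  pop2 <- resample_population(pop, access$frame)
  fa_stopifnot(same_frame(pop2, access$frame),
               "frame mismatch between access bins and population grid")
  codes <- access$codes
  K <- access$K
  popv <- pop2$values
  bins <- vapply(0:K, function(k) sum(popv[!is.na(codes) & codes == k]), 0)
  unreach <- sum(popv[is.na(codes)])
  k <- 0:(K - 1)
  out <- tibble::tibble(
    label = bin_labels(access),
    lo_min = c(k * access$interval_min, access$cap_min, NA),
    hi_min = c((k + 1) * access$interval_min, Inf, NA),
    population = c(bins, unreach))
  structure(out, class = c("impact_table", class(out)),
            interval_min = access$interval_min, cap_min = access$cap_min,
            total_population = sum(popv))
}

#' Per-cell loss of access between two travel-time fields
#'
#' Compares a pre-flood and a post-flood time field on the same frame.
#' Each cell is classed `NO_CHANGE` (no increase, or out of reach in both
#' conditions), `INCREASED` (both reachable, time went up), or
#' `LOST_ACCESS` (reachable within the cap before, unreachable or beyond
#' the cap after). Negative increases — possible only through snapping or
#' reach-radius artifacts, since removing roads cannot speed travel — are
#' clamped to `NO_CHANGE` and counted.
#'
#' @param before,after `time_field` grids on the same frame.
#' @param cap_min cap in minutes beyond which access counts as lost.
#' @return A `loss_field`: list with `increase` (matrix of minutes),
#'   `category` (matrix: 0 no change, 1 increased, 2 lost), the frame, and
#'   `n_clamped`.
#' @export
access_loss <- function(before, after, cap_min = Inf) {
  fa_stopifnot(same_frame(before, after), "frame mismatch between before and after")
  b <- before$values; a <- after$values
  b_ok <- !is.na(b) & b < cap_min
  a_ok <- !is.na(a) & a < cap_min
  inc <- matrix(0, nrow(b), ncol(b))
  cat_ <- matrix(0L, nrow(b), ncol(b))
  both <- b_ok & a_ok
  inc[both] <- a[both] - b[both]
  n_clamped <- sum(inc[both] < -1e-9)
  inc[inc < 0] <- 0
  cat_[both & inc > 0] <- 1L
  cat_[b_ok & !a_ok] <- 2L
  inc[cat_ == 2L] <- NA_real_
  structure(list(increase = inc, category = cat_,
                 cell_m = before$cell_m, x0 = before$x0, y0 = before$y0,
                 n_clamped = n_clamped),
            class = "loss_field", crs = attr(before, "crs"))
}

#' Population by increase-in-travel-time range
#'
#' Partitions the whole population over the rows `NO_CHANGE`, one row per
#' increase range `(lo, hi]`, and `LOST_ACCESS`; the row sum equals the
#' population raster total.
#'
#' @param loss an [access_loss()] result.
#' @param pop a [population_grid()] (resampled by sum if finer).
#' @param breaks increasing vector of range bounds in minutes; increases
#'   above the last bound fall in an open-ended top range.
#' @return A `loss_table` tibble: `label`, `population`.
#' @export
loss_table <- function(loss, pop, breaks = c(60, 120, 180, 240, 300)) {
  frame <- fa_grid(loss$increase, loss$cell_m, loss$x0, loss$y0,
                   crs = attr(loss, "crs"))
  pop2 <- resample_population(pop, frame)
  popv <- pop2$values
  edges <- c(0, breaks, Inf)
  ranges <- cut(loss$increase[loss$category == 1L], edges, right = TRUE)
  range_pop <- vapply(levels(ranges), function(lv) {
    cells <- which(loss$category == 1L)
    sum(popv[cells][!is.na(ranges) & ranges == lv])
  }, 0)
  lab <- c("NO_CHANGE", paste0("+", levels(ranges), " min"), "LOST_ACCESS")
  out <- tibble::tibble(
    label = lab,
    population = c(sum(popv[loss$category == 0L]), unname(range_pop),
                   sum(popv[loss$category == 2L])))
  structure(out, class = c("loss_table", class(out)),
            total_population = sum(popv), n_clamped = loss$n_clamped)
}

#' Area within a travel-time threshold
#'
#' @param access an [bin_times()] result on a cell grid.
#' @param threshold_min threshold in minutes; must be a multiple of the bin
#'   interval.
#' @return Area in square kilometers of cells with time strictly below the
#'   threshold.
#' @export
area_within_threshold <- function(access, threshold_min) {
  fa_stopifnot(inherits(access, "access_bins") && !is.null(access$frame),
               "`access` must be binned cell field")
  r <- threshold_min / access$interval_min
  fa_stopifnot(abs(r - round(r)) < 1e-9,
               "threshold must be a multiple of the bin interval")
  n <- sum(!is.na(access$codes) & access$codes < round(r))
  n * access$frame$cell_m^2 / 1e6
}

#' Compare raster- and network-based impact tables
#'
#' Side-by-side population per bin for the two accessibility engines, with
#' absolute and percentage differences. Both tables must use the same bin
#' scheme.
#'
#' @param raster_table,network_table `impact_table`s from [population_by_bin()].
#' @param raster_area_km2,network_area_km2 optional areas within a common
#'   threshold (from [area_within_threshold()]) attached to the report.
#' @return A `comparison_report` tibble with one row per bin label (K + 2
#'   rows): `label`, `pop_raster`, `pop_network`, `diff`, `pct_diff`.
#' @export
compare_methods <- function(raster_table, network_table,
                            raster_area_km2 = NULL, network_area_km2 = NULL) {
  same <- identical(raster_table$label, network_table$label) &&
    isTRUE(all.equal(attr(raster_table, "interval_min"),
                     attr(network_table, "interval_min"))) &&
    isTRUE(all.equal(attr(raster_table, "cap_min"),
                     attr(network_table, "cap_min")))
  fa_stopifnot(same, "impact tables use differing bin schemes")
  out <- tibble::tibble(
    label = raster_table$label,
    pop_raster = raster_table$population,
    pop_network = network_table$population,
    diff = network_table$population - raster_table$population)
  out$pct_diff <- ifelse(out$pop_raster > 0, 100 * out$diff / out$pop_raster, NA_real_)
  out <- structure(out, class = c("comparison_report", class(out)))
  if (!is.null(raster_area_km2) || !is.null(network_area_km2)) {
    attr(out, "area_km2") <- c(raster = raster_area_km2 %||% NA_real_,
                               network = network_area_km2 %||% NA_real_)
  }
  out
}
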