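#' Gridded rasters: friction, population and travel-time fields
#'
#' All rasters share one frame convention: a numeric matrix in row-major
#' orientation with row 1 at the *top* of the map, a square cell size
#' `cell_m` in meters, and `(x0, y0)` the top-left corner of the grid in
#' projected meters. `NA` cells are the sentinel for "no value": impassable
#' in a friction grid, unreachable in a time field.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param cell_m cell edge length in meters (> 0).
#' @param x0,y0 coordinates of the top-left corner of the top-left cell.
#' @param crs coordinate reference string; all inputs to a pipeline must share it.
#' @return An object of class `fa_grid` (plus a subclass naming the quantity).
#' @name grids
NULL

fa_grid <- function(values, cell_m, x0, y0, crs = default_crs(),
                    subclass = character()) {
  fa_stopifnot(is.matrix(values) && is.numeric(values), "`values` must be a numeric matrix")
  fa_stopifnot(is.numeric(cell_m) && length(cell_m) == 1 && cell_m > 0,
               "`cell_m` must be a single positive number")
  g <- structure(
    list(values = values, cell_m = as.numeric(cell_m),
         x0 = as.numeric(x0), y0 = as.numeric(y0)),
    class = c(subclass, "fa_grid"))
  attr(g, "crs") <- crs
  g
}

#' @rdname grids
#' @export
friction_grid <- function(values, cell_m, x0, y0, crs = default_crs()) {
  fa_stopifnot(all(values[is.finite(values)] > 0),
               "friction costs must be positive minutes-per-meter")
  fa_grid(values, cell_m, x0, y0, crs, "friction_grid")
}

#' @rdname grids
#' @export
population_grid <- function(values, cell_m, x0, y0, crs = default_crs()) {
  fa_stopifnot(all(is.finite(values)) && all(values >= 0),
               "population cells must be finite and non-negative")
  fa_grid(values, cell_m, x0, y0, crs, "population_grid")
}

time_field_grid <- function(values, cell_m, x0, y0, crs = default_crs()) {
  fa_stopifnot(all(values[!is.na(values)] >= 0), "travel times must be >= 0")
  fa_grid(values, cell_m, x0, y0, crs, "time_field")
}

#' @export
print.fa_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d x %d cells of %g m, top-left (%g, %g)\n",
              class(x)[1], nrow(v), ncol(v), x$cell_m, x$x0, x$y0))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: min %.4g, max %.4g, NA cells %d\n",
                min(fin), max(fin), sum(is.na(v))))
  }
  invisible(x)
}

# Cell-center coordinates as vectors aligned with as.vector(values)
# (column-major, matching R matrix storage).
grid_cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  list(x = g$x0 + (cols - 0.5) * g$cell_m,
       y = g$y0 - (rows - 0.5) * g$cell_m,
       row = rows, col = cols)
}

# Row/col of the cell containing each point; NA outside the grid.
grid_cell_of <- function(g, x, y) {
  col <- floor((x - g$x0) / g$cell_m) + 1
  row <- floor((g$y0 - y) / g$cell_m) + 1
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

same_frame <- function(a, b) {
  isTRUE(all.equal(a$cell_m, b$cell_m)) &&
    isTRUE(all.equal(c(a$x0, a$y0), c(b$x0, b$y0))) &&
    all(dim(a$values) == dim(b$values))
}

#' Resample a population grid to a coarser frame by block sum
#'
#' Counts are summed, never interpolated, so the raster total is conserved
#' exactly. The target cell size must be an integer multiple of the source
#' cell size and the two frames must share their top-left corner.
#'
#' @param pop a [population_grid()].
#' @param target an `fa_grid` giving the target frame.
#' @return A `population_grid` on the target frame.
#' @export
resample_population <- function(pop, target) {
  check_same_crs(pop, target)
  if (same_frame(pop, target)) return(pop)
  ratio <- target$cell_m / pop$cell_m
  fa_stopifnot(abs(ratio - round(ratio)) < 1e-9 && ratio >= 1,
               "target cell size must be an integer multiple of the population cell size")
  fa_stopifnot(isTRUE(all.equal(c(pop$x0, pop$y0), c(target$x0, target$y0))),
               "frame mismatch: grids must share their top-left corner")
  ratio <- as.integer(round(ratio))
  nr <- nrow(target$values); nc <- ncol(target$values)
  out <- matrix(0, nr, nc)
  src <- pop$values
  rb <- (seq_len(nrow(src)) - 1L) %/% ratio + 1L
  cb <- (seq_len(ncol(src)) - 1L) %/% ratio + 1L
  keep_r <- rb <= nr; keep_c <- cb <= nc
  agg <- rowsum(src[keep_r, keep_c, drop = FALSE], rb[keep_r])
  agg <- t(rowsum(t(agg), cb[keep_c]))
  out[seq_len(nrow(agg)), seq_len(ncol(agg))] <- agg
  population_grid(out, target$cell_m, target$x0, target$y0, crs = attr(pop, "crs"))
}

#' Read / write Esri ASCII grids
#'
#' Plain-text raster interchange. `NA` cells are written as the nodata
#' value; a one-line sidecar file `<path>.crs` records the CRS string.
#'
#' @param grid an `fa_grid`.
#' @param path file path (conventionally `.asc`).
#' @param what subclass for the object read back: `"friction"`,
#'   `"population"` or `"time"`.
#' @param nodata nodata marker written to file.
#' @return `read_ascii_grid()` returns an `fa_grid`; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid$y0 - nr * grid$cell_m
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_m),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(attr(grid, "crs") %||% default_crs(), paste0(path, ".crs"))
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, what = c("friction", "population", "time")) {
  what <- match.arg(what)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  fa_stopifnot(all(c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize") %in%
                     names(hdr)),
               sprintf("malformed Esri ASCII header in '%s'", path))
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  fa_stopifnot(length(vals) == nr * nc,
               sprintf("'%s': expected %d cells, found %d", path, nr * nc, length(vals)))
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  crs_path <- paste0(path, ".crs")
  crs <- if (file.exists(crs_path)) readLines(crs_path)[1] else default_crs()
  y0 <- hdr$yllcorner + nr * hdr$cellsize
  ctor <- switch(what, friction = friction_grid, population = population_grid,
                 time = time_field_grid)
  ctor(v, hdr$cellsize, hdr$xllcorner, y0, crs = crs)
}
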