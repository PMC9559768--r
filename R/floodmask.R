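#' Flood masks: polygon sets with union semantics
#'
#' A flood mask is a set of polygons whose union delimits the flooded area.
#' Each polygon is a list of closed rings (first ring the exterior, any
#' further rings holes, interpreted by the even-odd rule); a ring is an
#' n x 2 coordinate matrix in projected meters whose first and last points
#' coincide. Containment queries treat the boundary as inside (a node on
#' the flood edge counts as flooded), and the union of several masks is
#' represented by the collection of member polygons: a point is flooded if
#' it falls inside any of them.
#'
#' @param polygons a list of polygons; each polygon a list of closed ring
#'   matrices, or a single ring matrix (taken as a hole-free polygon).
#' @param crs coordinate reference string.
#' @return An object of class `flood_mask`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)) * 1000
#' m <- flood_mask(list(sq))
#' point_in_mask(500, 500, m)
flood_mask <- function(polygons, crs = default_crs()) {
  fa_stopifnot(is.list(polygons), "`polygons` must be a list")
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  for (i in seq_along(polygons)) {
    for (j in seq_along(polygons[[i]])) {
      r <- polygons[[i]][[j]]
      ok <- is.matrix(r) && ncol(r) == 2 && nrow(r) >= 4 &&
        isTRUE(all.equal(r[1, ], r[nrow(r), ], tolerance = 1e-12)) &&
        all(is.finite(r))
      if (!ok) {
        stop(sprintf("invalid ring at polygon %d, ring %d: rings must be closed numeric matrices with >= 4 points", i, j),
             call. = FALSE)
      }
    }
  }
  m <- structure(list(polygons = polygons), class = "flood_mask")
  attr(m, "crs") <- crs
  m
}

#' @export
print.flood_mask <- function(x, ...) {
  n_ring <- sum(vapply(x$polygons, length, 1L))
  cat(sprintf("<flood_mask> %d polygon(s), %d ring(s), union area %.4g km^2\n",
              length(x$polygons), n_ring, mask_area(x) / 1e6))
  invisible(x)
}

empty_mask <- function(crs = default_crs()) {
  structure(list(polygons = list()), class = "flood_mask", crs = crs)
}

is_empty_mask <- function(mask) length(mask$polygons) == 0

#' Merge two flood masks
#'
#' The result covers the geometric union of the inputs: any point inside
#' either mask is inside the result, and [mask_area()] of the result is the
#' area of the union (never more than the sum of the parts).
#'
#' @param a,b `flood_mask` objects in the same coordinate frame.
#' @return A `flood_mask`.
#' @export
merge_masks <- function(a, b) {
  fa_stopifnot(inherits(a, "flood_mask") && inherits(b, "flood_mask"),
               "`a` and `b` must be flood_mask objects")
  check_same_crs(a, b)
  flood_mask(c(a$polygons, b$polygons), crs = attr(a, "crs"))
}

# Even-odd crossing count of a single polygon (all its rings) for point
# vectors px, py; boundary points are reported separately.
polygon_contains <- function(polygon, px, py, boundary_eps = 1e-9) {
  n <- length(px)
  crossings <- integer(n)
  boundary <- logical(n)
  for (ring in polygon) {
    x1 <- ring[-nrow(ring), 1]; y1 <- ring[-nrow(ring), 2]
    x2 <- ring[-1, 1];          y2 <- ring[-1, 2]
    for (k in seq_along(x1)) {
      straddles <- (y1[k] <= py) != (y2[k] <= py)
      if (any(straddles)) {
        xint <- x1[k] + (py - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
        crossings <- crossings + (straddles & xint > px)
      }
      d <- point_segment_distance(px, py, x1[k], y1[k], x2[k], y2[k])
      boundary <- boundary | d <= boundary_eps
    }
  }
  (crossings %% 2L == 1L) | boundary
}

#' Point-in-mask query
#'
#' Even-odd rule with holes; the boundary counts as inside. `point_in_mask()`
#' answers for a single point, `points_in_mask()` for coordinate vectors.
#'
#' @param x,y point coordinates in meters.
#' @param mask a [flood_mask()].
#' @return Logical, `TRUE` where the point lies in the union.
#' @export
point_in_mask <- function(x, y, mask) {
  points_in_mask(x, y, mask)[1]
}

#' @rdname point_in_mask
#' @export
points_in_mask <- function(x, y, mask) {
  fa_stopifnot(inherits(mask, "flood_mask"), "`mask` must be a flood_mask")
  inside <- logical(length(x))
  for (polygon in mask$polygons) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- polygon_contains(polygon, x[todo], y[todo])
  }
  inside
}

shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Area of the mask union
#'
#' Exact area of the union of all mask polygons (holes subtracted), by slab
#' decomposition: the plane is cut at every vertex y and every pairwise
#' segment-intersection y; within a slab the union cross-section length is
#' linear in y, so evaluating it at the slab midpoint integrates exactly.
#'
#' @param mask a [flood_mask()].
#' @return Area in square meters.
#' @export
mask_area <- function(mask) {
  if (is_empty_mask(mask)) return(0)
  segs <- list()
  for (pi in seq_along(mask$polygons)) {
    for (ring in mask$polygons[[pi]]) {
      n <- nrow(ring)
      segs[[length(segs) + 1]] <- cbind(
        ring[-n, 1], ring[-n, 2], ring[-1, 1], ring[-1, 2], pi)
    }
  }
  segs <- do.call(rbind, segs)
  ys <- c(segs[, 2], segs[, 4])
  # pairwise intersection y's
  m <- nrow(segs)
  for (i in seq_len(m - 1)) {
    p1 <- segs[i, 1:2]; p2 <- segs[i, 3:4]
    r <- p2 - p1
    q1x <- segs[(i + 1):m, 1]; q1y <- segs[(i + 1):m, 2]
    sx <- segs[(i + 1):m, 3] - q1x; sy <- segs[(i + 1):m, 4] - q1y
    denom <- r[1] * sy - r[2] * sx
    ok <- abs(denom) > 1e-12
    if (any(ok)) {
      t <- ((q1x - p1[1]) * sy - (q1y - p1[2]) * sx) / denom
      u <- ((q1x - p1[1]) * r[2] - (q1y - p1[2]) * r[1]) / denom
      hit <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
      if (any(hit)) ys <- c(ys, p1[2] + t[hit] * r[2])
    }
  }
  ys <- sort(unique(ys))
  area <- 0
  for (k in seq_len(length(ys) - 1)) {
    h <- ys[k + 1] - ys[k]
    if (h <= 1e-12) next
    ym <- (ys[k] + ys[k + 1]) / 2
    # per-polygon even-odd intervals at height ym, then union across polygons
    ivals <- NULL
    for (pi in seq_along(mask$polygons)) {
      s <- segs[segs[, 5] == pi, , drop = FALSE]
      straddles <- (s[, 2] <= ym) != (s[, 4] <= ym)
      if (!any(straddles)) next
      s <- s[straddles, , drop = FALSE]
      xint <- s[, 1] + (ym - s[, 2]) * (s[, 3] - s[, 1]) / (s[, 4] - s[, 2])
      xint <- sort(xint)
      if (length(xint) %% 2 == 0 && length(xint) > 0) {
        lo <- xint[seq(1, length(xint), by = 2)]
        hi <- xint[seq(2, length(xint), by = 2)]
        ivals <- rbind(ivals, cbind(lo, hi))
      }
    }
    if (is.null(ivals)) next
    ord <- order(ivals[, 1])
    lo <- ivals[ord, 1]; hi <- ivals[ord, 2]
    total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
    for (j in seq_along(lo)[-1]) {
      if (lo[j] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[j])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[j]; cur_hi <- hi[j]
      }
    }
    total <- total + (cur_hi - cur_lo)
    area <- area + total * h
  }
  unname(area)
}

#' Visvalingam line simplification of a closed ring
#'
#' Iteratively removes the vertex whose triangle with its two neighbours has
#' the smallest effective area, recomputing neighbour areas after each
#' removal, until `ceiling(retain_fraction * n)` points remain (never fewer
#' than 4, the smallest closed ring). Effective areas carry the running
#' maximum of removed areas (the standard monotone update), so the recorded
#' removal areas are non-decreasing. Ties break on the lowest original
#' vertex index.
#'
#' @param ring closed ring matrix (first point equals last point).
#' @param retain_fraction fraction of points to keep, in (0, 1].
#' @return The simplified closed ring, a subset of the input points, with
#'   attribute `removed_areas` giving the effective area of each removed
#'   vertex in removal order.
#' @export
simplify_visvalingam <- function(ring, retain_fraction) {
  fa_stopifnot(is.matrix(ring) && ncol(ring) == 2 && nrow(ring) >= 4,
               "`ring` must be an n x 2 matrix with n >= 4")
  fa_stopifnot(isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], tolerance = 1e-12)),
               "open ring: first and last points must coincide")
  fa_stopifnot(is.numeric(retain_fraction) && retain_fraction > 0 &&
                 retain_fraction <= 1,
               "`retain_fraction` must be in (0, 1]")
  n_total <- nrow(ring)
  target_total <- max(4L, as.integer(ceiling(retain_fraction * n_total)))
  if (target_total >= n_total) {
    out <- ring
    attr(out, "removed_areas") <- numeric(0)
    return(out)
  }
  pts <- ring[-n_total, , drop = FALSE]   # unique vertices, circular
  m <- nrow(pts)
  target_m <- target_total - 1L
  alive <- rep(TRUE, m)
  nxt <- c(seq_len(m)[-1], 1L)
  prv <- c(m, seq_len(m)[-m])
  tri_area <- function(i) {
    a <- pts[prv[i], ]; b <- pts[i, ]; c <- pts[nxt[i], ]
    abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
  }
  areas <- vapply(seq_len(m), tri_area, 0)
  removed_areas <- numeric(0)
  carry <- 0
  n_alive <- m
  while (n_alive > target_m) {
    idx <- which(alive)
    eff <- pmax(areas[idx], carry)
    best <- idx[which.min(eff)]   # which.min takes the first = lowest index
    carry <- max(carry, areas[best])
    removed_areas <- c(removed_areas, carry)
    alive[best] <- FALSE
    n_alive <- n_alive - 1L
    p <- prv[best]; q <- nxt[best]
    nxt[p] <- q; prv[q] <- p
    areas[p] <- tri_area(p)
    areas[q] <- tri_area(q)
  }
  keep <- sort(which(alive))
  out <- rbind(pts[keep, , drop = FALSE], pts[keep[1], , drop = FALSE])
  attr(out, "removed_areas") <- removed_areas
  out
}

#' Simplify every ring of a mask
#'
#' Applies [simplify_visvalingam()] per ring; the canonical preprocessing
#' retains one percent of points per ring (with the 4-point floor).
#'
#' @param mask a [flood_mask()].
#' @param retain_fraction fraction of points retained per ring.
#' @return A simplified `flood_mask` with attribute `retain_fraction`.
#' @export
simplify_mask <- function(mask, retain_fraction = 0.01) {
  polys <- lapply(mask$polygons, function(p) {
    lapply(p, function(r) {
      s <- simplify_visvalingam(r, retain_fraction)
      attr(s, "removed_areas") <- NULL
      s
    })
  })
  out <- flood_mask(polys, crs = attr(mask, "crs"))
  attr(out, "retain_fraction") <- retain_fraction
  out
}
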