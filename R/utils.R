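# Internal helpers: seed streams, planar geometry, validation.

# Derive a generator-specific RNG seed from the scenario seed. Fixed affine
# offsets keep the streams decoupled; result stays below 2^31 - 1.
fa_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offset) %% 2147483629L
}

fa_stopifnot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @importFrom stats runif rnorm rlnorm rmultinom
NULL

# Squared / plain Euclidean distance from points (px, py) to segment
# (ax, ay)-(bx, by). Vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - ax)^2 + (py - ay)^2))
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# TRUE if segments p1-p2 and q1-q2 intersect (touching counts).
segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

check_extent <- function(extent) {
  fa_stopifnot(is.numeric(extent) && length(extent) == 4 &&
                 all(is.finite(extent)),
               "`extent` must be numeric c(xmin, ymin, xmax, ymax)")
  fa_stopifnot(extent[3] > extent[1] && extent[4] > extent[2],
               "degenerate extent: xmax must exceed xmin and ymax exceed ymin")
  invisible(extent)
}

default_crs <- function() "local:meters"

check_same_crs <- function(a, b) {
  ca <- attr(a, "crs") %||% default_crs()
  cb <- attr(b, "crs") %||% default_crs()
  fa_stopifnot(identical(ca, cb),
               sprintf("CRS mismatch: '%s' vs '%s' (no silent reprojection)", ca, cb))
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
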