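# Planar convex-polygon primitives used by the range module.
#
# All polygons are two-column matrices (x, y) in km, vertices ordered
# counter-clockwise, without a repeated closing vertex. These are internal:
# the user-facing surface is in geo_ranges.R.

# Twice the signed area of triangle (o, a, b); > 0 when the turn o->a->b is
# counter-clockwise.
cross2 <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

#' Shoelace area of a polygon
#'
#' Signed area is positive for counter-clockwise vertex order; the absolute
#' value is returned.
#'
#' @param poly two-column numeric matrix of vertices (no closing repeat).
#' @return area in squared input units.
#' @keywords internal
#' @noRd
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Andrew's monotone-chain convex hull. Returns vertices counter-clockwise
# with collinear boundary points dropped (strictly convex polygon). For
# degenerate inputs (< 3 non-collinear points) the result has fewer than 3
# rows: the distinct extreme points.
monotone_chain <- function(pts) {
  pts <- unique(pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2L &&
             cross2(pts[h[length(h) - 1L], ], pts[h[length(h)], ], pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  idx <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(idx) < 3L) {
    # all points collinear: keep the two extremes
    return(pts[c(1L, n), , drop = FALSE])
  }
  pts[idx, , drop = FALSE]
}

# Clip a convex polygon by the half-plane {p : n . p <= c}. Standard
# Sutherland-Hodgman edge pass; returns a matrix with 0 rows when the
# polygon lies entirely outside.
clip_halfplane <- function(poly, normal, c0, tol = 1e-12) {
  n <- nrow(poly)
  if (is.null(n) || n == 0L) return(poly[0L, , drop = FALSE])
  s <- poly %*% normal - c0
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- s[i]; sj <- s[j]
    if (si <= tol) out <- rbind(out, poly[i, ])
    if ((si < -tol && sj > tol) || (si > tol && sj < -tol)) {
      t <- si / (si - sj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Area of the intersection of two convex polygons: clip a successively by
# every edge half-plane of b (b counter-clockwise, so the interior is the
# left side of each directed edge).
convex_intersection <- function(a, b) {
  out <- a
  n <- nrow(b)
  for (i in seq_len(n)) {
    if (nrow(out) == 0L) break
    j <- if (i == n) 1L else i + 1L
    e <- b[j, ] - b[i, ]
    # interior of a CCW polygon satisfies  (-ey, ex) . (p - b_i) >= 0,
    # i.e. (ey, -ex) . p <= (ey, -ex) . b_i
    nrm <- c(e[2L], -e[1L])
    out <- clip_halfplane(out, nrm, sum(nrm * b[i, ]))
  }
  out
}

# Vectorised point-in-convex-polygon test (boundary counts as inside).
# poly CCW; pts an n x 2 matrix. Returns logical vector.
points_in_convex <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    v <- e[1L] * (pts[, 2L] - poly[i, 2L]) - e[2L] * (pts[, 1L] - poly[i, 1L])
    inside <- inside & (v >= -tol)
  }
  inside
}

# Split a convex polygon into two complementary parts by a straight chord
# whose direction is given by angle theta, positioned so that the part on
# the lower side takes `fraction` of the total area. Returns a list of the
# two CCW parts.
split_by_chord <- function(poly, theta, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  nrm <- c(cos(theta), sin(theta))
  proj <- as.numeric(poly %*% nrm)
  lo <- min(proj); hi <- max(proj)
  total <- polygon_area(poly)
  f <- function(c0) polygon_area(clip_halfplane(poly, nrm, c0)) / total - fraction
  c0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  a <- clip_halfplane(poly, nrm, c0)
  b <- clip_halfplane(poly, -nrm, -c0)
  list(a, b)
}
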