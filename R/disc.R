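#' Optic disc area and ovality ratio
#'
#' The disc area follows the pixel-counting definition: the number of
#' raster pixel centers (integer coordinates) strictly inside the
#' boundary polygon under the even-odd rule. The ovality ratio is the
#' minimum Feret diameter of the boundary divided by the maximum Feret
#' diameter, in `(0, 1]`; 1 means a circular disc.
#'
#' @param boundary Numeric n x 2 matrix (columns x, y), a simple closed
#'   polygon with at least 8 vertices. Self-intersecting polygons are
#'   rejected.
#' @return One-row tibble with columns `disc_area` (px^2) and
#'   `ovality_ratio`.
#' @export
#' @examples
#' sq <- cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5))
#' disc_metrics(sq)
disc_metrics <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 8) {
    stop("boundary must be an n x 2 matrix with n >= 8", call. = FALSE)
  }
  if (!all(is.finite(boundary))) {
    stop("boundary contains non-finite coordinates", call. = FALSE)
  }
  if (!polygon_is_simple(boundary)) {
    stop("disc boundary polygon is self-intersecting", call. = FALSE)
  }
  fer <- feret_diameters(boundary)
  tibble::tibble(
    disc_area = pixel_area(boundary),
    ovality_ratio = unname(fer["min"] / fer["max"])
  )
}

## count integer pixel centers strictly inside the polygon (even-odd rule)
pixel_area <- function(poly) {
  xs <- seq(ceiling(min(poly[, 1])), floor(max(poly[, 1])))
  ys <- seq(ceiling(min(poly[, 2])), floor(max(poly[, 2])))
  if (length(xs) == 0 || length(ys) == 0) return(0)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  sum(points_in_polygon(px, py, poly))
}

## even-odd (ray casting) point-in-polygon test, vectorized over points;
## points exactly on an edge are treated as outside (strict interior for
## points in generic position)
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## min and max Feret (caliper) diameters of a point set, via its convex
## hull: the max is attained by a vertex pair, the min by the width
## perpendicular to a hull edge (rotating calipers)
feret_diameters <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) {
    d <- sqrt(max(rowSums(sweep(hp, 2, hp[1, ])^2)))
    return(c(min = 0, max = d))
  }
  dmax <- 0
  for (i in seq_len(m - 1)) {
    d2 <- (hp[(i + 1):m, 1] - hp[i, 1])^2 + (hp[(i + 1):m, 2] - hp[i, 2])^2
    dmax <- max(dmax, d2)
  }
  dmax <- sqrt(dmax)
  dmin <- Inf
  for (i in seq_len(m)) {
    a <- hp[i, ]
    b <- hp[if (i == m) 1 else i + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    ## unit normal to the edge; width = extent of projections onto it
    nrm <- c(-e[2], e[1]) / len
    proj <- (hp[, 1] - a[1]) * nrm[1] + (hp[, 2] - a[2]) * nrm[2]
    dmin <- min(dmin, max(proj) - min(proj))
  }
  c(min = dmin, max = dmax)
}

## simple-polygon check: no two non-adjacent edges intersect
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges adjacent to edge i
    if (length(js) == 0) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

## proper-intersection test of segment (p1, p2) against rows of (q1, q2)
segments_intersect <- function(p1, p2, q1, q2) {
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p1[1], p1[2])
  d2 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p2[1], p2[2])
  d3 <- cross(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
  d4 <- cross(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
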