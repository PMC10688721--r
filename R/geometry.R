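#' Radially project a point onto a circle
#'
#' Clicked vessel crossings land near, not exactly on, the vessel
#' measurement circle; all angle and distance computations first snap them
#' radially. A displacement larger than `tolerance` triggers a warning
#' (the click was suspiciously far from the circle), never an error.
#'
#' @param point,center Numeric `c(x, y)` points; `point` must differ from
#'   `center`.
#' @param radius Circle radius (px), positive.
#' @param tolerance Warn when the radial displacement exceeds this (px).
#' @return The projected `c(x, y)` point, with the displacement attached
#'   as attribute `"displacement"`.
#' @export
#' @examples
#' project_to_circle(c(520, 0), c(0, 0), 260)
project_to_circle <- function(point, center, radius, tolerance = Inf) {
  stopifnot(radius > 0)
  v <- as.numeric(point) - as.numeric(center)
  d <- sqrt(sum(v^2))
  if (d == 0) {
    stop("cannot project the circle center onto the circle", call. = FALSE)
  }
  disp <- abs(d - radius)
  if (disp > tolerance) {
    warning(sprintf(
      "crossing point is %.2f px off the measurement circle (tolerance %.2f px)",
      disp, tolerance
    ), call. = FALSE)
  }
  structure(as.numeric(center) + v * (radius / d), displacement = disp)
}

## unsigned angle between two vectors, degrees in [0, 180]
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("angle undefined for a zero-length vector", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

## unit vector from the disc center toward the temporal side: horizontal,
## pointing toward the half-plane containing the fovea
temporal_direction <- function(lm) {
  dx <- lm$fovea[1] - lm$disc_center[1]
  if (dx == 0) {
    stop("temporal direction undefined: fovea is vertically above/below the disc center",
         call. = FALSE)
  }
  c(sign(dx), 0)
}

#' Retinal vessel angles at the measurement circle
#'
#' The four landmarked crossings of the major supratemporal (ST) and
#' infratemporal (IT) retinal arteries (RA) and veins (RV) with the
#' vessel measurement circle are snapped onto the circle, and each vessel
#' angle is the unsigned angle at the disc center between the temporal
#' horizontal ray (the horizontal ray from the disc center toward the
#' fovea side) and the ray to the crossing. The total angles are the sums
#' `T_RA = ST_RA + IT_RA` and `T_RV = ST_RV + IT_RV`, i.e. the angle
#' subtended between the two vessels of each type.
#'
#' @param lm A [landmark_set()].
#' @param cfg A [measurement_config()].
#' @return One-row tibble with columns `T_RA`, `ST_RA`, `IT_RA`, `T_RV`,
#'   `ST_RV`, `IT_RV` (degrees).
#' @export
vessel_angles <- function(lm, cfg = measurement_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  tdir <- temporal_direction(lm)
  r <- cfg$vessel_circle_diameter / 2
  ang <- function(which) {
    p <- project_to_circle(lm$crossings[[which]], lm$disc_center, r,
                           cfg$crossing_tolerance)
    angle_between(p - lm$disc_center, tdir)
  }
  st_ra <- ang("st_artery"); it_ra <- ang("it_artery")
  st_rv <- ang("st_vein");   it_rv <- ang("it_vein")
  tibble::tibble(
    T_RA = st_ra + it_ra, ST_RA = st_ra, IT_RA = it_ra,
    T_RV = st_rv + it_rv, ST_RV = st_rv, IT_RV = it_rv
  )
}

#' Crossing-to-fovea distances and angles
#'
#' For each of the four (circle-snapped) vessel crossings: the Euclidean
#' distance to the fovea, and the unsigned angle at the fovea between the
#' fovea-to-crossing ray and the fovea-to-disc-center ray.
#'
#' @inheritParams vessel_angles
#' @return One-row tibble with columns `STAFD`, `ITAFD`, `STVFD`, `ITVFD`
#'   (px) and `STAFA`, `ITAFA`, `STVFA`, `ITVFA` (degrees).
#' @export
fovea_vessel_metrics <- function(lm, cfg = measurement_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  r <- cfg$vessel_circle_diameter / 2
  to_disc <- lm$disc_center - lm$fovea
  one <- function(which) {
    p <- project_to_circle(lm$crossings[[which]], lm$disc_center, r,
                           cfg$crossing_tolerance)
    v <- p - lm$fovea
    d <- sqrt(sum(v^2))
    if (d == 0) {
      stop(sprintf("crossing %s coincides with the fovea: angle undefined", which),
           call. = FALSE)
    }
    c(d, angle_between(v, to_disc))
  }
  sa <- one("st_artery"); ia <- one("it_artery")
  sv <- one("st_vein");   iv <- one("it_vein")
  tibble::tibble(
    STAFD = sa[1], ITAFD = ia[1], STVFD = sv[1], ITVFD = iv[1],
    STAFA = sa[2], ITAFA = ia[2], STVFA = sv[2], ITVFA = iv[2]
  )
}

#' Papillomacular distance and angle
#'
#' `PMD` is the distance from the optic disc center to the fovea; `PMA`
#' is the unsigned acute angle between that line and the horizontal, in
#' `[0, 90]` degrees. Both are symmetric in the two endpoints.
#'
#' @inheritParams vessel_angles
#' @return One-row tibble with columns `PMD` (px) and `PMA` (degrees).
#' @export
papillomacular_metrics <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  v <- lm$fovea - lm$disc_center
  tibble::tibble(
    PMD = sqrt(sum(v^2)),
    PMA = atan2(abs(v[2]), abs(v[1])) * 180 / pi
  )
}

#' Centers of the eight peripapillary color circles
#'
#' The temporal circle center lies on the disc-to-fovea ray at the ring
#' center distance; the remaining seven follow at 45-degree steps around
#' the disc center, sweeping first through the superior side (smaller y in
#' raster coordinates), giving the compass order T, ST, S, SN, N, IN, I,
#' IT.
#'
#' @inheritParams vessel_angles
#' @param image_size Optional `c(width, height)`; when given, any circle
#'   extending outside the raster raises an error.
#' @return Tibble with columns `roi`, `x`, `y` (8 rows).
#' @export
peripapillary_centers <- function(lm, cfg = measurement_config(),
                                  image_size = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  u <- lm$fovea - lm$disc_center
  t0 <- atan2(u[2], u[1])
  ## step direction: the first 45-degree step must decrease y (superior)
  step <- if (sin(t0 - pi / 4) <= sin(t0 + pi / 4)) -pi / 4 else pi / 4
  t <- t0 + step * (0:7)
  centers <- tibble::tibble(
    roi = roi_labels()[1:8],
    x = lm$disc_center[1] + cfg$ring_center_distance * cos(t),
    y = lm$disc_center[2] + cfg$ring_center_distance * sin(t)
  )
  if (!is.null(image_size)) {
    rad <- cfg$peripapillary_circle_diameter / 2
    bad <- centers$x - rad < 0 | centers$x + rad > image_size[1] - 1 |
      centers$y - rad < 0 | centers$y + rad > image_size[2] - 1
    if (any(bad)) {
      stop(sprintf("peripapillary circle(s) %s extend outside the image",
                   paste(centers$roi[bad], collapse = ", ")), call. = FALSE)
    }
  }
  centers
}
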