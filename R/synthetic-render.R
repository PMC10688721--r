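#' Rendering parameters for one schematic eye
#'
#' Describes a synthetic fundus: an elliptical optic disc, four retinal
#' vessels drawn as circular arcs launched from the disc center so that
#' their crossing with the vessel measurement circle has a closed form,
#' and a tessellated background whose patches (and the vessels) rescale
#' the base color's brightness only --- so the tessellation fundus index
#' of every region equals the base-color TFI analytically.
#'
#' @param image_size Square raster side (px).
#' @param disc_center,fovea `c(x, y)` points, both inside the raster.
#' @param disc_semi_major,disc_semi_minor Disc ellipse semi-axes (px),
#'   minor <= major.
#' @param disc_rotation Ellipse rotation (degrees).
#' @param vessels Named list (`st_artery`, `it_artery`, `st_vein`,
#'   `it_vein`), each a list with `launch_angle` (degrees from the
#'   temporal horizontal ray), `arc_radius` (px, curvature radius of the
#'   vessel arc) and `width` (px).
#' @param base_rgb Background base color, integers in `[0, 204]` so a
#'   brightness factor up to 1.25 cannot clip.
#' @param patch_count Number of tessellation patches.
#' @param patch_radius Length-2 range of patch radii (px).
#' @param patch_contrast Length-2 range of patch brightness factors.
#' @param vessel_factor Vessel brightness factor (relative to base).
#' @param disc_rgb Disc fill color.
#' @param vessel_circle_diameter Diameter (px) of the measurement circle
#'   the vessels must cross (kept with the parameters so rendering and
#'   measurement agree).
#' @param seed Integer seed for the patch field.
#' @return An object of class `eye_render_params`.
#' @export
eye_render_params <- function(image_size = 1500,
                              disc_center = c(980, 750),
                              fovea = c(380, 750),
                              disc_semi_major = 115,
                              disc_semi_minor = 105,
                              disc_rotation = 0,
                              vessels = default_vessels(),
                              base_rgb = c(170, 95, 55),
                              patch_count = 250,
                              patch_radius = c(8, 28),
                              patch_contrast = c(0.8, 1.2),
                              vessel_factor = 0.55,
                              disc_rgb = c(235, 200, 160),
                              vessel_circle_diameter = 520,
                              seed = 1L) {
  inside <- function(p) all(p >= 0) && all(p <= image_size - 1)
  if (!inside(disc_center) || !inside(fovea)) {
    stop("disc center and fovea must lie inside the image", call. = FALSE)
  }
  if (disc_semi_minor > disc_semi_major) {
    stop("disc semi-minor axis must not exceed the semi-major axis",
         call. = FALSE)
  }
  if (any(base_rgb < 0) || any(base_rgb * max(patch_contrast) > 255) ||
      any(disc_rgb < 0) || any(disc_rgb > 255)) {
    stop("colors must stay within [0, 255] after patch contrast scaling",
         call. = FALSE)
  }
  need <- c("st_artery", "it_artery", "st_vein", "it_vein")
  if (!all(need %in% names(vessels))) {
    stop("vessels must name st_artery, it_artery, st_vein, it_vein",
         call. = FALSE)
  }
  r <- vessel_circle_diameter / 2
  for (v in need) {
    if (2 * vessels[[v]]$arc_radius < r) {
      stop(sprintf(
        "vessel %s: arc radius %.0f px is too tight to reach the measurement circle (need >= %.0f)",
        v, vessels[[v]]$arc_radius, r / 2
      ), call. = FALSE)
    }
  }
  structure(
    list(image_size = image_size, disc_center = disc_center, fovea = fovea,
         disc_semi_major = disc_semi_major, disc_semi_minor = disc_semi_minor,
         disc_rotation = disc_rotation, vessels = vessels[need],
         base_rgb = round(base_rgb), patch_count = patch_count,
         patch_radius = patch_radius, patch_contrast = patch_contrast,
         vessel_factor = vessel_factor, disc_rgb = disc_rgb,
         vessel_circle_diameter = vessel_circle_diameter,
         seed = as.integer(seed)),
    class = "eye_render_params"
  )
}

default_vessels <- function(st_ra = 38, it_ra = 35, st_rv = 45, it_rv = 42) {
  list(
    st_artery = list(launch_angle = st_ra, arc_radius = 900, width = 12),
    it_artery = list(launch_angle = it_ra, arc_radius = 900, width = 12),
    st_vein = list(launch_angle = st_rv, arc_radius = 950, width = 16),
    it_vein = list(launch_angle = it_rv, arc_radius = 950, width = 16)
  )
}

#' Draw rendering parameters from a simulation configuration
#'
#' Samples the geometric and color features a schematic rendering can
#' express (vessel launch angles, papillomacular distance and angle, disc
#' area and ovality, temporal-region tessellation fundus index) from the
#' per-sex marginal distributions of `cfg`, and converts them to
#' [eye_render_params()]: the disc semi-axes solve `area = pi * a * b`
#' and `ovality = b / a`; the fovea is placed temporally (negative x)
#' from the disc center at the drawn papillomacular distance and angle;
#' the base color realizes the drawn TFI at a fixed brightness.
#'
#' @param cfg A [sim_config()].
#' @param sex `"female"` or `"male"`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return An [eye_render_params()].
#' @export
sample_eye_parameters <- function(cfg, sex = c("female", "male"), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  sex <- match.arg(sex)
  mu <- if (sex == "female") cfg$feature_means_f else cfg$feature_means_m
  sd <- cfg$feature_sds
  with_seed(seed, {
    draw <- function(f) stats::rnorm(1, mu[[f]], sd[[f]])
    st_ra <- clamp(draw("ST_RA"), 8, 85)
    it_ra <- clamp(draw("IT_RA"), 8, 85)
    st_rv <- clamp(draw("ST_RV"), 8, 85)
    it_rv <- clamp(draw("IT_RV"), 8, 85)
    pmd <- clamp(draw("PMD"), 450, 700)
    pma <- clamp(draw("PMA"), 0, 20)
    area <- clamp(draw("disc_area"), 15000, 60000)
    oval <- clamp(draw("ovality_ratio"), 0.55, 1)
    tfi <- clamp(draw("T_TFI"), 0.3, 0.7)
    rot <- stats::runif(1, 0, 180)

    b <- sqrt(area * oval / pi)
    a <- b / oval
    disc <- c(980, 750)
    fov <- disc + pmd * c(-cos(pma * pi / 180), sin(pma * pi / 180))

    ## base color with the drawn TFI at fixed brightness; green/blue split fixed
    lum <- 320
    red <- tfi * lum
    base <- c(red, 0.58 * (lum - red), 0.42 * (lum - red))

    eye_render_params(
      disc_center = disc, fovea = fov,
      disc_semi_major = a, disc_semi_minor = b, disc_rotation = rot,
      vessels = default_vessels(st_ra, it_ra, st_rv, it_rv),
      base_rgb = base,
      seed = seed
    )
  })
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Render a schematic fundus image with exact ground-truth landmarks
#'
#' Produces the raster and the landmark set an annotator would supply,
#' except that every landmark is analytically exact: the disc boundary is
#' a 64-gon sampled from the disc ellipse, and each vessel-circle
#' crossing point is computed in closed form from the vessel's launch
#' angle (the vessel arc is the circle of radius `arc_radius` through the
#' disc center and that crossing point). The returned object also carries
#' the implied true feature values for round-trip checks.
#'
#' @param p An [eye_render_params()].
#' @return A list of class `rendered_eye` with elements `image`
#'   ([fundus_image()]), `landmarks` ([landmark_set()]) and `truth`
#'   (one-row tibble of the generator's implied feature values: the four
#'   launch angles, crossing-fovea distances/angles, `PMD`, `PMA`,
#'   `ovality_ratio`, `disc_area` of the boundary 64-gon, and the
#'   background `TFI` shared by all nine regions).
#' @export
render_fundus_image <- function(p) {
  stopifnot(inherits(p, "eye_render_params"))
  n <- p$image_size
  disc <- p$disc_center
  r_meas <- p$vessel_circle_diameter / 2

  ## exact crossing points: temporal horizontal ray from the disc center
  ## points toward the fovea's side; superior means smaller y
  s <- sign(p$fovea[1] - disc[1])
  crossing_at <- function(angle_deg, superior) {
    t <- angle_deg * pi / 180
    disc + r_meas * c(s * cos(t), if (superior) -sin(t) else sin(t))
  }
  crossings <- list(
    st_artery = crossing_at(p$vessels$st_artery$launch_angle, TRUE),
    it_artery = crossing_at(p$vessels$it_artery$launch_angle, FALSE),
    st_vein = crossing_at(p$vessels$st_vein$launch_angle, TRUE),
    it_vein = crossing_at(p$vessels$it_vein$launch_angle, FALSE)
  )

  ## disc boundary 64-gon from the rotated ellipse
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  rot <- p$disc_rotation * pi / 180
  ex <- p$disc_semi_major * cos(th)
  ey <- p$disc_semi_minor * sin(th)
  boundary <- cbind(
    disc[1] + ex * cos(rot) - ey * sin(rot),
    disc[2] + ex * sin(rot) + ey * cos(rot)
  )

  img <- with_seed(p$seed, render_raster(p, crossings))

  lm <- landmark_set(
    disc_center = disc, fovea = p$fovea, disc_boundary = boundary,
    crossings = crossings,
    laterality = if (s < 0) "right" else "left"
  )

  base <- p$base_rgb
  truth <- dplyr::bind_cols(
    tibble::tibble(
      ST_RA = p$vessels$st_artery$launch_angle,
      IT_RA = p$vessels$it_artery$launch_angle,
      ST_RV = p$vessels$st_vein$launch_angle,
      IT_RV = p$vessels$it_vein$launch_angle
    ),
    fovea_crossing_truth(crossings, p$fovea, disc),
    tibble::tibble(
      PMD = sqrt(sum((p$fovea - disc)^2)),
      PMA = atan2(abs(p$fovea[2] - disc[2]), abs(p$fovea[1] - disc[1])) * 180 / pi,
      ovality_ratio = p$disc_semi_minor / p$disc_semi_major,
      disc_area = abs(polygon_signed_area(boundary)),
      TFI = base[1] / sum(base)
    )
  )
  structure(list(image = img, landmarks = lm, truth = truth),
            class = "rendered_eye")
}

#' @export
print.rendered_eye <- function(x, ...) {
  cat(sprintf("rendered_eye: %d x %d px, %s eye\n",
              x$image$width, x$image$height, x$landmarks$laterality))
  invisible(x)
}

fovea_crossing_truth <- function(crossings, fovea, disc) {
  to_disc <- disc - fovea
  one <- function(p) {
    v <- p - fovea
    c(sqrt(sum(v^2)), angle_between(v, to_disc))
  }
  sa <- one(crossings$st_artery); ia <- one(crossings$it_artery)
  sv <- one(crossings$st_vein);   iv <- one(crossings$it_vein)
  tibble::tibble(
    STAFD = sa[1], ITAFD = ia[1], STVFD = sv[1], ITVFD = iv[1],
    STAFA = sa[2], ITAFA = ia[2], STVFA = sv[2], ITVFA = iv[2]
  )
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

## --- rasterization ---------------------------------------------------------

render_raster <- function(p, crossings) {
  n <- p$image_size
  ## brightness-factor field: patches and vessels overwrite (not
  ## multiply), so values never leave the configured contrast range.
  ## All sub-assignments run in this frame so the field is modified in
  ## place instead of being copied per primitive.
  fac <- matrix(1, n, n)
  clip <- function(cx, cy, rad) {
    x0 <- max(0, ceiling(cx - rad)); x1 <- min(n - 1, floor(cx + rad))
    y0 <- max(0, ceiling(cy - rad)); y1 <- min(n - 1, floor(cy + rad))
    if (x0 > x1 || y0 > y1) NULL else list(xs = x0:x1, ys = y0:y1)
  }
  if (p$patch_count > 0) {
    cx <- stats::runif(p$patch_count, 0, n - 1)
    cy <- stats::runif(p$patch_count, 0, n - 1)
    rad <- stats::runif(p$patch_count, p$patch_radius[1], p$patch_radius[2])
    f <- stats::runif(p$patch_count, p$patch_contrast[1], p$patch_contrast[2])
    for (i in seq_len(p$patch_count)) {
      b <- clip(cx[i], cy[i], rad[i])
      if (is.null(b)) next
      mask <- outer((b$ys - cy[i])^2, (b$xs - cx[i])^2, "+") <= rad[i]^2
      sub <- fac[b$ys + 1, b$xs + 1, drop = FALSE]
      sub[mask] <- f[i]
      fac[b$ys + 1, b$xs + 1] <- sub
    }
  }
  for (v in names(p$vessels)) {
    g <- arc_geometry(p$disc_center, crossings[[v]],
                      p$vessels[[v]]$arc_radius)
    w2 <- p$vessels[[v]]$width / 2
    x0 <- max(0, floor(min(g$px) - w2)); x1 <- min(n - 1, ceiling(max(g$px) + w2))
    y0 <- max(0, floor(min(g$py) - w2)); y1 <- min(n - 1, ceiling(max(g$py) + w2))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - g$o[1])
    dy <- outer(ys - g$o[2], rep(1, length(xs)))
    ring <- abs(sqrt(dx^2 + dy^2) - g$R) <= w2
    ## angular window: sweep from the disc center to 18% past the crossing
    rel <- ((atan2(dy, dx) - g$a0) * sign(g$span)) %% (2 * pi)
    mask <- ring & rel <= abs(g$span) * 1.18
    sub <- fac[ys + 1, xs + 1, drop = FALSE]
    sub[mask] <- p$vessel_factor
    fac[ys + 1, xs + 1] <- sub
  }
  base <- p$base_rgb
  chan <- list(r = base[1] * fac, g = base[2] * fac, b = base[3] * fac)

  ## disc ellipse fill (drawn over background and vessel roots)
  chan <- fill_ellipse(chan, p$disc_center, p$disc_semi_major,
                       p$disc_semi_minor, p$disc_rotation, p$disc_rgb)
  fundus_image(round(chan$r), round(chan$g), round(chan$b))
}

## circle of radius R through `from` and `to` (fixed branch of the two
## centers), with the short angular sweep from `from` to `to`; sampled
## points bound the raster region to touch
arc_geometry <- function(from, to, R) {
  chord <- to - from
  d <- sqrt(sum(chord^2))
  h <- sqrt(max(0, R^2 - (d / 2)^2))
  mid <- (from + to) / 2
  nrm <- c(-chord[2], chord[1]) / d
  o <- mid + h * nrm
  a0 <- atan2(from[2] - o[2], from[1] - o[1])
  a1 <- atan2(to[2] - o[2], to[1] - o[1])
  span <- atan2(sin(a1 - a0), cos(a1 - a0))
  tt <- a0 + seq(0, 1.18, length.out = 64) * span
  list(o = o, R = R, a0 = a0, span = span,
       px = o[1] + R * cos(tt), py = o[2] + R * sin(tt))
}

fill_ellipse <- function(chan, center, a, b, rot_deg, rgb) {
  rad <- max(a, b)
  x0 <- max(0, ceiling(center[1] - rad))
  x1 <- min(ncol(chan$r) - 1, floor(center[1] + rad))
  y0 <- max(0, ceiling(center[2] - rad))
  y1 <- min(nrow(chan$r) - 1, floor(center[2] + rad))
  if (x0 > x1 || y0 > y1) return(chan)
  xs <- x0:x1
  ys <- y0:y1
  rot <- rot_deg * pi / 180
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(ys - center[2], rep(1, length(xs)))
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  for (k in 1:3) {
    ch <- c("r", "g", "b")[k]
    sub <- chan[[ch]][ys + 1, xs + 1, drop = FALSE]
    sub[mask] <- rgb[k]
    chan[[ch]][ys + 1, xs + 1] <- sub
  }
  chan
}
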