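# shared fixtures: landmark sets and brute-force oracles, all built in code

circle_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

ellipse_polygon <- function(center, a, b, rot_deg = 0, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rot <- rot_deg * pi / 180
  ex <- a * cos(th); ey <- b * sin(th)
  cbind(center[1] + ex * cos(rot) - ey * sin(rot),
        center[2] + ex * sin(rot) + ey * cos(rot))
}

# right-eye-style landmarks: disc at (500, 500), fovea temporal at +x,
# crossings at given angles (degrees) on the 260 px measurement circle
make_landmarks <- function(disc = c(500, 500), fovea = c(800, 500),
                           st_ra = 45, it_ra = 30, st_rv = 50, it_rv = 40,
                           r = 260) {
  s <- sign(fovea[1] - disc[1])
  at <- function(a, superior) {
    t <- a * pi / 180
    disc + r * c(s * cos(t), if (superior) -sin(t) else sin(t))
  }
  landmark_set(
    disc_center = disc, fovea = fovea,
    disc_boundary = circle_polygon(disc, 100),
    crossings = list(
      st_artery = at(st_ra, TRUE), it_artery = at(it_ra, FALSE),
      st_vein = at(st_rv, TRUE), it_vein = at(it_rv, FALSE)
    ),
    laterality = if (s < 0) "right" else "left"
  )
}

# brute-force Feret oracle: projection extents over a fine direction grid
# (min) and all vertex pairs (max)
feret_oracle <- function(pts, n_dir = 36000) {
  th <- seq(0, pi, length.out = n_dir)
  widths <- vapply(th, function(t) {
    proj <- pts[, 1] * cos(t) + pts[, 2] * sin(t)
    max(proj) - min(proj)
  }, numeric(1))
  d <- as.matrix(stats::dist(pts))
  c(min = min(widths), max = max(d))
}

# brute-force per-pixel ROI mean oracle
roi_mean_oracle <- function(mat, center, diameter) {
  acc <- 0; cnt <- 0
  r2 <- (diameter / 2)^2
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      if ((j - 1 - center[1])^2 + (i - 1 - center[2])^2 <= r2) {
        acc <- acc + mat[i, j]; cnt <- cnt + 1
      }
    }
  }
  acc / cnt
}

# brute-force AUROC oracle: explicit pair counting
auroc_oracle <- function(scores, labels, positive = "female") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force Holm oracle straight from the step-down definition
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
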