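test_that("disc area counts interior pixel centers and ovality uses Feret diameters", {
  # 10 x 10 px axis-aligned square covering pixel centers 0..9
  sq <- cbind(c(-0.5, 4.5, 9.5, 9.5, 9.5, 4.5, -0.5, -0.5),
              c(-0.5, -0.5, -0.5, 4.5, 9.5, 9.5, 9.5, 4.5))
  dm <- disc_metrics(sq)
  expect_equal(dm$disc_area, 100)
  expect_equal(dm$ovality_ratio, 10 / (10 * sqrt(2)), tolerance = 1e-9)
  ref <- feret_oracle(sq)
  expect_equal(dm$ovality_ratio, ref["min"] / ref["max"], tolerance = 1e-3,
               ignore_attr = TRUE)

  # 64-gon approximating a circle of radius 100
  circ <- circle_polygon(c(150, 150), 100)
  dmc <- disc_metrics(circ)
  expect_equal(dmc$ovality_ratio, 1, tolerance = 0.01)
  expect_equal(dmc$disc_area, pi * 100^2, tolerance = 0.01)

  # rotated ellipse: ovality equals the axis ratio
  for (rot in c(0, 17, 45, 121)) {
    dme <- disc_metrics(ellipse_polygon(c(300, 300), 200, 100, rot))
    expect_equal(dme$ovality_ratio, 0.5, tolerance = 0.01)
  }
})

test_that("ovality and area agree with brute-force oracles on random convex polygons", {
  set.seed(42)
  i <- 0
  while (i < 10) {
    # random convex polygon: hull of random points (needs >= 8 vertices)
    pts <- cbind(runif(60, 50, 450), runif(60, 50, 450))
    hull <- pts[grDevices::chull(pts), ]
    if (nrow(hull) < 8) next
    i <- i + 1
    dm <- disc_metrics(hull)
    ref <- feret_oracle(hull)
    expect_equal(dm$ovality_ratio, ref[["min"]] / ref[["max"]],
                 tolerance = 1e-4)
    # area oracle: independent half-plane test (valid for convex
    # polygons), counting strictly interior pixel centers
    xs <- seq(ceiling(min(hull[, 1])), floor(max(hull[, 1])))
    ys <- seq(ceiling(min(hull[, 2])), floor(max(hull[, 2])))
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    inside <- rep(TRUE, length(px))
    nh <- nrow(hull)
    for (k in seq_len(nh)) {
      a <- hull[k, ]; b <- hull[if (k == nh) 1 else k + 1, ]
      s <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      inside <- inside & (s > 0)   # chull() returns clockwise in y-down terms
    }
    if (sum(inside) == 0) {
      inside <- rep(TRUE, length(px))
      for (k in seq_len(nh)) {
        a <- hull[k, ]; b <- hull[if (k == nh) 1 else k + 1, ]
        s <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
        inside <- inside & (s < 0)
      }
    }
    expect_equal(dm$disc_area, sum(inside))
  }
})

test_that("self-intersecting disc boundaries are rejected", {
  bowtie <- cbind(c(0, 10, 0, 10, 5, 2, 8, 4),
                  c(0, 10, 10, 0, 5, 3, 7, 2))
  expect_error(disc_metrics(bowtie), "self-intersecting")
  expect_error(disc_metrics(circle_polygon(c(0, 0), 10, n = 6)), "n >= 8")
})
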