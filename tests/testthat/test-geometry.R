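test_that("projection onto the measurement circle is radial and exact", {
  # already on the circle: identity
  p <- project_to_circle(c(260, 0), c(0, 0), 260)
  expect_equal(as.numeric(p), c(260, 0))
  expect_equal(attr(p, "displacement"), 0)

  # radial scaling toward the center
  expect_equal(as.numeric(project_to_circle(c(520, 0), c(0, 0), 260)),
               c(260, 0))

  # property: projected points sit on the circle to 1e-9
  set.seed(11)
  for (i in 1:50) {
    center <- runif(2, -100, 100)
    pt <- center + runif(2, -400, 400)
    if (all(pt == center)) next
    pr <- project_to_circle(pt, center, 260)
    expect_equal(sqrt(sum((pr - center)^2)), 260, tolerance = 1e-9)
  }

  expect_error(project_to_circle(c(5, 5), c(5, 5), 260), "center")
  expect_warning(project_to_circle(c(520, 0), c(0, 0), 260, tolerance = 5),
                 "off the measurement circle")
})

test_that("vessel angles are measured from the temporal horizontal ray", {
  lm <- make_landmarks(st_ra = 45, it_ra = 30, st_rv = 50, it_rv = 40)
  va <- vessel_angles(lm)
  expect_equal(va$ST_RA, 45)
  expect_equal(va$IT_RA, 30)
  expect_equal(va$T_RA, va$ST_RA + va$IT_RA)
  expect_equal(va$T_RV, va$ST_RV + va$IT_RV)

  # crossing exactly on the temporal ray: zero angle
  lm0 <- make_landmarks(st_ra = 45, it_ra = 30)
  lm0$crossings$st_vein <- c(760, 500)
  expect_equal(vessel_angles(lm0)$ST_RV, 0)

  # nasal-half crossings are allowed (angle past 90 degrees)
  lmn <- make_landmarks(st_ra = 135)
  expect_equal(vessel_angles(lmn)$ST_RA, 135)
})

test_that("crossing-to-fovea distances and angles match hand trigonometry", {
  lm <- make_landmarks(disc = c(500, 500), fovea = c(800, 500))
  lm$crossings$st_artery <- c(500, 240)   # straight above the disc center
  fv <- fovea_vessel_metrics(lm)
  expect_equal(fv$STAFD, sqrt(300^2 + 260^2), tolerance = 1e-9)
  expect_equal(fv$STAFA, atan2(260, 300) * 180 / pi, tolerance = 1e-9)

  # crossing on the fovea-disc segment (and on the circle): collinear
  lm$crossings$it_artery <- c(760, 500)
  expect_equal(fovea_vessel_metrics(lm)$ITAFA, 0)

  # crossing coincident with the fovea is rejected
  lmf <- make_landmarks(fovea = c(760, 500))
  lmf$crossings$st_artery <- c(760, 500)
  expect_error(fovea_vessel_metrics(lmf), "fovea")
})

test_that("papillomacular distance and angle follow the disc-fovea line", {
  lm <- make_landmarks(disc = c(500, 500), fovea = c(800, 500))
  pm <- papillomacular_metrics(lm)
  expect_equal(pm$PMD, 300)
  expect_equal(pm$PMA, 0)

  lm2 <- make_landmarks(disc = c(500, 500), fovea = c(800, 530))
  pm2 <- papillomacular_metrics(lm2)
  expect_equal(pm2$PMD, sqrt(300^2 + 30^2), tolerance = 1e-9)
  expect_equal(pm2$PMA, atan2(30, 300) * 180 / pi, tolerance = 1e-9)

  # symmetric in the two endpoints
  lm3 <- make_landmarks(disc = c(800, 530), fovea = c(500, 500))
  expect_equal(papillomacular_metrics(lm3), pm2)
})

test_that("peripapillary circle centers step 45 degrees from the temporal ray", {
  lm <- make_landmarks(disc = c(500, 500), fovea = c(800, 500))
  cc <- peripapillary_centers(lm)
  expect_equal(cc$roi, c("T", "ST", "S", "SN", "N", "IN", "I", "IT"))

  # temporal center on the disc-to-fovea ray, at the ring distance
  expect_equal(c(cc$x[1], cc$y[1]), c(880, 500))

  # the first step goes superior (smaller y)
  expect_lt(cc$y[2], cc$y[1])

  # consecutive centers subtend 45 degrees at the disc center
  for (i in 1:7) {
    u <- c(cc$x[i] - 500, cc$y[i] - 500)
    v <- c(cc$x[i + 1] - 500, cc$y[i + 1] - 500)
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(ang, 45, tolerance = 1e-9)
  }

  # nasal center is the reflection of the temporal center through the disc
  expect_equal(c(cc$x[5], cc$y[5]), c(2 * 500 - cc$x[1], 2 * 500 - cc$y[1]),
               tolerance = 1e-9)

  # and the geometry respects a left-eye (fovea at -x) layout too
  lmL <- make_landmarks(disc = c(500, 500), fovea = c(200, 500))
  ccL <- peripapillary_centers(lmL)
  expect_equal(c(ccL$x[1], ccL$y[1]), c(120, 500))
  expect_lt(ccL$y[2], ccL$y[1])

  # circles extending outside a given raster are rejected
  expect_error(peripapillary_centers(lm, image_size = c(600, 600)),
               "outside the image")
})
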