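# the canonical header is frozen: any change to names or order is a
# breaking change for every stored feature CSV
test_that("the 54 canonical feature names are frozen in order", {
  expected <- c(
    "T_RA", "ST_RA", "IT_RA", "T_RV", "ST_RV", "IT_RV",
    "STAFD", "ITAFD", "STVFD", "ITVFD", "PMD",
    "STAFA", "ITAFA", "STVFA", "ITVFA", "PMA",
    "disc_area", "ovality_ratio",
    "T_R", "T_G", "T_B", "T_TFI",
    "ST_R", "ST_G", "ST_B", "ST_TFI",
    "S_R", "S_G", "S_B", "S_TFI",
    "SN_R", "SN_G", "SN_B", "SN_TFI",
    "N_R", "N_G", "N_B", "N_TFI",
    "IN_R", "IN_G", "IN_B", "IN_TFI",
    "I_R", "I_G", "I_B", "I_TFI",
    "IT_R", "IT_G", "IT_B", "IT_TFI",
    "F_R", "F_G", "F_B", "F_TFI"
  )
  expect_identical(fundus_feature_names(), expected)
})

make_extractable_eye <- function(seed = 5) {
  cfg <- default_sim_config(10.5, seed = seed)
  render_fundus_image(sample_eye_parameters(cfg, "male", seed = seed))
}

test_that("extract_features emits exactly the 54 named parameters", {
  eye <- make_extractable_eye()
  feats <- extract_features(eye$image, eye$landmarks)
  expect_identical(names(feats), fundus_feature_names())
  expect_equal(ncol(feats), 54)
  expect_true(all(vapply(feats, is.numeric, logical(1))))
  # definitional identities hold exactly
  expect_identical(feats$T_RA, feats$ST_RA + feats$IT_RA)
  expect_identical(feats$T_RV, feats$ST_RV + feats$IT_RV)
  # range invariants
  expect_true(feats$ovality_ratio > 0 && feats$ovality_ratio <= 1)
  tfis <- unlist(feats[paste0(roi_labels(), "_TFI")])
  expect_true(all(tfis > 0 & tfis < 1))
})

test_that("features are invariant to integer translation of image and landmarks", {
  eye <- make_extractable_eye(seed = 9)
  base <- extract_features(eye$image, eye$landmarks)
  dx <- 7; dy <- 11
  shifted <- extract_features(
    translate_image(eye$image, dx, dy),
    translate_landmarks(eye$landmarks, dx, dy)
  )
  # colors and area are exact; angles and distances to 1e-9
  exact <- c("disc_area", as.vector(outer(roi_labels(),
                                          c("R", "G", "B", "TFI"),
                                          paste, sep = "_")))
  expect_identical(shifted[exact], base[exact])
  for (col in setdiff(names(base), exact)) {
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("features are invariant under a horizontal mirror (laterality flip)", {
  eye <- make_extractable_eye(seed = 13)
  base <- extract_features(eye$image, eye$landmarks)
  mirrored <- extract_features(
    mirror_image(eye$image),
    mirror_landmarks(eye$landmarks, eye$image$width)
  )
  expect_equal(as.list(mirrored), as.list(base), tolerance = 1e-9)
})

test_that("component failures name the failing parameter group", {
  eye <- make_extractable_eye(seed = 17)
  lm_bad <- eye$landmarks
  lm_bad$crossings$st_artery <- eye$landmarks$disc_center
  expect_error(extract_features(eye$image, lm_bad), "vessel angles")

  # a raster too small for the peripapillary ring is reported as such
  small <- uniform_image(300, 300)
  lm <- make_landmarks(disc = c(150, 150), fovea = c(280, 150))
  expect_error(extract_features(small, lm), "peripapillary")
})
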