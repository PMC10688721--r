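test_that("feature tables are seed-deterministic with the canonical 54 columns", {
  cfg <- default_sim_config(10.5, n_female = 8, n_male = 7, seed = 21)
  t1 <- generate_feature_table(cfg)
  t2 <- generate_feature_table(cfg)
  expect_identical(t1, t2)
  expect_identical(names(t1), c("id", "sex", fundus_feature_names()))
  expect_equal(nrow(t1), 15)
  expect_equal(sum(t1$sex == "female"), 8)

  # a different seed produces different draws
  cfg2 <- default_sim_config(10.5, n_female = 8, n_male = 7, seed = 22)
  expect_false(identical(generate_feature_table(cfg2)$T_RA, t1$T_RA))
})

test_that("invalid simulation configurations are rejected with diagnostics", {
  m <- baseline <- default_sim_config(8.5)
  expect_error(default_sim_config(8.5, n_female = 1), "at least 2")

  bad_corr <- diag(54)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 1.5   # breaks positive semidefiniteness
  expect_error(
    sim_config(5, 5, baseline$feature_means_f, baseline$feature_means_m,
               baseline$feature_sds, correlation = bad_corr),
    "positive semidefinite"
  )
  asym <- diag(54); asym[1, 2] <- 0.3
  expect_error(
    sim_config(5, 5, baseline$feature_means_f, baseline$feature_means_m,
               baseline$feature_sds, correlation = asym),
    "symmetric"
  )
  sds <- baseline$feature_sds; sds[3] <- 0
  expect_error(
    sim_config(5, 5, baseline$feature_means_f, baseline$feature_means_m, sds),
    "positive"
  )
})

test_that("an injected correlation structure survives into the draws", {
  corr <- diag(54)
  corr[1, 2] <- corr[2, 1] <- 0.9
  base <- default_sim_config(NULL, n_female = 400, n_male = 400, seed = 3)
  cfg <- sim_config(400, 400, base$feature_means_f, base$feature_means_m,
                    base$feature_sds, correlation = corr, seed = 3)
  tab <- generate_feature_table(cfg)
  expect_equal(cor(tab$T_RA, tab$ST_RA), 0.9, tolerance = 0.05)
  expect_lt(abs(cor(tab$T_RA, tab$PMD)), 0.15)
})

test_that("eye render parameters are seed-deterministic and honor forced ovality", {
  cfg <- default_sim_config(11.5)
  p1 <- sample_eye_parameters(cfg, "female", seed = 31)
  p2 <- sample_eye_parameters(cfg, "female", seed = 31)
  expect_identical(p1, p2)

  # ovality mean 1 with vanishing SD forces equal disc semi-axes
  forced <- cfg
  forced$feature_means_f["ovality_ratio"] <- 1
  forced$feature_sds["ovality_ratio"] <- 1e-9
  pc <- sample_eye_parameters(forced, "female", seed = 31)
  expect_equal(pc$disc_semi_major, pc$disc_semi_minor, tolerance = 1e-6)
})

test_that("rendered eyes are deterministic and carry exact crossings on the circle", {
  cfg <- default_sim_config(11.5)
  p <- sample_eye_parameters(cfg, "male", seed = 41)
  e1 <- render_fundus_image(p)
  e2 <- render_fundus_image(p)
  expect_identical(e1$image, e2$image)
  expect_identical(e1$landmarks, e2$landmarks)

  r <- p$vessel_circle_diameter / 2
  for (cr in e1$landmarks$crossings) {
    expect_equal(sqrt(sum((cr - e1$landmarks$disc_center)^2)), r,
                 tolerance = 1e-9)
  }

  # an arc too tight to reach the measurement circle is rejected
  v <- p$vessels
  v$st_artery$arc_radius <- 50
  expect_error(
    eye_render_params(vessels = v),
    "too tight"
  )
})

test_that("a configured sex effect on TFI appears in the rendered background", {
  # controlled experiment: +0.05 TFI for females, tiny draw noise so a
  # modest number of renders pins the mean difference
  base <- default_sim_config(NULL)
  base$feature_means_f["T_TFI"] <- base$feature_means_m["T_TFI"] + 0.05
  base$feature_sds["T_TFI"] <- 0.005
  tfi_of <- function(sex, seed) {
    eye <- render_fundus_image(sample_eye_parameters(base, sex, seed))
    extract_features(eye$image, eye$landmarks)$N_TFI
  }
  f <- vapply(1:8, function(i) tfi_of("female", 100 + i), numeric(1))
  m <- vapply(1:8, function(i) tfi_of("male", 200 + i), numeric(1))
  expect_lt(abs((mean(f) - mean(m)) - 0.05), 0.012)
})
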