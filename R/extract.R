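#' Extract the 54 fundus parameters from a raster and its landmarks
#'
#' Assembles the full measurement protocol: the six vessel angles at the
#' vessel measurement circle, the four crossing-to-fovea distances and
#' angles, the papillomacular distance and angle, the optic disc area and
#' ovality ratio, and the mean R/G/B intensities plus tessellation fundus
#' index in the eight peripapillary circles and the foveal circle. All 54
#' values follow deterministically from the landmark set; the raster is
#' consulted only for the 36 color parameters.
#'
#' @param img A [fundus_image()].
#' @param lm A [landmark_set()].
#' @param cfg A [measurement_config()].
#' @return One-row tibble with the 54 columns of
#'   [fundus_feature_names()], in canonical order.
#' @export
extract_features <- function(img, lm, cfg = measurement_config()) {
  stopifnot(inherits(img, "fundus_image"), inherits(lm, "landmark_set"))

  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("while measuring %s: %s", label, conditionMessage(e)),
           call. = FALSE)
    })
  }

  va <- step("vessel angles", vessel_angles(lm, cfg))
  fv <- step("crossing-fovea metrics", fovea_vessel_metrics(lm, cfg))
  pm <- step("papillomacular metrics", papillomacular_metrics(lm))
  dm <- step("disc metrics", disc_metrics(lm$disc_boundary))

  centers <- step(
    "peripapillary circle placement",
    peripapillary_centers(lm, cfg, image_size = c(img$width, img$height))
  )
  centers <- dplyr::bind_rows(
    centers,
    tibble::tibble(roi = "F", x = lm$fovea[1], y = lm$fovea[2])
  )
  diam <- c(rep(cfg$peripapillary_circle_diameter, 8),
            cfg$foveal_circle_diameter)
  color <- purrr::map2(seq_len(9), centers$roi, function(i, roi) {
    stats <- step(
      paste0("color circle ", roi),
      roi_color_stats(img, c(centers$x[i], centers$y[i]), diam[i])
    )
    rlang::set_names(stats, paste(roi, names(stats), sep = "_"))
  })

  out <- dplyr::bind_cols(
    va[, c("T_RA", "ST_RA", "IT_RA", "T_RV", "ST_RV", "IT_RV")],
    fv[, c("STAFD", "ITAFD", "STVFD", "ITVFD")],
    pm[, "PMD", drop = FALSE],
    fv[, c("STAFA", "ITAFA", "STVFA", "ITVFA")],
    pm[, "PMA", drop = FALSE],
    dm,
    color
  )
  out[, fundus_feature_names()]
}

#' Extract features for several eyes into one table
#'
#' @param eyes A data frame (or tibble) with one row per eye and columns
#'   `id`, `image` (paths to PNG rasters) and `landmarks` (paths to
#'   landmark JSON files).
#' @param cfg A [measurement_config()].
#' @return Tibble with `id` plus the 54 feature columns.
#' @export
extract_features_batch <- function(eyes, cfg = measurement_config()) {
  stopifnot(all(c("id", "image", "landmarks") %in% names(eyes)))
  purrr::pmap_dfr(
    eyes[, c("id", "image", "landmarks")],
    function(id, image, landmarks) {
      dplyr::bind_cols(
        tibble::tibble(id = id),
        extract_features(read_fundus_png(image), read_landmarks(landmarks), cfg)
      )
    }
  )
}
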