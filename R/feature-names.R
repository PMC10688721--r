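#' Canonical names of the 54 fundus parameters
#'
#' The measurement protocol produces exactly 54 parameters per eye, in a
#' fixed order: 18 geometric parameters followed by 36 color parameters.
#'
#' Geometric (18): the six retinal vessel angles measured from the temporal
#' horizontal ray at the vessel measurement circle (`T_RA`, `ST_RA`,
#' `IT_RA` for arteries, `T_RV`, `ST_RV`, `IT_RV` for veins, degrees); the
#' four crossing-to-fovea distances (`STAFD`, `ITAFD`, `STVFD`, `ITVFD`,
#' pixels) and the corresponding angles at the fovea against the
#' fovea-disc line (`STAFA`, `ITAFA`, `STVFA`, `ITVFA`, degrees); the
#' papillomacular distance `PMD` (pixels) and angle `PMA` (degrees); the
#' optic disc area `disc_area` (pixels squared) and `ovality_ratio`
#' (minimum/maximum Feret diameter of the disc boundary, dimensionless).
#'
#' Color (36): for each of the nine circular regions of interest --- the
#' eight peripapillary locations `T`, `ST`, `S`, `SN`, `N`, `IN`, `I`,
#' `IT` (temporal, supratemporal, superior, supranasal, nasal, infranasal,
#' inferior, infratemporal) plus the foveal region `F` --- the mean red,
#' green and blue intensities (`<roi>_R`, `<roi>_G`, `<roi>_B`, 0-255)
#' and the tessellation fundus index `<roi>_TFI = R / (R + G + B)`
#' computed from those three means.
#'
#' @return Character vector of length 54, the canonical column order of
#'   every feature table produced or consumed by this package.
#' @export
#' @examples
#' length(fundus_feature_names())
fundus_feature_names <- function() {
  geometric <- c(
    "T_RA", "ST_RA", "IT_RA", "T_RV", "ST_RV", "IT_RV",
    "STAFD", "ITAFD", "STVFD", "ITVFD", "PMD",
    "STAFA", "ITAFA", "STVFA", "ITVFA", "PMA",
    "disc_area", "ovality_ratio"
  )
  color <- as.vector(vapply(
    roi_labels(),
    function(roi) paste(roi, c("R", "G", "B", "TFI"), sep = "_"),
    character(4)
  ))
  c(geometric, color)
}

#' Labels of the nine color regions of interest
#'
#' Eight peripapillary locations in compass order starting temporally and
#' sweeping through superior, plus the foveal region.
#'
#' @return Character vector of length 9.
#' @export
roi_labels <- function() {
  c("T", "ST", "S", "SN", "N", "IN", "I", "IT", "F")
}

#' Measurement configuration
#'
#' Geometric constants of the measurement protocol. All circle sizes are
#' diameters in pixels: the vessel measurement circle centered on the
#' optic disc (default 520 px), the eight peripapillary color circles
#' (default 240 px) and the foveal color circle (default 80 px). The
#' peripapillary circle centers sit at `ring_center_distance` pixels from
#' the disc center (default 380 px, which places each 120-px-radius circle
#' tangent to the 260-px-radius vessel circle). Landmarked vessel
#' crossings are radially snapped onto the vessel circle; a displacement
#' larger than `crossing_tolerance` pixels raises a warning.
#'
#' @param vessel_circle_diameter Diameter (px) of the vessel measurement
#'   circle centered on the optic disc.
#' @param peripapillary_circle_diameter Diameter (px) of each of the eight
#'   peripapillary color circles.
#' @param foveal_circle_diameter Diameter (px) of the foveal color circle.
#' @param ring_center_distance Distance (px) from the disc center to each
#'   peripapillary circle center.
#' @param crossing_tolerance Radial displacement (px) beyond which
#'   snapping a clicked crossing onto the vessel circle warns.
#' @return A list of class `measurement_config`.
#' @export
#' @examples
#' measurement_config()
measurement_config <- function(vessel_circle_diameter = 520,
                               peripapillary_circle_diameter = 240,
                               foveal_circle_diameter = 80,
                               ring_center_distance = 380,
                               crossing_tolerance = 5) {
  cfg <- list(
    vessel_circle_diameter = vessel_circle_diameter,
    peripapillary_circle_diameter = peripapillary_circle_diameter,
    foveal_circle_diameter = foveal_circle_diameter,
    ring_center_distance = ring_center_distance,
    crossing_tolerance = crossing_tolerance
  )
  sizes <- unlist(cfg)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all measurement_config values must be positive and finite",
         call. = FALSE)
  }
  if (ring_center_distance <= peripapillary_circle_diameter / 2) {
    stop("ring_center_distance must exceed the peripapillary circle radius",
         call. = FALSE)
  }
  structure(cfg, class = "measurement_config")
}

#' @export
print.measurement_config <- function(x, ...) {
  cat("Fundus measurement configuration (px):\n")
  cat(sprintf("  vessel circle diameter:        %g\n", x$vessel_circle_diameter))
  cat(sprintf("  peripapillary circle diameter: %g\n", x$peripapillary_circle_diameter))
  cat(sprintf("  foveal circle diameter:        %g\n", x$foveal_circle_diameter))
  cat(sprintf("  ring center distance:          %g\n", x$ring_center_distance))
  cat(sprintf("  crossing snap tolerance:       %g\n", x$crossing_tolerance))
  invisible(x)
}
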