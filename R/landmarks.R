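#' Per-eye landmark set
#'
#' The measurement protocol is landmark-driven: once the disc center, the
#' fovea, the disc boundary and the four vessel-circle crossing points are
#' located, all 54 parameters follow deterministically. Points are
#' continuous pixel coordinates in the raster convention of
#' [fundus_image()] (0-based, x rightward, y downward).
#'
#' @param disc_center,fovea Numeric `c(x, y)` points; must differ.
#' @param disc_boundary Numeric n x 2 matrix (columns x, y), a simple
#'   closed polygon with at least 8 vertices tracing the optic disc rim.
#' @param crossings Named list with points `st_artery`, `it_artery`,
#'   `st_vein`, `it_vein`: where the major supratemporal / infratemporal
#'   retinal artery and vein cross the vessel measurement circle.
#' @param laterality `"right"` or `"left"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(disc_center, fovea, disc_boundary, crossings,
                         laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  disc_center <- as.numeric(disc_center)
  fovea <- as.numeric(fovea)
  if (length(disc_center) != 2 || length(fovea) != 2) {
    stop("disc_center and fovea must be length-2 (x, y) points", call. = FALSE)
  }
  if (all(disc_center == fovea)) {
    stop("fovea must not coincide with the disc center", call. = FALSE)
  }
  disc_boundary <- as.matrix(disc_boundary)
  if (ncol(disc_boundary) != 2 || nrow(disc_boundary) < 8) {
    stop("disc_boundary must be an n x 2 matrix with n >= 8", call. = FALSE)
  }
  need <- c("st_artery", "it_artery", "st_vein", "it_vein")
  if (!all(need %in% names(crossings))) {
    stop("crossings must name st_artery, it_artery, st_vein, it_vein",
         call. = FALSE)
  }
  crossings <- lapply(crossings[need], as.numeric)
  if (any(vapply(crossings, length, 1L) != 2)) {
    stop("each crossing must be a length-2 (x, y) point", call. = FALSE)
  }
  structure(
    list(disc_center = disc_center, fovea = fovea,
         disc_boundary = disc_boundary, crossings = crossings,
         laterality = laterality),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "landmark_set (%s eye): disc (%.1f, %.1f), fovea (%.1f, %.1f), %d boundary vertices\n",
    x$laterality, x$disc_center[1], x$disc_center[2],
    x$fovea[1], x$fovea[2], nrow(x$disc_boundary)
  ))
  invisible(x)
}

#' Read / write landmarks as JSON
#'
#' The on-disk layout is a JSON object with `disc_center` and `fovea` as
#' `[x, y]`, `disc_boundary` as `[[x, y], ...]`, a `crossings` object with
#' the four named points, and `laterality`.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a [landmark_set()];
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(
    disc_center = j$disc_center,
    fovea = j$fovea,
    disc_boundary = j$disc_boundary,
    crossings = as.list(j$crossings),
    laterality = j$laterality
  )
}

#' @param lm A [landmark_set()].
#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(
    list(
      disc_center = lm$disc_center,
      fovea = lm$fovea,
      disc_boundary = lm$disc_boundary,
      crossings = lm$crossings,
      laterality = lm$laterality
    ),
    path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' Translate landmarks by a pixel offset
#'
#' @param lm A [landmark_set()].
#' @param dx,dy Offsets (px).
#' @return A [landmark_set()].
#' @export
translate_landmarks <- function(lm, dx, dy) {
  stopifnot(inherits(lm, "landmark_set"))
  off <- c(dx, dy)
  landmark_set(
    lm$disc_center + off, lm$fovea + off,
    sweep(lm$disc_boundary, 2, off, "+"),
    lapply(lm$crossings, function(p) p + off),
    lm$laterality
  )
}

#' Mirror landmarks horizontally
#'
#' Reflects x through the vertical midline of a raster of the given
#' width (x becomes `width - 1 - x`) and flips the laterality flag; the
#' superior/inferior identity of each crossing is unchanged because y is
#' untouched.
#'
#' @param lm A [landmark_set()].
#' @param width Raster width in pixels.
#' @return A [landmark_set()].
#' @export
mirror_landmarks <- function(lm, width) {
  stopifnot(inherits(lm, "landmark_set"))
  mx <- function(p) c(width - 1 - p[1], p[2])
  bd <- lm$disc_boundary
  bd[, 1] <- width - 1 - bd[, 1]
  landmark_set(
    mx(lm$disc_center), mx(lm$fovea), bd,
    lapply(lm$crossings, mx),
    if (lm$laterality == "right") "left" else "right"
  )
}
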