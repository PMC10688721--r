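#' Mean color and tessellation fundus index of a circular region
#'
#' Averages the red, green and blue channels over all pixels whose
#' centers lie within `diameter / 2` of `center`, then computes the
#' tessellation fundus index `TFI = R / (R + G + B)` from the three
#' means. No vessel masking is applied. The circle must lie fully inside
#' the raster.
#'
#' @param img A [fundus_image()].
#' @param center Numeric `c(x, y)` circle center (px, continuous).
#' @param diameter Circle diameter (px).
#' @return One-row tibble with columns `R`, `G`, `B` (mean intensities,
#'   0-255) and `TFI` (fraction).
#' @export
#' @examples
#' roi_color_stats(uniform_image(50, 50, c(150, 75, 75)), c(25, 25), 30)
roi_color_stats <- function(img, center, diameter) {
  stopifnot(inherits(img, "fundus_image"), diameter > 0)
  cx <- center[1]; cy <- center[2]
  r <- diameter / 2
  if (cx - r < 0 || cx + r > img$width - 1 ||
      cy - r < 0 || cy + r > img$height - 1) {
    stop(sprintf(
      "color circle at (%.1f, %.1f), diameter %.0f px, is clipped by the %d x %d image",
      cx, cy, diameter, img$width, img$height
    ), call. = FALSE)
  }
  xs <- seq(ceiling(cx - r), floor(cx + r))   # 0-based pixel centers
  ys <- seq(ceiling(cy - r), floor(cy + r))
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  keep <- outer(dy2, dx2, "+") <= r^2         # rows = y, cols = x
  ri <- img$r[ys + 1, xs + 1, drop = FALSE][keep]
  gi <- img$g[ys + 1, xs + 1, drop = FALSE][keep]
  bi <- img$b[ys + 1, xs + 1, drop = FALSE][keep]
  mr <- mean(ri); mg <- mean(gi); mb <- mean(bi)
  tibble::tibble(R = mr, G = mg, B = mb, TFI = mr / (mr + mg + mb))
}
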