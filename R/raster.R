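#' Three-channel fundus raster
#'
#' An 8-bit RGB raster with an explicit pixel-coordinate convention:
#' origin at the top-left pixel, x rightward, y downward, 0-based, with
#' pixel centers at integer coordinates. The pixel in matrix row `i`,
#' column `j` (1-based R indexing) has center `(x, y) = (j - 1, i - 1)`.
#'
#' @param r,g,b Numeric matrices of equal dimension with intensities in
#'   0-255 (rows = y, columns = x).
#' @return An object of class `fundus_image`: a list with elements `r`,
#'   `g`, `b`, `width`, `height`.
#' @export
fundus_image <- function(r, g, b) {
  if (!is.matrix(r) || !is.matrix(g) || !is.matrix(b)) {
    stop("channels must be matrices", call. = FALSE)
  }
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b))) {
    stop("all three channels must have identical dimensions", call. = FALSE)
  }
  rng <- range(r, g, b)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(r = r, g = g, b = b, width = ncol(r), height = nrow(r)),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("fundus_image: %d x %d px, 3 x 8-bit channels\n",
              x$width, x$height))
  invisible(x)
}

#' Uniform-color raster
#'
#' @param width,height Dimensions in pixels.
#' @param rgb Length-3 vector of channel intensities (0-255).
#' @return A [fundus_image()].
#' @export
uniform_image <- function(width, height, rgb = c(120, 120, 120)) {
  fundus_image(
    matrix(rgb[1], height, width),
    matrix(rgb[2], height, width),
    matrix(rgb[3], height, width)
  )
}

#' Read / write a fundus raster as PNG
#'
#' `read_fundus_png()` loads an 8-bit RGB (or RGBA, alpha dropped; or
#' greyscale, replicated) PNG; `write_fundus_png()` stores one. Channel
#' values are rescaled between the PNG 0-1 convention and this package's
#' 0-255 convention; writing rounds to the nearest 8-bit level.
#'
#' @param path File path.
#' @return `read_fundus_png()` returns a [fundus_image()];
#'   `write_fundus_png()` returns `path` invisibly.
#' @export
read_fundus_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) {
    m <- round(a * 255)
    return(fundus_image(m, m, m))
  }
  fundus_image(
    round(a[, , 1] * 255),
    round(a[, , 2] * 255),
    round(a[, , 3] * 255)
  )
}

#' @param img A [fundus_image()].
#' @rdname read_fundus_png
#' @export
write_fundus_png <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  a <- array(0, c(img$height, img$width, 3))
  a[, , 1] <- round(img$r) / 255
  a[, , 2] <- round(img$g) / 255
  a[, , 3] <- round(img$b) / 255
  png::writePNG(a, path)
  invisible(path)
}

#' Translate a raster by an integer pixel offset
#'
#' Used for invariance checks: the content is shifted by `(dx, dy)` on a
#' larger canvas padded with `fill`.
#'
#' @param img A [fundus_image()].
#' @param dx,dy Non-negative integer offsets (px).
#' @param fill Length-3 RGB fill for the padding.
#' @return A [fundus_image()] of size `(width + dx) x (height + dy)`.
#' @export
translate_image <- function(img, dx, dy, fill = c(0, 0, 0)) {
  stopifnot(inherits(img, "fundus_image"), dx >= 0, dy >= 0,
            dx == round(dx), dy == round(dy))
  shift1 <- function(m, f) {
    out <- matrix(f, img$height + dy, img$width + dx)
    out[(dy + 1):(dy + img$height), (dx + 1):(dx + img$width)] <- m
    out
  }
  fundus_image(shift1(img$r, fill[1]), shift1(img$g, fill[2]),
               shift1(img$b, fill[3]))
}

#' Mirror a raster horizontally
#'
#' Flips x so the pixel at x becomes the pixel at `width - 1 - x`; used
#' for the laterality-flip invariance check together with
#' [mirror_landmarks()].
#'
#' @param img A [fundus_image()].
#' @return A [fundus_image()].
#' @export
mirror_image <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  flip <- function(m) m[, ncol(m):1, drop = FALSE]
  fundus_image(flip(img$r), flip(img$g), flip(img$b))
}
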