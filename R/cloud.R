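#' CIELAB point cloud
#'
#' A set of (L*, a*, b*) triplets, usually one per pixel of a square image
#' region. The a* and b* channels are clamped to \[-128, 127\] when the
#' cloud is derived from an image, mirroring the common 8-bit Lab
#' convention.
#'
#' @param points numeric matrix (or data frame) with columns L, a, b.
#' @param source optional provenance list (image id, row/col offset, size).
#' @param clamp clamp a and b to \[-128, 127\] (default FALSE for raw
#'   numeric clouds).
#' @return Object of class `lab_cloud`: a numeric matrix with columns
#'   `L`, `a`, `b` and a `source` attribute.
#' @export
lab_cloud <- function(points, source = NULL, clamp = FALSE) {
  m <- as.matrix(points)
  if (ncol(m) != 3) stop("points must have 3 columns (L, a, b)")
  if (nrow(m) == 0) stop("empty point cloud")
  if (any(!is.finite(m))) stop("points must be finite")
  colnames(m) <- c("L", "a", "b")
  if (clamp) m[, c("a", "b")] <- pmin(pmax(m[, c("a", "b")], -128), 127)
  structure(m, source = source, class = c("lab_cloud", "matrix", "array"))
}

#' @export
print.lab_cloud <- function(x, ...) {
  mu <- colMeans(x)
  cat(sprintf("<lab_cloud> %d points, mean L*a*b* = (%.2f, %.2f, %.2f)\n",
              nrow(x), mu[1], mu[2], mu[3]))
  invisible(x)
}

#' @export
plot.lab_cloud <- function(x, ...) {
  graphics::plot(x[, "a"], x[, "b"], xlab = "a*", ylab = "b*",
                 pch = ".", asp = 1, ...)
  invisible(x)
}

# Read an RGB raster from a file path (PNG or TIFF) or pass through an
# H x W x 3 array in [0, 1].
as_rgb_array <- function(image) {
  if (is.character(image)) {
    ext <- tolower(tools::file_ext(image))
    image <- switch(ext,
      png = png::readPNG(image),
      tif = ,
      tiff = tiff::readTIFF(image),
      stop("unsupported image format: ", ext))
  }
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be an H x W x 3 RGB array or a PNG/TIFF path")
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1 + 1e-9) image <- image / 255
  image
}

#' Extract a CIELAB point cloud from an image region
#'
#' Converts every pixel of a square region of an sRGB image to CIELAB
#' (D65, 2-degree observer) and returns the points in row-major order with
#' a* and b* clamped to \[-128, 127\]. The protocol region is 81 x 81
#' pixels, i.e. 6561 points per cloud.
#'
#' @param image an H x W x 3 RGB array in \[0, 1\] (or \[0, 255\]), or a
#'   path to a PNG/TIFF file.
#' @param top_left integer `(row, col)` of the region's top-left pixel
#'   (1-based).
#' @param size region edge length in pixels (default 81).
#' @return A [lab_cloud()] with `size^2` points.
#' @export
extract_lab_cloud <- function(image, top_left = c(1, 1), size = 81) {
  img <- as_rgb_array(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- as.integer(top_left[1]); c0 <- as.integer(top_left[2])
  if (r0 < 1 || c0 < 1 || r0 + size - 1 > h || c0 + size - 1 > w)
    stop(sprintf("region [%d:%d, %d:%d] outside %d x %d image",
                 r0, r0 + size - 1, c0, c0 + size - 1, h, w))
  rows <- r0:(r0 + size - 1); cols <- c0:(c0 + size - 1)
  block <- img[rows, cols, , drop = FALSE]
  # row-major point order: transpose each channel before flattening
  rgbm <- cbind(as.vector(t(block[, , 1])),
                as.vector(t(block[, , 2])),
                as.vector(t(block[, , 3])))
  lab <- srgb_matrix_to_lab(rgbm)
  lab_cloud(lab, clamp = TRUE,
            source = list(top_left = c(r0, c0), size = size))
}
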