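#' Read and write grey-level images
#'
#' Images are plain numeric matrices with intensities in `[0, 255]`,
#' `nrow = height`, `ncol = width`; pixel `(x, y)` in the package's 0-based
#' continuous coordinates is stored at `img[y + 1, x + 1]`. PNG and TIFF
#' (8- or 16-bit) are supported; multi-channel files are collapsed to grey
#' by channel averaging.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_grey_image()`: a numeric matrix in `[0, 255]`.
#' @export
read_grey_image <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    rlang::abort("unsupported image format (use .png or .tif/.tiff)",
      class = "spineasm_error_format")
  }
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a * 255
}

#' @rdname read_grey_image
#' @param image Numeric matrix in `[0, 255]`.
#' @export
write_grey_image <- function(image, path) {
  a <- pmin(pmax(image / 255, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(a, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(a, path)
  } else {
    rlang::abort("unsupported image format (use .png or .tif/.tiff)",
      class = "spineasm_error_format")
  }
  invisible(path)
}

#' Bilinear grey-level sampling at subpixel positions
#'
#' Interpolates the image bilinearly at continuous positions `(x, y)`
#' (0-based, origin at the top-left pixel centre). Positions outside the
#' image are clamped to the border pixel (edge replication).
#'
#' @param image Numeric matrix.
#' @param x,y Numeric vectors of equal length.
#' @return Numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2 + (w == 1)); y0 <- pmin(floor(y), h - 2 + (h == 1))
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1
  v00 <- image[i00]
  v01 <- if (w > 1) image[i00 + h] else v00
  v10 <- if (h > 1) image[i00 + 1] else v00
  v11 <- if (w > 1 && h > 1) image[i00 + h + 1] else v00
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
    (1 - fx) * fy * v10 + fx * fy * v11
}

# Separable Gaussian smoothing with replicated borders (EBImage filter2
# handles the convolution; kernels are normalised outer products).
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k1 <- stats::dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  as.matrix(EBImage::filter2(image, kern, boundary = "replicate"))
}

# Sobel gradients; returns list(gx, gy) with x rightward, y downward.
sobel_gradients <- function(image) {
  # EBImage filter2 correlates row (y) x col (x) kernels on the matrix layout
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  sy <- t(sx)
  # filter2 convolves (kernel flipped), which negates the antisymmetric
  # Sobel response; negate back so gx/gy are true forward gradients
  list(
    gx = -as.matrix(EBImage::filter2(image, sx, boundary = "replicate")),
    gy = -as.matrix(EBImage::filter2(image, sy, boundary = "replicate"))
  )
}
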