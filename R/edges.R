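#' Canny edge detection
#'
#' Classic Canny pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression of the gradient magnitude along the (quantised) gradient
#' direction, double thresholding at two quantiles of the nonzero gradient
#' magnitude, and hysteresis: weak edge pixels are kept only when their
#' 8-connected edge component contains a strong pixel.
#'
#' @param image Numeric grey matrix in `[0, 255]`.
#' @param sigma Smoothing scale in pixels (default 1.5).
#' @param low_q,high_q Hysteresis thresholds as quantiles of the nonzero
#'   gradient magnitude (defaults 0.70 and 0.90).
#' @return A logical matrix marking edge pixels.
#' @export
canny_edges <- function(image, sigma = 1.5, low_q = 0.70, high_q = 0.90) {
  if (length(image) == 0 || all(image == image[1])) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  sm <- gaussian_smooth(image, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  h <- nrow(mag); w <- ncol(mag)
  # quantise gradient direction to 4 bins and compare with the two
  # neighbours across the edge
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0: horiz grad, 1: diag, 2: vert, 3: anti-diag
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nmax <- matrix(FALSE, h, w)
  # offsets (dr, dc) along the gradient for each direction bin
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (b in 0:3) {
    o <- offs[[b + 1]]
    keep <- mag >= shift(mag, o[1], o[2]) & mag >= shift(mag, -o[1], -o[2])
    nmax <- nmax | (bin == b & keep)
  }
  nz <- mag[mag > 1e-12]
  lo <- stats::quantile(nz, low_q, names = FALSE)
  hi <- stats::quantile(nz, high_q, names = FALSE)
  weak <- nmax & mag >= lo
  strong <- nmax & mag >= hi
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- EBImage::bwlabel(weak)
  keep_lab <- unique(lab[strong])
  keep_lab <- keep_lab[keep_lab > 0]
  matrix(lab %in% keep_lab, h, w)
}

#' Harris corner detection
#'
#' Computes the Harris response `det(M) - k * trace(M)^2` from the
#' Gaussian-windowed structure tensor of the Sobel gradients, keeps local
#' maxima above a relative threshold, and suppresses non-maximal responses
#' within a radius.
#'
#' @param image Numeric grey matrix in `[0, 255]`.
#' @param k Harris sensitivity (default 0.04).
#' @param sigma Structure-tensor window scale in pixels (default 2).
#' @param deriv_sigma Pre-smoothing for the gradients (default 1).
#' @param nms_radius Non-maximum suppression radius in pixels (default 3).
#' @param rel_threshold Keep responses at least this fraction of the maximum
#'   response (default 0.01).
#' @param refine Subpixel-refine each corner by the gradient-orthogonality
#'   condition (every window gradient is orthogonal to the offset from the
#'   corner point), which removes the inward localisation bias of the raw
#'   response peak; refined duplicates that converge to the same point are
#'   merged, keeping the strongest (default TRUE).
#' @param refine_radius Refinement window radius in pixels (default 4).
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates) and
#'   `response`, ordered by decreasing response.
#' @export
harris_corners <- function(image, k = 0.04, sigma = 2, deriv_sigma = 1,
                           nms_radius = 3, rel_threshold = 0.01,
                           refine = TRUE, refine_radius = 4) {
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), response = numeric(0))
  if (length(image) == 0 || all(image == image[1])) return(empty)
  g <- sobel_gradients(gaussian_smooth(image, deriv_sigma))
  Axx <- gaussian_smooth(g$gx * g$gx, sigma)
  Ayy <- gaussian_smooth(g$gy * g$gy, sigma)
  Axy <- gaussian_smooth(g$gx * g$gy, sigma)
  R <- (Axx * Ayy - Axy^2) - k * (Axx + Ayy)^2
  rmax <- max(R)
  if (rmax <= 0) return(empty)
  cand <- which(R >= rel_threshold * rmax)
  ord <- cand[order(R[cand], decreasing = TRUE)]
  h <- nrow(R)
  rows <- (ord - 1) %% h + 1
  cols <- (ord - 1) %/% h + 1
  keep <- logical(length(ord))
  taken_r <- numeric(0); taken_c <- numeric(0)
  for (i in seq_along(ord)) {
    if (length(taken_r) == 0 ||
        all((taken_r - rows[i])^2 + (taken_c - cols[i])^2 > nms_radius^2)) {
      keep[i] <- TRUE
      taken_r <- c(taken_r, rows[i])
      taken_c <- c(taken_c, cols[i])
    }
  }
  out <- tibble::tibble(
    x = cols[keep] - 1, y = rows[keep] - 1,
    response = R[ord[keep]]
  )
  if (refine && nrow(out) > 0) {
    for (i in seq_len(nrow(out))) {
      q <- refine_corner(g$gx, g$gy, c(out$x[i], out$y[i]), refine_radius)
      out$x[i] <- q[1]; out$y[i] <- q[2]
    }
    # refined duplicates collapse onto the same corner: merge within 2 px,
    # keeping the strongest response (rows are response-ordered)
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      if (i < nrow(out)) {
        j <- (i + 1):nrow(out)
        close <- (out$x[j] - out$x[i])^2 + (out$y[j] - out$y[i])^2 <= 4
        keep[j][close] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

# Gradient-orthogonality subpixel corner refinement: solve
#   sum_p w_p (grad I(p) grad I(p)^T) (q - p) = 0
# for q over a window around the current estimate, iterated a few times.
refine_corner <- function(gx, gy, q, radius = 4, iters = 5) {
  h <- nrow(gx); w <- ncol(gx)
  for (it in seq_len(iters)) {
    c0 <- max(0, round(q[1]) - radius); c1 <- min(w - 1, round(q[1]) + radius)
    r0 <- max(0, round(q[2]) - radius); r1 <- min(h - 1, round(q[2]) + radius)
    if (c1 <= c0 || r1 <= r0) break
    xs <- c0:c1; ys <- r0:r1
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    ix <- gx[ys + 1, xs + 1]; iy <- gy[ys + 1, xs + 1]
    wgt <- exp(-((px - q[1])^2 + (py - q[2])^2) / (2 * (radius / 1.5)^2))
    a11 <- sum(wgt * ix * ix); a12 <- sum(wgt * ix * iy); a22 <- sum(wgt * iy * iy)
    b1 <- sum(wgt * (ix * ix * px + ix * iy * py))
    b2 <- sum(wgt * (ix * iy * px + iy * iy * py))
    det <- a11 * a22 - a12^2
    if (abs(det) < 1e-12) break
    qn <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
    if (sqrt(sum((qn - q)^2)) > 2 * radius) break  # diverged; keep estimate
    moved <- sqrt(sum((qn - q)^2))
    q <- qn
    if (moved < 1e-3) break
  }
  q
}
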