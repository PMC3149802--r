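#' Specification of a synthetic spine image
#'
#' Describes a radiograph-like phantom: `N` bright convex quadrilateral
#' vertebral bodies stacked vertically on a dark background, vertebra height
#' `alpha` and intervertebral gap `beta = alpha / 4` (the 4:1 empirical
#' ratio, enforced by construction), each body perturbed by a two-mode
#' generative deformation (anisotropic width scaling and horizontal shear,
#' so a principal-component analysis of the resulting shapes has a known
#' two-dimensional answer), a small random spine tilt, Gaussian blur and
#' additive Gaussian noise.
#'
#' @param n_vertebrae Number of vertebral bodies (default 5, a C3-C7
#'   cervical column).
#' @param alpha Vertebra height in pixels (default 40).
#' @param width_ratio Body width as a multiple of `alpha` (default 1.25).
#' @param shape_sd Scale of the two deformation modes in generator standard
#'   deviations (default 1; 0 disables deformation).
#' @param corner_radius Corner rounding radius in pixels applied to the
#'   rendered body only; ground-truth landmarks stay on the sharp
#'   quadrilateral (default 0).
#' @param tilt_deg Maximum spine tilt; each image draws a tilt uniformly in
#'   `[-tilt_deg, tilt_deg]` degrees (default 2).
#' @param blur_sigma Gaussian blur scale in pixels (default 1).
#' @param noise_sd Additive Gaussian noise standard deviation in grey levels
#'   (default 3).
#' @param fg,bg Body and background intensities on the 0-255 grey scale
#'   (defaults 180 and 60, mimicking radiograph contrast).
#' @param L Landmarks per vertebra in the exported ground truth (default
#'   20).
#' @param margin Canvas margin around the spine in pixels (default 25).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_vertebrae = 5, alpha = 40, width_ratio = 1.25,
                           shape_sd = 1, corner_radius = 0, tilt_deg = 2,
                           blur_sigma = 1, noise_sd = 3, fg = 180, bg = 60,
                           L = 20, margin = 25) {
  stopifnot(n_vertebrae >= 1, alpha > 0, width_ratio > 0, shape_sd >= 0,
            corner_radius >= 0, blur_sigma >= 0, noise_sd >= 0, L >= 4,
            L %% 4 == 0, margin > 0)
  structure(
    list(n_vertebrae = as.integer(n_vertebrae), alpha = alpha,
         beta = alpha / 4, width_ratio = width_ratio, shape_sd = shape_sd,
         corner_radius = corner_radius, tilt_deg = tilt_deg,
         blur_sigma = blur_sigma, noise_sd = noise_sd, fg = fg, bg = bg,
         L = as.integer(L), margin = margin),
    class = "synthetic_spec"
  )
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic spine image with ground truth
#'
#' Renders the phantom described by a [synthetic_spec()] and returns the
#' image together with exact ground-truth landmarks (via
#' [default_marking()]), the 2N true anterior corners, and the two anchor
#' points (upper anterior corner of the first vertebra, lower anterior
#' corner of the last). All randomness flows from `seed`; the same seed
#' reproduces the image bit for bit.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list with `image` (grey matrix in `[0, 255]`), `shape`
#'   (ground-truth landmarks, all vertebrae), `corners` (tibble `vertebra`,
#'   `type`, `x`, `y` of the anterior corners), `anchor_top`,
#'   `anchor_bottom`, and `tilt_deg` (the drawn tilt).
#' @export
generate_spine <- function(spec, seed = 1) {
  with_local_seed(seed, {
    N <- spec$n_vertebrae
    a <- spec$alpha; b <- spec$beta
    wv <- spec$width_ratio * a
    width <- ceiling(wv + 2 * spec$margin)
    height <- ceiling(N * a + (N - 1) * b + 2 * spec$margin)
    x0 <- spec$margin
    tilt <- stats::runif(1, -spec$tilt_deg, spec$tilt_deg) * pi / 180
    cxc <- width / 2; cyc <- height / 2
    rot <- function(p) {
      dx <- p[, 1] - cxc; dy <- p[, 2] - cyc
      cbind(cxc + cos(tilt) * dx - sin(tilt) * dy,
            cyc + sin(tilt) * dx + cos(tilt) * dy)
    }
    corner_list <- vector("list", N)
    for (v in seq_len(N)) {
      yt <- spec$margin + (v - 1) * (a + b)
      # base quad, marking order: upper-anterior, lower-anterior,
      # lower-posterior, upper-posterior
      quad <- rbind(c(x0, yt), c(x0, yt + a), c(x0 + wv, yt + a), c(x0 + wv, yt))
      b1 <- stats::rnorm(1, 0, spec$shape_sd)
      b2 <- stats::rnorm(1, 0, spec$shape_sd)
      cx <- mean(quad[, 1]); cy <- mean(quad[, 2])
      # mode 1: anisotropic width scaling; mode 2: horizontal shear
      quad[, 1] <- cx + (quad[, 1] - cx) * (1 + 0.04 * b1)
      quad[, 1] <- quad[, 1] + 0.06 * b2 * (quad[, 2] - cy)
      corner_list[[v]] <- rot(quad)
    }
    if (any(vapply(corner_list, function(q) {
      any(q[, 1] < 1 | q[, 1] > width - 2 | q[, 2] < 1 | q[, 2] > height - 2)
    }, FALSE))) {
      rlang::abort("spine geometry exceeds the canvas; increase margin",
        class = "spineasm_error_parameter")
    }
    img <- matrix(spec$bg, height, width)
    for (v in seq_len(N)) {
      img <- render_convex_polygon(img, render_polygon_points(
        corner_list[[v]], spec$corner_radius), spec$fg)
    }
    if (spec$blur_sigma > 0) img <- gaussian_smooth(img, spec$blur_sigma)
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    }
    img <- pmin(pmax(img, 0), 255)
    shape <- dplyr::bind_rows(lapply(seq_len(N), function(v) {
      default_marking(corner_list[[v]], spec$L, vertebra = v)
    }))
    corners <- dplyr::bind_rows(lapply(seq_len(N), function(v) {
      q <- corner_list[[v]]
      tibble::tibble(vertebra = v, type = c("upper", "lower"),
                     x = q[1:2, 1], y = q[1:2, 2])
    }))
    list(
      image = img, shape = validate_shape(shape), corners = corners,
      anchor_top = as.numeric(corner_list[[1]][1, ]),
      anchor_bottom = as.numeric(corner_list[[N]][2, ]),
      tilt_deg = tilt * 180 / pi
    )
  })
}

# polygon actually rendered: the quad, optionally with rounded corners
# (each corner replaced by an inscribed arc of the given radius)
render_polygon_points <- function(quad, radius) {
  if (radius <= 0) return(quad)
  n <- nrow(quad)
  pts <- NULL
  for (i in seq_len(n)) {
    p <- quad[i, ]
    a <- quad[if (i == 1) n else i - 1, ]
    b <- quad[if (i == n) 1 else i + 1, ]
    ua <- (a - p) / sqrt(sum((a - p)^2))
    ub <- (b - p) / sqrt(sum((b - p)^2))
    pa <- p + radius * ua
    pb <- p + radius * ub
    # quadratic Bezier from pa to pb with the corner as control point
    tt <- seq(0, 1, length.out = 5)
    arc <- outer((1 - tt)^2, pa) + outer(2 * tt * (1 - tt), p) + outer(tt^2, pb)
    pts <- rbind(pts, arc)
  }
  pts
}

# anti-aliased fill of a convex polygon by 4x4 subpixel coverage
render_convex_polygon <- function(img, poly, value) {
  h <- nrow(img); w <- ncol(img)
  # ensure counter-clockwise-in-matrix orientation for the half-plane tests
  area2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                 c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  c0 <- max(1, floor(min(poly[, 1])) ); c1 <- min(w, ceiling(max(poly[, 1])) + 2)
  r0 <- max(1, floor(min(poly[, 2])) ); r1 <- min(h, ceiling(max(poly[, 2])) + 2)
  sub <- c(-0.375, -0.125, 0.125, 0.375)
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
  cov <- matrix(0, length(ys), length(xs))
  for (dx in sub) for (dy in sub) {
    px <- matrix(xs + dx, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys + dy, length(ys), length(xs))
    inside <- matrix(TRUE, length(ys), length(xs))
    n <- nrow(poly)
    for (e in seq_len(n)) {
      pa <- poly[e, ]; pb <- poly[if (e == n) 1 else e + 1, ]
      inside <- inside &
        ((pb[1] - pa[1]) * (py - pa[2]) - (pb[2] - pa[2]) * (px - pa[1]) >= 0)
    }
    cov <- cov + inside
  }
  cov <- cov / 16
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] * (1 - cov) + value * cov
  img
}

#' Generate a seeded synthetic training set
#'
#' Draws `f` independent synthetic spines (per-image seeds derived from the
#' master seed), supporting sample-size studies such as re-running the
#' segmentation-error-versus-sample-size curve at f = 25, 50, 75, 100.
#'
#' @param spec A [synthetic_spec()].
#' @param f Number of images (>= 2).
#' @param seed Master seed.
#' @return A tibble with one row per image: `image_id`, and list-columns
#'   `image`, `shape`, `corners`, `anchors` (each `anchors` entry a list
#'   with `top`, `bottom`).
#' @export
generate_training_set <- function(spec, f, seed = 1) {
  if (f < 2) {
    rlang::abort("f must be >= 2", class = "spineasm_error_parameter")
  }
  draws <- lapply(seq_len(f), function(i) {
    generate_spine(spec, seed = (seed * 10007 + i) %% 2147483647)
  })
  tibble::tibble(
    image_id = seq_len(f),
    image = lapply(draws, `[[`, "image"),
    shape = lapply(draws, `[[`, "shape"),
    corners = lapply(draws, `[[`, "corners"),
    anchors = lapply(draws, function(d) list(top = d$anchor_top,
                                             bottom = d$anchor_bottom))
  )
}
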