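#' Outward unit normal of a landmark on its vertebra contour
#'
#' The normal at a landmark is perpendicular to the chord joining its two
#' neighbours on the closed vertebra contour (wrap-around), oriented outward
#' (away from the vertebra centroid).
#'
#' @param shape A shape tibble.
#' @param vertebra,landmark Identify the landmark.
#' @return Unit 2-vector `c(nx, ny)`.
#' @export
landmark_normal <- function(shape, vertebra, landmark) {
  normals <- shape_normals(dplyr::filter(shape, .data$vertebra == !!vertebra))
  as.numeric(normals[normals$landmark == landmark, c("nx", "ny")])
}

# Outward unit normals for every landmark of every vertebra block;
# vectorised. Returns the shape with nx, ny columns appended.
shape_normals <- function(shape) {
  shape |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::group_modify(function(df, key) {
      L <- nrow(df)
      if (L < 3) {
        rlang::abort("a contour needs at least 3 landmarks",
          class = "spineasm_error_validation")
      }
      df <- dplyr::arrange(df, .data$landmark)
      nxt <- c(2:L, 1); prv <- c(L, 1:(L - 1))
      cx <- df$x[nxt] - df$x[prv]
      cy <- df$y[nxt] - df$y[prv]
      len <- sqrt(cx^2 + cy^2)
      if (any(len < 1e-12)) {
        rlang::abort("coincident neighbour landmarks: normal undefined",
          class = "spineasm_error_validation")
      }
      nx <- -cy / len; ny <- cx / len
      # orient away from the vertebra centroid
      ox <- df$x - mean(df$x); oy <- df$y - mean(df$y)
      flip <- nx * ox + ny * oy < 0
      nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
      df$nx <- nx; df$ny <- ny
      df
    }) |>
    dplyr::ungroup()
}

# Profile sample offsets: k_p + 1 grey samples symmetric about 0, spaced by
# 1; multiplied by spacing_px at use. With k_p odd the samples sit at
# half-integer offsets so the k_p first differences are centred on the
# landmark.
profile_offsets <- function(k_p) seq(-k_p / 2, k_p / 2, by = 1)

#' Sample a normalized gradient profile along a normal
#'
#' Samples `k_p + 1` grey levels at `center + j * spacing_px * normal` for
#' offsets `j` symmetric about 0 (bilinear interpolation, edge-clamped),
#' forms the `k_p` first differences `g_j = I_j - I_{j-1}`, and normalizes.
#' The default normalization divides every difference by the sum of the
#' sampled grey levels; `"abs_grad_sum"` divides by the sum of absolute
#' differences (the classic Active Shape Model normalizer), `"none"` skips
#' normalization. A zero normalizer yields an all-zero profile.
#'
#' @param image Numeric grey matrix in `[0, 255]`.
#' @param center Landmark position `c(x, y)`.
#' @param normal Unit direction `c(nx, ny)`.
#' @param k_p Number of gradient values in the profile (default 7).
#' @param spacing_px Sample spacing in pixels.
#' @param norm `"grey_sum"`, `"abs_grad_sum"` or `"none"`.
#' @return Numeric vector of length `k_p`.
#' @export
sample_profile <- function(image, center, normal, k_p = 7, spacing_px,
                           norm = c("grey_sum", "abs_grad_sum", "none")) {
  norm <- match.arg(norm)
  if (k_p < 2) rlang::abort("k_p must be >= 2", class = "spineasm_error_parameter")
  if (spacing_px <= 0) {
    rlang::abort("spacing_px must be positive", class = "spineasm_error_parameter")
  }
  w <- ncol(image); h <- nrow(image)
  slack <- k_p * spacing_px
  if (center[1] < -slack || center[1] > w - 1 + slack ||
      center[2] < -slack || center[2] > h - 1 + slack) {
    rlang::abort("profile center too far outside the image",
      class = "spineasm_error_bounds")
  }
  off <- profile_offsets(k_p) * spacing_px
  grey <- bilinear_sample(image, center[1] + off * normal[1],
                          center[2] + off * normal[2])
  g <- diff(grey)
  denom <- switch(norm,
    grey_sum = sum(grey),
    abs_grad_sum = sum(abs(g)),
    none = 1
  )
  if (abs(denom) < 1e-12) return(rep(0, k_p)) else g / denom
}

# Profiles for all landmarks of a shape at once: returns an n x k_p matrix.
# spacing is per-vertebra (a fraction of that vertebra's anterior corner
# distance) unless spacing_px overrides it.
shape_profiles <- function(image, shape, k_p = 7, spacing_fraction = 0.05,
                           spacing_px = NULL, norm = "grey_sum") {
  sn <- shape_normals(shape)
  sn <- dplyr::arrange(sn, .data$vertebra, .data$landmark)
  sp <- if (is.null(spacing_px)) {
    vs <- vertebra_sizes(shape)
    spacing_fraction * vs[match(sn$vertebra, as.integer(names(vs)))]
  } else {
    rep(spacing_px, nrow(sn))
  }
  t(vapply(seq_len(nrow(sn)), function(i) {
    sample_profile(image, c(sn$x[i], sn$y[i]), c(sn$nx[i], sn$ny[i]),
                   k_p = k_p, spacing_px = sp[i], norm = norm)
  }, numeric(k_p)))
}

#' Vertebra size of each block in a shape
#'
#' The vertebra size used to scale profile spacing is the Euclidean distance
#' between the upper and lower anterior corner landmarks of the block.
#'
#' @param shape A shape tibble.
#' @return Named numeric vector, one size per vertebra.
#' @export
vertebra_sizes <- function(shape) {
  ac <- anterior_corners(shape)
  sizes <- ac |>
    tidyr::pivot_wider(names_from = "type", values_from = c("x", "y")) |>
    dplyr::mutate(size = sqrt((.data$x_upper - .data$x_lower)^2 +
                                (.data$y_upper - .data$y_lower)^2))
  stats::setNames(sizes$size, sizes$vertebra)
}

#' Learn per-landmark grey-level profile statistics
#'
#' For every landmark, collects its normalized gradient profile across the
#' training images and stores the sample mean, the sample covariance, and a
#' regularized inverse covariance `solve(S + eps I)` with
#' `eps = 1e-6 * trace(S) / k_p` (or `1e-6` when the trace vanishes, e.g.
#' identical training images). Profile spacing in each image is
#' `spacing_fraction` times that shape's vertebra size, so the profile scale
#' follows the imaged vertebra rather than the pixel grid.
#'
#' @param images List of grey matrices.
#' @param shapes List of landmark shapes (image frame), same length and
#'   structure.
#' @param k_p Profile point count (default 7).
#' @param spacing_fraction Spacing as a fraction of vertebra size (default
#'   0.05).
#' @param norm Profile normalization (see [sample_profile()]).
#' @return An object of class `profile_model`: `k_p`, `spacing_fraction`,
#'   `norm`, `V`, `L`, and per-landmark statistics `gbar` (k_p x n matrix),
#'   `Sinv` (list of k_p x k_p matrices), `S`, `epsilon`.
#' @export
build_profile_model <- function(images, shapes, k_p = 7,
                                spacing_fraction = 0.05, norm = "grey_sum") {
  f <- length(images)
  if (f < 2 || length(shapes) != f) {
    rlang::abort("at least 2 paired images and shapes are required",
      class = "spineasm_error_validation")
  }
  st <- shape_structure(shapes[[1]])
  profs <- lapply(seq_len(f), function(i) {
    shape_profiles(images[[i]], shapes[[i]], k_p = k_p,
                   spacing_fraction = spacing_fraction, norm = norm)
  })
  gbar <- matrix(0, k_p, st$n)
  S <- vector("list", st$n)
  Sinv <- vector("list", st$n)
  epsilon <- numeric(st$n)
  for (j in seq_len(st$n)) {
    G <- t(vapply(profs, function(p) p[j, ], numeric(k_p)))
    gbar[, j] <- colMeans(G)
    Sj <- stats::cov(G)
    Sj <- (Sj + t(Sj)) / 2
    eps <- 1e-6 * sum(diag(Sj)) / k_p
    if (eps <= 0) eps <- 1e-6
    S[[j]] <- Sj
    epsilon[j] <- eps
    Sinv[[j]] <- solve(Sj + diag(eps, k_p))
  }
  structure(
    list(k_p = as.integer(k_p), spacing_fraction = spacing_fraction,
         norm = norm, V = st$V, L = st$L, gbar = gbar, S = S, Sinv = Sinv,
         epsilon = epsilon),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf(
    "<profile_model> %d landmark(s), k_p = %d, spacing = %.1f%% of vertebra size, norm = %s\n",
    ncol(x$gbar), x$k_p, 100 * x$spacing_fraction, x$norm
  ))
  invisible(x)
}

#' Mahalanobis distance of a profile to a landmark's profile statistics
#'
#' `D = (g - gbar)^T S^-1 (g - gbar)` with the model's regularized inverse
#' covariance; `D >= 0` and `D(gbar) = 0`.
#'
#' @param g Profile vector of length `k_p`.
#' @param profile_model A `profile_model`.
#' @param landmark Global landmark index (1 .. V*L).
#' @return Nonnegative scalar.
#' @export
mahalanobis_profile <- function(g, profile_model, landmark) {
  d <- g - profile_model$gbar[, landmark]
  as.numeric(d %*% profile_model$Sinv[[landmark]] %*% d)
}
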