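#' Similarity transforms of the plane
#'
#' A similarity transform is a scaling `s > 0`, a rotation `theta` (radians,
#' measured in image coordinates) and a translation `(tx, ty)` in pixels:
#' `T(p) = s R(theta) p + t`. Transforms compose and invert exactly.
#'
#' @param scale Positive scale factor.
#' @param theta Rotation angle in radians.
#' @param tx,ty Translation in pixels.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, theta = 0, tx = 0, ty = 0) {
  if (scale <= 0) {
    rlang::abort("scale must be positive", class = "spineasm_error_parameter")
  }
  structure(list(scale = scale, theta = theta, tx = tx, ty = ty),
    class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> s = %.6g, theta = %.6g rad, t = (%.6g, %.6g)\n",
    x$scale, x$theta, x$tx, x$ty
  ))
  invisible(x)
}

tf_as_complex <- function(tf) {
  list(z = tf$scale * exp(1i * tf$theta), t = complex(real = tf$tx, imaginary = tf$ty))
}

#' Apply, compose and invert similarity transforms
#'
#' @param tf,a,b Transforms created by [similarity_transform()].
#' @param shape A shape tibble or a two-column matrix of points.
#' @return `apply_transform()` returns an object of the same kind as `shape`
#'   with transformed coordinates; `compose_transforms()` returns the
#'   transform applying `b` first, then `a`; `invert_transform()` the exact
#'   inverse.
#' @export
apply_transform <- function(tf, shape) {
  cz <- tf_as_complex(tf)
  if (is.data.frame(shape)) {
    p <- complex(real = shape$x, imaginary = shape$y)
    q <- cz$z * p + cz$t
    shape$x <- Re(q)
    shape$y <- Im(q)
    shape
  } else {
    p <- complex(real = shape[, 1], imaginary = shape[, 2])
    q <- cz$z * p + cz$t
    cbind(Re(q), Im(q))
  }
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  za <- tf_as_complex(a); zb <- tf_as_complex(b)
  z <- za$z * zb$z
  t <- za$z * zb$t + za$t
  similarity_transform(Mod(z), Arg(z), Re(t), Im(t))
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  cz <- tf_as_complex(tf)
  zi <- 1 / cz$z
  t <- -zi * cz$t
  similarity_transform(Mod(zi), Arg(zi), Re(t), Im(t))
}

#' Closed-form weighted similarity alignment of two shapes
#'
#' Returns the similarity transform `T` minimising the weighted sum of
#' squared distances `sum_k w_k * ||T(p_k) - q_k||^2` between corresponding
#' landmarks of `shape` (the `p_k`) and `reference` (the `q_k`). The solution
#' is the exact complex least-squares fit, so the alignment is deterministic
#' and needs no iteration. Weights default to uniform; a per-landmark weight
#' vector (e.g. inverse landmark variance) may be supplied.
#'
#' @param shape,reference Shape tibbles with equal landmark counts.
#' @param weights Optional nonnegative per-landmark weights (summing > 0).
#' @return A [similarity_transform()].
#' @export
align_pair <- function(shape, reference, weights = NULL) {
  if (nrow(shape) != nrow(reference)) {
    rlang::abort("shapes must have equal landmark counts",
      class = "spineasm_error_validation")
  }
  p <- complex(real = shape$x, imaginary = shape$y)
  q <- complex(real = reference$x, imaginary = reference$y)
  w <- if (is.null(weights)) rep(1, length(p)) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) {
    rlang::abort("weights must be nonnegative with positive sum",
      class = "spineasm_error_parameter")
  }
  w <- w / sum(w)
  pbar <- sum(w * p); qbar <- sum(w * q)
  pc <- p - pbar; qc <- q - qbar
  denom <- sum(w * Mod(pc)^2)
  if (denom < 1e-300) {
    rlang::abort("degenerate shape: all landmarks coincide",
      class = "spineasm_error_alignment")
  }
  z <- sum(w * Conj(pc) * qc) / denom
  if (Mod(z) < 1e-300) {
    rlang::abort("degenerate alignment: zero optimal scale",
      class = "spineasm_error_alignment")
  }
  t <- qbar - z * pbar
  similarity_transform(Mod(z), Arg(z), Re(t), Im(t))
}

#' Generalized Procrustes alignment of a training set
#'
#' Aligns a set of shapes into a common frame by iterated pairwise similarity
#' fits: every shape is first aligned to the first shape; then, until the
#' mean shape stabilises, the arithmetic mean of the aligned shapes is
#' computed, the mean is re-normalised by aligning it to the first shape
#' (which anchors size, orientation and origin), and every shape is
#' re-aligned to the mean. The iteration removes the dependency of the final
#' frame on the first shape beyond that anchoring.
#'
#' @param shapes A list of shape tibbles with identical structure, or a
#'   single tibble with an `image` column identifying the shapes.
#' @param weights Optional per-landmark weights passed to [align_pair()].
#' @param tol Convergence tolerance on the RMS displacement of the mean
#'   shape between iterations (default `1e-6`, in the anchored frame).
#' @param max_iter Iteration cap; non-convergence yields a warning and the
#'   best result, flagged in the diagnostics.
#' @return A list of class `gpa_alignment`: `aligned` (tibble of aligned
#'   shapes with an `image` column), `mean_shape` (shape tibble),
#'   `iterations`, `converged`, and the per-iteration alignment `objective`
#'   (weighted sum of squared distances to the current mean).
#' @export
generalized_procrustes <- function(shapes, weights = NULL, tol = 1e-6,
                                   max_iter = 100) {
  shapes <- as_shape_list(shapes)
  f <- length(shapes)
  if (f < 2) {
    rlang::abort("at least 2 shapes are required",
      class = "spineasm_error_validation")
  }
  st <- shape_structure(shapes[[1]])
  ns <- vapply(shapes, nrow, 0L)
  if (length(unique(ns)) != 1L) {
    rlang::abort("all shapes must share one structure",
      class = "spineasm_error_validation")
  }
  first <- shapes[[1]]
  aligned <- lapply(shapes, function(s) apply_transform(align_pair(s, first), s))
  mean_of <- function(lst) {
    v <- rowMeans(vapply(lst, shape_to_vector, numeric(2 * st$n)))
    vector_to_shape(v, st$V, st$L)
  }
  normalize <- function(m) apply_transform(align_pair(m, first), m)
  objective <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  prev_mean <- NULL
  mean_shape <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    mean_shape <- normalize(mean_of(aligned))
    if (!is.null(prev_mean)) {
      move <- sqrt(mean((shape_to_vector(mean_shape) -
                           shape_to_vector(prev_mean))^2))
      if (move < tol) {
        converged <- TRUE
        break
      }
    }
    prev_mean <- mean_shape
    aligned <- lapply(shapes, function(s) {
      apply_transform(align_pair(s, mean_shape, weights), s)
    })
    obj <- sum(vapply(aligned, function(s) {
      w <- if (is.null(weights)) rep(1, st$n) else weights
      sum(w * ((s$x - mean_shape$x)^2 + (s$y - mean_shape$y)^2))
    }, 0))
    # scale-free: divide by the squared centroid size of the current mean so
    # the per-iteration values are comparable across re-normalisations
    msize <- sum((mean_shape$x - mean(mean_shape$x))^2 +
                   (mean_shape$y - mean(mean_shape$y))^2)
    objective <- c(objective, obj / msize)
  }
  if (!converged) {
    rlang::warn("generalized Procrustes alignment did not converge; returning best result")
  }
  aligned_tbl <- dplyr::bind_rows(
    purrr::imap(aligned, function(s, i) dplyr::mutate(s, image = i, .before = 1))
  )
  structure(
    list(aligned = aligned_tbl, mean_shape = mean_shape,
         iterations = iterations, converged = converged, objective = objective),
    class = "gpa_alignment"
  )
}

# Accept either a list of shape tibbles or one long tibble keyed by `image`.
as_shape_list <- function(shapes) {
  if (is.data.frame(shapes)) {
    if (!"image" %in% names(shapes)) {
      rlang::abort("a combined shape tibble needs an `image` column",
        class = "spineasm_error_validation")
    }
    shapes <- shapes |>
      dplyr::group_by(.data$image) |>
      dplyr::group_split(.keep = FALSE)
    shapes <- lapply(shapes, validate_shape)
  }
  lapply(shapes, validate_shape)
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(sprintf(
    "<gpa_alignment> %d shapes, %d landmarks; %d iteration(s), %s\n",
    length(unique(x$aligned$image)), nrow(x$mean_shape), x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}
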