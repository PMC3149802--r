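#' Build a point-distribution model from aligned shapes
#'
#' Computes the mean shape vector and the principal modes of variation of a
#' set of Procrustes-aligned shapes: the eigenvectors of the sample
#' variance-covariance matrix of the interleaved coordinate vectors. The
#' smallest number of modes `t` whose eigenvalues capture at least
#' `variance_fraction` of the total variance is retained (capped at
#' `min(2n, f - 1)`, the rank of the sample covariance). Any shape instance
#' is then `x = xbar + P b` with mode weights `b`.
#'
#' Two model kinds are supported: a `"vertebra"` model describes a single
#' vertebral body (one block of `L` landmarks), a `"column"` model the whole
#' spine as one shape (all `V` blocks jointly).
#'
#' @param aligned A `gpa_alignment` (see [generalized_procrustes()]), a list
#'   of aligned shape tibbles, or a combined tibble with an `image` column.
#' @param variance_fraction Fraction of total variance to retain (default
#'   0.98).
#' @param kind `"vertebra"` or `"column"`.
#' @param bound Mode-weight bound convention used by [clamp_modes()]:
#'   `"sqrt"` clips each `b_i` to `[-3*sqrt(lambda_i), +3*sqrt(lambda_i)]`
#'   (three standard deviations, the standard Active Shape Model constraint);
#'   `"raw"` uses `[-3*lambda_i, +3*lambda_i]`. Default `"sqrt"`.
#' @return An object of class `shape_model` with elements `mean` (vector,
#'   length `2n`), `P` (`2n x t` orthonormal mode matrix), `lambda`
#'   (eigenvalues, non-increasing), `t`, `kind`, `V`, `L`, `f`,
#'   `variance_fraction`, `variance_captured`, `bound`.
#' @export
build_shape_model <- function(aligned, variance_fraction = 0.98,
                              kind = c("vertebra", "column"),
                              bound = c("sqrt", "raw")) {
  kind <- match.arg(kind)
  bound <- match.arg(bound)
  if (inherits(aligned, "gpa_alignment")) aligned <- aligned$aligned
  shapes <- as_shape_list(aligned)
  f <- length(shapes)
  if (f < 2) {
    rlang::abort("at least 2 aligned shapes are required",
      class = "spineasm_error_validation")
  }
  if (variance_fraction <= 0 || variance_fraction > 1) {
    rlang::abort("variance_fraction must lie in (0, 1]",
      class = "spineasm_error_parameter")
  }
  st <- shape_structure(shapes[[1]])
  X <- t(vapply(shapes, shape_to_vector, numeric(2 * st$n)))
  xbar <- colMeans(X)
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  tol <- max(eig$values[1], 0) * 1e-10
  pos <- which(eig$values > tol)
  model <- structure(
    list(mean = xbar, P = matrix(0, 2 * st$n, 0), lambda = numeric(0), t = 0L,
         kind = kind, V = st$V, L = st$L, f = f,
         variance_fraction = variance_fraction, variance_captured = 1,
         bound = bound, profiles = NULL),
    class = "shape_model"
  )
  if (length(pos) == 0) {
    rlang::warn("training shapes have zero variance; returning a mean-only model")
    return(model)
  }
  lambda <- eig$values[pos]
  total <- sum(lambda)
  # small slack so an exact retention boundary (e.g. 9/10 vs 0.9) is not
  # flipped by eigenvalue rounding
  t_keep <- which(cumsum(lambda) / total >= variance_fraction - 1e-12)[1]
  t_keep <- min(t_keep, 2 * st$n, f - 1)
  P <- eig$vectors[, pos[seq_len(t_keep)], drop = FALSE]
  # deterministic sign: first component of magnitude > 1e-12 is positive
  for (j in seq_len(ncol(P))) {
    nz <- which(abs(P[, j]) > 1e-12)[1]
    if (!is.na(nz) && P[nz, j] < 0) P[, j] <- -P[, j]
  }
  model$P <- P
  model$lambda <- lambda[seq_len(t_keep)]
  model$t <- as.integer(t_keep)
  model$variance_captured <- sum(model$lambda) / total
  model
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "<shape_model> kind = %s, %d vertebra(e) x %d landmarks, %d mode(s) (%.1f%% variance, f = %d)%s\n",
    x$kind, x$V, x$L, x$t, 100 * x$variance_captured, x$f,
    if (!is.null(x$profiles)) ", with grey-level profiles" else ""
  ))
  invisible(x)
}

#' Project a shape onto the model's mode weights
#'
#' Computes `b = P^T (x - xbar)`: because the mode matrix has orthonormal
#' columns this is the least-squares weight vector for expressing `x` in the
#' model subspace.
#'
#' @param model A `shape_model`.
#' @param shape A shape tibble or an interleaved coordinate vector of
#'   matching length.
#' @return Numeric vector `b` of length `model$t`.
#' @export
shape_project <- function(model, shape) {
  x <- if (is.data.frame(shape)) shape_to_vector(shape) else as.numeric(shape)
  if (length(x) != length(model$mean)) {
    rlang::abort("shape length does not match the model",
      class = "spineasm_error_validation")
  }
  as.numeric(crossprod(model$P, x - model$mean))
}

#' Reconstruct a shape from mode weights
#'
#' Returns `x = xbar + P b` as a shape tibble with the model's structure.
#'
#' @param model A `shape_model`.
#' @param b Mode weight vector of length `model$t` (recycled `0` allowed via
#'   `b = numeric(0)` for a mean-only model).
#' @return A shape tibble.
#' @export
shape_reconstruct <- function(model, b) {
  if (length(b) != model$t) {
    rlang::abort("b length does not match the model's mode count",
      class = "spineasm_error_validation")
  }
  x <- model$mean + if (model$t > 0) as.numeric(model$P %*% b) else 0
  vector_to_shape(x, model$V, model$L)
}

#' Clamp mode weights to the model's plausibility bounds
#'
#' Clips each weight `b_i` to the symmetric interval implied by the model's
#' `bound` convention — `[-3*sqrt(lambda_i), +3*sqrt(lambda_i)]` for
#' `"sqrt"` (three standard deviations along each mode, the standard Active
#' Shape Model constraint) or `[-3*lambda_i, +3*lambda_i]` for `"raw"`.
#' Clamping is idempotent.
#'
#' @param model A `shape_model`.
#' @param b Mode weight vector of length `model$t`.
#' @return The clamped weight vector.
#' @export
clamp_modes <- function(model, b) {
  if (length(b) != model$t) {
    rlang::abort("b length does not match the model's mode count",
      class = "spineasm_error_validation")
  }
  lim <- mode_limits(model)
  pmin(pmax(b, -lim), lim)
}

mode_limits <- function(model) {
  if (model$bound == "sqrt") 3 * sqrt(model$lambda) else 3 * model$lambda
}

#' Mean shape of a model as a tibble
#'
#' @param model A `shape_model`.
#' @return A shape tibble of the model mean.
#' @export
mean_shape <- function(model) {
  vector_to_shape(model$mean, model$V, model$L)
}
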