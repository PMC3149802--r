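#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape model: one row per retained mode
#'
#' @param x A `shape_model`.
#' @param ... Unused.
#' @return A tibble with `mode`, `eigenvalue`, `variance_prop`,
#'   `cumulative_prop`, `b_limit` (the clamp bound).
#' @exportS3Method generics::tidy
tidy.shape_model <- function(x, ...) {
  if (x$t == 0) {
    return(tibble::tibble(mode = integer(0), eigenvalue = numeric(0),
                          variance_prop = numeric(0),
                          cumulative_prop = numeric(0), b_limit = numeric(0)))
  }
  total <- sum(x$lambda) / x$variance_captured
  tibble::tibble(
    mode = seq_len(x$t),
    eigenvalue = x$lambda,
    variance_prop = x$lambda / total,
    cumulative_prop = cumsum(x$lambda / total),
    b_limit = mode_limits(x)
  )
}

#' @rdname tidy.shape_model
#' @exportS3Method generics::glance
glance.shape_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n_vertebrae = x$V, n_landmarks_per_vertebra = x$L,
    n_training_shapes = x$f, n_modes = x$t,
    variance_captured = x$variance_captured,
    has_profiles = !is.null(x$profiles)
  )
}

#' Tidy an ASM fit: per-iteration search diagnostics
#'
#' @param x An `asm_fit`.
#' @param ... Unused.
#' @return The per-iteration diagnostics tibble (`iteration`, `moved`,
#'   `mean_mahalanobis`, and `vertebra` for spine-wise fits).
#' @exportS3Method generics::tidy
tidy.asm_fit <- function(x, ...) {
  x$diagnostics
}

#' @rdname tidy.asm_fit
#' @exportS3Method generics::glance
glance.asm_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations, converged = x$converged, hit_cap = x$hit_cap,
    n_landmarks = nrow(x$shape)
  )
}

#' Tidy an evaluation report: per-vertebra error summary
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-vertebra tibble with mean errors and success flags.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  x$vertebrae
}

#' @rdname tidy.eval_report
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    mean_point_to_line = mean(x$landmarks$point_to_line),
    mean_point_to_point = mean(x$landmarks$point_to_point),
    success_rate = 100 * mean(x$vertebrae$success),
    threshold = x$threshold
  )
}
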