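#' Train a full Active Shape Model (shape + profiles) from a training set
#'
#' Convenience wrapper over the training pipeline: for a `"column"` model
#' the whole-spine shapes are Procrustes-aligned and modelled jointly; for a
#' `"vertebra"` model every vertebra block of every training image becomes
#' one training example (paired with its image), so a single model describes
#' all vertebra instances. Grey-level profile statistics are learned on the
#' unaligned (image-frame) landmarks.
#'
#' @param training A tibble as returned by [generate_training_set()] (list
#'   columns `image` and `shape`), or a list with elements `images` and
#'   `shapes`.
#' @param kind `"vertebra"` or `"column"`.
#' @param variance_fraction Variance retained by the shape model (default
#'   0.98).
#' @param k_p,spacing_fraction,norm Profile parameters (see
#'   [build_profile_model()]): by default a profile of 7 points spaced by 5%
#'   of the vertebra size.
#' @param bound Mode-bound convention (see [build_shape_model()]).
#' @return A `shape_model` with the `profile_model` attached as
#'   `$profiles` and the alignment kept as attribute `"gpa"`.
#' @export
train_asm <- function(training, kind = c("vertebra", "column"),
                      variance_fraction = 0.98, k_p = 7,
                      spacing_fraction = 0.05, norm = "grey_sum",
                      bound = c("sqrt", "raw")) {
  kind <- match.arg(kind)
  bound <- match.arg(bound)
  if (is.data.frame(training)) {
    images <- training$image
    shapes <- training$shape
  } else {
    images <- training$images
    shapes <- training$shapes
  }
  if (kind == "vertebra") {
    ex_images <- list(); ex_shapes <- list()
    for (i in seq_along(shapes)) {
      for (blk in split(shapes[[i]], shapes[[i]]$vertebra)) {
        ex_images[[length(ex_images) + 1]] <- images[[i]]
        ex_shapes[[length(ex_shapes) + 1]] <-
          dplyr::mutate(blk, vertebra = 1L)
      }
    }
    images <- ex_images
    shapes <- ex_shapes
  }
  gpa <- generalized_procrustes(shapes)
  model <- build_shape_model(gpa, variance_fraction = variance_fraction,
                             kind = kind, bound = bound)
  model$profiles <- build_profile_model(images, shapes, k_p = k_p,
                                        spacing_fraction = spacing_fraction,
                                        norm = norm)
  attr(model, "gpa") <- gpa
  model
}

#' Write and read a trained model file
#'
#' The model file is versioned structured text (JSON) storing the mean
#' shape, mode matrix, eigenvalues, metadata and — when present — the
#' per-landmark profile statistics, with floats at full precision so a
#' write/read round trip reproduces the model.
#'
#' @param model A `shape_model` (optionally with `$profiles`).
#' @param path Output path (conventionally `.json`).
#' @export
write_asm_model <- function(model, path) {
  # matrices stored as flat column-major vectors with explicit dims so the
  # file layout does not depend on a JSON matrix convention
  obj <- list(
    format_version = 1,
    kind = model$kind, V = model$V, L = model$L, f = model$f,
    variance_fraction = model$variance_fraction,
    variance_captured = model$variance_captured,
    bound = model$bound, t = model$t,
    mean = model$mean, lambda = model$lambda, P = as.numeric(model$P)
  )
  if (!is.null(model$profiles)) {
    p <- model$profiles
    obj$profiles <- list(
      k_p = p$k_p, spacing_fraction = p$spacing_fraction, norm = p$norm,
      V = p$V, L = p$L, gbar = as.numeric(p$gbar), epsilon = p$epsilon,
      S = lapply(p$S, as.numeric)
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_asm_model
#' @return `read_asm_model()`: the restored `shape_model`.
#' @export
read_asm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1) {
    rlang::abort("unsupported model file version",
      class = "spineasm_error_format")
  }
  n2 <- length(obj$mean)
  P <- matrix(as.numeric(unlist(obj$P)), nrow = n2, ncol = as.integer(obj$t))
  model <- structure(
    list(mean = as.numeric(obj$mean), P = P,
         lambda = as.numeric(obj$lambda), t = as.integer(obj$t),
         kind = obj$kind, V = as.integer(obj$V), L = as.integer(obj$L),
         f = as.integer(obj$f),
         variance_fraction = obj$variance_fraction,
         variance_captured = obj$variance_captured,
         bound = obj$bound, profiles = NULL),
    class = "shape_model"
  )
  if (!is.null(obj$profiles)) {
    p <- obj$profiles
    k_p <- as.integer(p$k_p)
    n <- as.integer(p$V) * as.integer(p$L)
    gbar <- matrix(as.numeric(unlist(p$gbar)), nrow = k_p, ncol = n)
    S <- if (is.list(p$S)) {
      lapply(p$S, function(s) matrix(as.numeric(unlist(s)), k_p, k_p))
    } else {
      lapply(seq_len(n), function(j) matrix(p$S[j, ], k_p, k_p))
    }
    eps <- as.numeric(p$epsilon)
    Sinv <- lapply(seq_len(n), function(j) solve(S[[j]] + diag(eps[j], k_p)))
    model$profiles <- structure(
      list(k_p = k_p, spacing_fraction = p$spacing_fraction, norm = p$norm,
           V = as.integer(p$V), L = as.integer(p$L), gbar = gbar, S = S,
           Sinv = Sinv, epsilon = eps),
      class = "profile_model"
    )
  }
  model
}
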